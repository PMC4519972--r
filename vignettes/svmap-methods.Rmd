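---
title: "SV markers and linkage maps for haploid fungi: models and methods"
author: "svmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SV markers and linkage maps for haploid fungi: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmap)
```

# The problem

In heterothallic basidiomycetes the two nuclei of a fruiting heterokaryon
can be recovered as compatible homokaryotic strains. Sequencing one of them
as a reference assembly and re-sequencing the other with a paired-end
library exposes every structural variation (SV) between the two haploid
genomes. Each SV is a candidate *co-dominant* PCR marker: primers placed in
the flanking sequence amplify products of different length from the two
parents (and both products from the heterokaryon), so a single agarose gel
scores every single-spore isolate (SSI) unambiguously. Because basidiospores
are haploid meiotic products, an SSI population can be genotyped and mapped
directly, with no phase or dominance complications.

`svmap` implements the complete desk side of this strategy — SV detection
from discordant read pairs, marker design, population QC, linkage mapping
and scaffold anchoring — together with a simulator that generates every
input with recorded ground truth, so each stage is testable against an
exact oracle.

# The simulator

`simulateParentalGenomes()` draws a uniform-composition random reference
and derives the donor genome by planting a configurable spectrum of
variants, pairwise disjoint and separated by at least `minVariantGap`
(default 2000 bp) so that read-pair signatures and marker flanks of
different variants never interfere:

* *insertion* — donor gains novel sequence at a reference point;
* *deletion* — donor lacks a reference interval;
* *duplication* — a reference interval appears twice in tandem;
* *inversion* — an interval is reverse-complemented;
* *complex* — an interval is replaced by novel sequence of different length.

The exact reference/donor correspondence is kept as piecewise liftover
segments. `simulateReadPairs()` draws fragments from the donor
(Normal insert, default mean 505 bp and s.d. 50 bp, the library geometry of
the motivating experiment; 100 bp reads; 30x coverage) and places each read
on the reference through the segment containing its midpoint. This
reproduces the geometry an aligner would report — concordant pairs conserve
the sampled fragment length *exactly*, deletion-spanning pairs are
stretched by exactly the deleted length, pairs across an inversion
breakpoint become same-strand, tandem-duplication junctions become everted
— without modelling base-call errors, quality scores or mapping ambiguity.
Reads wholly inside donor-only sequence are emitted as half-mapped pairs.
What passing tests on these data show is therefore that the *inference*
logic is correct under ideal alignment; they do not probe robustness to
alignment artefacts, repeats or base errors in real libraries.

`simulateMeiosis()` models crossovers as a Poisson process of rate 1 per
Morgan without interference, so the recombination fraction between markers
separated by $d$ cM is Haldane's $r = (1 - e^{-2d/100})/2$ — a closed form
the tests use as an exact oracle (e.g. $r = 0.0906$ at 10 cM). The
motivating experiment's methods never state an interference model;
choosing "none" is what makes the generator exactly testable. Heterokaryotic
strains (default rate 43/235) carry both nuclei and therefore score the
two-band code `h` at every marker; missing calls (`-`, default 2%) are laid
down independently afterwards. The choice of a no-interference model also
means Kosambi distances (which assume partial interference) re-estimated
from these simulations are slightly *shorter* than the generating Haldane
scale; recovery tests therefore compare recombination fractions and marker
orders, not absolute cM.

# SV calling

Pairs are classified against an insert model fitted robustly
(median, 1.4826×MAD over forward/reverse pairs) with concordance
multiplier $k = 3$ (the source experiment is silent on this; 3 s.d. is the
conventional choice):

| signature | geometry | implied type |
|---|---|---|
| `del_like` | FR, insert $> \mu + k\sigma$ | deletion |
| `ins_like` | FR, insert $< \mu - k\sigma$ | insertion |
| `inv_like` | same-strand | inversion |
| `dup_like` | everted (RF) | tandem duplication |
| `one_end_unmapped` | mate in donor-only sequence | insertion (length is a lower bound) |

The signature-to-type table for duplications and inversions is a reasoned
reconstruction: the motivating study reports these classes without stating
its detection rules. Same-signature pairs whose breakpoint intervals fall
within `maxGap` (default 100 bp) cluster; clusters below `minSupport` are
dropped. The support threshold defaults to **6**, reading the published
"more than 5 pairs" rule strictly; it is exposed because the phrasing is
ambiguous. Overlapping surviving clusters of *conflicting* types merge into
one `complex` locus; same-type overlaps (an undersized-insert cluster plus
a half-mapped cluster at one insertion point) merge into one call.

Numerical choices in breakpoint estimation: deletion/insertion positions
use the *median* of per-pair inner-interval midpoints and the median
implied size change — sporadic fragment-length tail pairs (expected at rate
$2\Phi(-k)$ among concordant genome, i.e. a handful per Mb at $k=3$) join
clusters occasionally and must not drag a min/max envelope. Inversion edges
come from the closest approach of the two same-strand families, duplication
edges from the outer envelope of everted pairs; both are accurate to about
a read length (reads straddling a breakpoint are placed by their majority
segment, so single-read overhangs of up to half a read length are
expected). Insertions longer than the usable inner gap
($\mu - 2R - k\sigma$) are detectable only as half-mapped clusters and are
flagged `lowerBound`.

# Marker design

Following the published selection rules, loci of SV length 200–800 bp
(inclusive) with 300 bp flanks free of N/gap characters and inside the
scaffold become candidates. Primer thermodynamics are deliberately out of
scope (the original work used a dedicated primer tool); the 20 bp outer
tips of the flanks stand in for primer sites, which preserves the
amplicon-size arithmetic exactly: size in the reference parent is
flank + locus + flank, the donor size is the same interval lifted through
the variant segments. A tip that occurs more than once in either genome
(`non_specific`) or does not lift to a unique forward-strand donor position
(`no_unique_product` — deleted, duplicated or inverted sites) rejects the
marker.

Whether two products are distinguishable on a gel is not stated numerically
anywhere in the source material, so the effectiveness rule
$|A - B| \ge \max(20\,\mathrm{bp},\ 0.05 \cdot \min(A, B))$ is this
package's own calibration of agarose resolution, exposed as `absMin` /
`relMin`. An inversion conserves length and is correctly rejected as
non-co-dominant by size.

# Genotype QC and linkage mapping

Strains showing `h` at any screening marker are heterokaryotic and
excluded; strains with `-` at every screening marker are undetermined and
also excluded. A residual `h` in a declared homokaryon is biologically
impossible and treated as a scoring error (coerced to `-` with a counted
warning). Markers with >20% missing data or 1:1 segregation $p < 10^{-3}$
are flagged, never auto-dropped — the source experiment states no exclusion
rule, so the decision is left to the user.

Mapping is two-point throughout: for haploid co-dominant data the
recombinant count $R$ among $n$ doubly-scored strains fully determines the
likelihood, giving $\hat r = R/n$ (capped at 0.5) and
$LOD = R\log_{10} 2\hat r + (n-R)\log_{10} 2(1-\hat r)$. The multipoint EM
and error-detection machinery of the classic mapping software is *not*
reproduced — a deliberate divergence: two-point statistics are fully
specified by the data type, testable against closed forms, and sufficient
at these marker densities.

Grouping takes connected components over pairs with $LOD \ge 3$ (the
published threshold). An optional co-requirement $\hat r \le$ `maxRf`
guards against sporadic spurious linkage: with $n = 192$ and ~100 markers
on 10 chromosomes there are ~4,500 between-chromosome pairs, and the
binomial tail gives each about a $10^{-4}$ chance of reaching LOD 3 by
chance — about one spurious edge every other experiment. At `maxRf = 0.3`
($R \le 57$ of 192, a $5.6\sigma$ deviation) spurious linkage is
negligible while true adjacent markers at 5–15 cM ($r \le 0.14$) are
unaffected. The package default is 0.5 (disabled), matching the published
rule exactly; the pipeline and the validation runs use 0.3 for the reason
above.

Ordering follows the framework-and-try strategy: a supplied framework
(physical-map order) or the most confidently linked triple seeds the order;
remaining markers are inserted at the slot minimising the sum of adjacent
$\hat r$; a window-3 permutation pass ("ripple") runs to convergence. Ties
break deterministically (first minimal slot; final orientation
canonicalised by marker id). On groups of ≤ 8 markers the result is checked
against the exhaustive-permutation optimum. Distances between adjacent
markers use Kosambi's function $d = 25\ln\frac{1+2r}{1-2r}$ cM with exact
inverse $r = \tanh(d/50)/2$. Groups are numbered by descending marker
count, then descending length — the published table follows this pattern
but states no convention. The per-group "average marker spacing" is map
length divided by marker *count* (not intervals), matching the published
table's arithmetic; totals are exact sums and the overall mean spacing is
reported to 3 decimals because the source tables round the same quantity
two different ways.

# Scaffold anchoring

Each scaffold joins the group holding the majority of its markers (ties to
the lowest group id — the source reports no split scaffolds and states no
rule). Orientation is the sign of the Spearman correlation between cM and
bp positions; one marker cannot orient a scaffold. Scaffold sizes come from
the assembly FASTA, not marker spans. The reduced scaffold count assumes
each group's scaffolds merge into one super-scaffold:
original − anchored + groups. Interleaving conflicts — a run of one
scaffold's markers strictly between two markers of another — are reported
with their cM gap, reproducing the published conflict case's pattern.

Recombination outliers are scanned over map-adjacent same-scaffold marker
intervals: an interval is *hot* at ≥ `hotFactor` (default 3) times the
genome-mean cM/kb and *cold* at ≤ `coldFactor` (default 1/3). These factors
are this package's own: the source names example intervals without a
numeric rule. Under the defaults its hotspot examples (≈5.7× and ≈4.5× the
mean) qualify while its coldspot examples (≈0.40× and ≈0.60×) do not —
users wanting the latter labelled cold must relax `coldFactor` to ≈0.45.

# Validation problem sizes

The test suite and acceptance script exercise, as the package's chosen
validation scale: the published class/group tables re-rolled exactly;
ordering versus exhaustive search on 100 simulated groups of 4–8 markers at
$n = 192$; Kosambi round-trips to $10^{-12}$; Haldane recovery at
$n = 50{,}000$ within 3 binomial s.e.; 40-seed mapping recovery (10
chromosomes × 10 markers, 5–15 cM spacing, $n = 192$, ≥95% joint
grouping-and-order success up to group reversal); and 20-seed SV recovery
(12 well-separated SVs ≥ 200 bp on 180 kb at 30×, recall = precision = 1
with breakpoints matched within one insert length). The bundled demo
pipeline uses ten 300 kb scaffolds at 1 cM per 47.7 kb.

# Known limitations

* Alignment is simulated by exact liftover; repeat-induced mismapping,
  base errors and coverage bias are unmodelled.
* Insertions longer than the library insert appear only as lower-bound
  calls; dispersed (non-tandem) duplications and inter-scaffold
  translocations are out of scope.
* Two-point ordering can invert very tight marker pairs (< ~2 cM at
  $n \approx 200$) — a population-size limit, not an algorithmic one.
* The no-interference meiosis model makes Kosambi cM systematically
  slightly shorter than the generating scale, as discussed above.
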