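## Parental genome pair simulation: a random reference, a donor derived from
## it by a known variant spectrum, and the piecewise liftover between the two
## coordinate systems. The liftover segments are what makes downstream read
## "alignment" exact: no aligner is ever run.

DNA_BASES <- c("A", "C", "G", "T")

randomDna <- function(n) {
  if (n == 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Reference span consumed by each variant type (insertion is a point).
refSpanOf <- function(type, len) {
  ifelse(type == "insertion", 0L, len)
}

#' Simulate a pair of parental haploid genomes
#'
#' Generates a random reference genome, plants the configured spectrum of
#' structural variants (pairwise disjoint, separated by at least
#' \code{minVariantGap} bp and kept away from scaffold ends) plus background
#' SNPs, and derives the donor genome by applying them. The exact
#' reference/donor coordinate correspondence is recorded as liftover segments.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{reference} and \code{donor}
#'   (\code{DNAStringSet}), \code{variants} (data.frame: scaffold, start, end
#'   0-based half-open on the reference, type, length, seq), \code{snps}
#'   (data.frame: scaffold, pos, ref, alt), \code{segments} (liftover table)
#'   and \code{config}.
#' @seealso [applyVariants()] for the deterministic re-application of a
#'   variant set, [simulateReadPairs()] for the read layer.
#' @export
simulateParentalGenomes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  set.seed(config@seed)
  lens <- config@scaffoldLengths
  scafIds <- sprintf("scaffold%02d", seq_along(lens))
  reference <- Biostrings::DNAStringSet(vapply(lens, randomDna, character(1)))
  names(reference) <- scafIds

  variants <- placeVariants(scafIds, lens, config)
  snps <- sampleSnps(reference, variants, config@snpRate)
  ad <- applyVariants(reference, variants, snps)
  list(reference = reference, donor = ad$donor, variants = variants,
       snps = snps, segments = ad$segments, config = config)
}

## Rejection-sample disjoint variant placements; error out when the requested
## spectrum cannot be placed with the required spacing.
placeVariants <- function(scafIds, lens, config) {
  counts <- config@svCounts
  total <- sum(counts)
  cols <- list(scaffold = character(0), start = integer(0), end = integer(0),
               type = character(0), length = integer(0), seq = character(0))
  if (total == 0L) return(as.data.frame(cols, stringsAsFactors = FALSE))
  types <- rep(names(counts), counts)
  types <- sample(types)                      # interleave classes
  margin <- 1000L
  gap <- config@minVariantGap
  placed <- lapply(scafIds, function(s) cbind(integer(0), integer(0)))
  names(placed) <- scafIds
  out <- vector("list", total)
  maxTries <- 200L * total
  tries <- 0L
  for (i in seq_along(types)) {
    ty <- types[i]
    rng <- config@svLengthRanges[[ty]]
    repeat {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("requested variants do not fit disjointly on the scaffolds ",
             "(capacity exceeded; reduce counts/lengths or enlarge scaffolds)")
      len <- if (rng[1] == rng[2]) rng[1] else
        sample(seq.int(rng[1], rng[2]), 1L)
      span <- refSpanOf(ty, len)
      sc <- sample(seq_along(scafIds), 1L, prob = lens)
      lo <- margin
      hi <- lens[sc] - margin - span
      if (hi <= lo) next
      st <- sample(seq.int(lo, hi), 1L)
      en <- st + span
      prev <- placed[[sc]]
      if (nrow(prev) && any(st - gap < prev[, 2] & en + gap > prev[, 1]))
        next
      placed[[sc]] <- rbind(prev, c(st, en))
      sq <- switch(ty,
        insertion = randomDna(len),
        complex   = randomDna(max(50L, len %/% 2L)),
        "")
      out[[i]] <- data.frame(scaffold = scafIds[sc], start = st, end = en,
                             type = ty, length = len, seq = sq,
                             stringsAsFactors = FALSE)
      break
    }
  }
  v <- do.call(rbind, out)
  v <- v[order(v$scaffold, v$start), , drop = FALSE]
  rownames(v) <- NULL
  v
}

sampleSnps <- function(reference, variants, snpRate) {
  empty <- data.frame(scaffold = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE)
  if (snpRate <= 0) return(empty)
  out <- lapply(names(reference), function(sc) {
    L <- Biostrings::width(reference[sc])
    n <- rbinom(1L, L, snpRate)
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(L, n) - 1L)
    vs <- variants[variants$scaffold == sc, , drop = FALSE]
    if (nrow(vs)) {
      inside <- vapply(pos, function(p) any(p >= vs$start & p < vs$end),
                       logical(1))
      pos <- pos[!inside]
    }
    if (!length(pos)) return(NULL)
    refb <- strsplit(as.character(reference[[sc]]), "")[[1]][pos + 1L]
    alt <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1L),
                  character(1), USE.NAMES = FALSE)
    data.frame(scaffold = sc, pos = pos, ref = refb, alt = alt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Apply a variant (and SNP) set to a reference genome
#'
#' Deterministically rebuilds the donor genome from the reference and an
#' explicit variant table, emitting the piecewise liftover between the two
#' coordinate systems. \code{simulateParentalGenomes()} uses this internally;
#' it is exported so a recorded truth set can be re-applied.
#'
#' Variant semantics (0-based half-open reference coordinates):
#' \describe{
#'   \item{insertion}{\code{start == end}; donor gains \code{seq} at the point.}
#'   \item{deletion}{donor lacks \code{[start, end)}.}
#'   \item{duplication}{donor carries \code{[start, end)} twice in tandem.}
#'   \item{inversion}{donor carries the reverse complement of \code{[start, end)}.}
#'   \item{complex}{\code{[start, end)} is replaced by the novel \code{seq}.}
#' }
#'
#' @param reference a \code{DNAStringSet}.
#' @param variants data.frame as produced by [simulateParentalGenomes()].
#' @param snps optional SNP table (scaffold, pos, ref, alt) applied before the
#'   structural variants.
#' @return list with \code{donor} (\code{DNAStringSet}) and \code{segments}, a
#'   data.frame mapping donor intervals to reference intervals with columns
#'   \code{scaffold}, \code{refStart}, \code{refEnd}, \code{donorStart},
#'   \code{donorEnd}, \code{strand} (\code{"-"} for inverted blocks) and
#'   \code{mapped} (\code{FALSE} for donor-only sequence).
#' @export
applyVariants <- function(reference, variants, snps = NULL) {
  donorSeqs <- character(length(reference))
  segList <- vector("list", length(reference))
  for (k in seq_along(reference)) {
    sc <- names(reference)[k]
    refChar <- as.character(reference[[k]])
    if (!is.null(snps) && nrow(snps)) {
      sn <- snps[snps$scaffold == sc, , drop = FALSE]
      if (nrow(sn)) {
        ch <- strsplit(refChar, "")[[1]]
        ch[sn$pos + 1L] <- sn$alt
        refChar <- paste(ch, collapse = "")
      }
    }
    vs <- variants[variants$scaffold == sc, , drop = FALSE]
    vs <- vs[order(vs$start), , drop = FALSE]
    pieces <- character(0)
    segs <- list()
    cr <- 0L   # reference cursor
    cd <- 0L   # donor cursor
    addSeg <- function(rs, re, ds, de, strand, mapped) {
      segs[[length(segs) + 1L]] <<- data.frame(
        scaffold = sc, refStart = rs, refEnd = re,
        donorStart = ds, donorEnd = de, strand = strand, mapped = mapped,
        stringsAsFactors = FALSE)
    }
    emitMatch <- function(upto) {
      w <- upto - cr
      if (w > 0L) {
        pieces[length(pieces) + 1L] <<- substr(refChar, cr + 1L, upto)
        addSeg(cr, upto, cd, cd + w, "+", TRUE)
        cd <<- cd + w
      }
      cr <<- upto
    }
    for (i in seq_len(nrow(vs))) {
      v <- vs[i, ]
      emitMatch(v$start)
      span <- v$end - v$start
      if (v$type == "deletion") {
        cr <- v$end
      } else if (v$type == "insertion") {
        L <- nchar(v$seq)
        pieces[length(pieces) + 1L] <- v$seq
        addSeg(v$start, v$start, cd, cd + L, "+", FALSE)
        cd <- cd + L
      } else if (v$type == "inversion") {
        blk <- substr(refChar, v$start + 1L, v$end)
        pieces[length(pieces) + 1L] <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(blk)))
        addSeg(v$start, v$end, cd, cd + span, "-", TRUE)
        cd <- cd + span
        cr <- v$end
      } else if (v$type == "duplication") {
        blk <- substr(refChar, v$start + 1L, v$end)
        pieces[length(pieces) + 1L] <- blk
        addSeg(v$start, v$end, cd, cd + span, "+", TRUE)
        cd <- cd + span
        pieces[length(pieces) + 1L] <- blk
        addSeg(v$start, v$end, cd, cd + span, "+", TRUE)
        cd <- cd + span
        cr <- v$end
      } else if (v$type == "complex") {
        L <- nchar(v$seq)
        pieces[length(pieces) + 1L] <- v$seq
        addSeg(v$start, v$start, cd, cd + L, "+", FALSE)
        cd <- cd + L
        cr <- v$end
      } else stop("unknown variant type: ", v$type)
    }
    emitMatch(nchar(refChar))
    donorSeqs[k] <- paste(pieces, collapse = "")
    segList[[k]] <- do.call(rbind, segs)
  }
  donor <- Biostrings::DNAStringSet(donorSeqs)
  names(donor) <- names(reference)
  segments <- do.call(rbind, segList)
  rownames(segments) <- NULL
  list(donor = donor, segments = segments)
}

#' Map reference positions to donor coordinates
#'
#' Uses the liftover segment table to translate single reference positions to
#' donor positions. Positions inside duplicated spans map twice; positions
#' deleted from the donor map to nothing.
#'
#' @param segments liftover table from [applyVariants()].
#' @param scaffold scaffold id.
#' @param pos single 0-based reference position.
#' @return integer vector of donor positions (possibly empty or length > 1),
#'   with attribute \code{strand} giving each hit's segment strand.
#' @export
refToDonorPos <- function(segments, scaffold, pos) {
  s <- segments[segments$scaffold == scaffold & segments$mapped, , drop = FALSE]
  hit <- s[pos >= s$refStart & pos < s$refEnd, , drop = FALSE]
  if (!nrow(hit)) return(structure(integer(0), strand = character(0)))
  dp <- ifelse(hit$strand == "+",
               hit$donorStart + (pos - hit$refStart),
               hit$donorEnd - 1L - (pos - hit$refStart))
  structure(as.integer(dp), strand = hit$strand)
}
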