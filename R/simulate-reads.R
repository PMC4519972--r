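## Paired-end fragments are drawn from the donor genome and their reference
## "alignments" are produced by exact liftover through the variant segments:
## a read is placed on the reference via the segment containing its midpoint,
## so reads straddling a breakpoint behave like an aligner's primary placement
## and reads wholly inside donor-only sequence are unmapped.

#' Simulate aligned read pairs from the donor genome
#'
#' Fragments of Normal(insertMean, insertSd) length are drawn uniformly from
#' the donor; the two reads (first forward, second reverse, donor frame) are
#' lifted to reference coordinates through the variant segments. Pairs not
#' spanning a breakpoint are exactly concordant: their reference-frame span
#' equals the sampled fragment length and their orientation is
#' forward/reverse.
#'
#' @param sim output of [simulateParentalGenomes()].
#' @param config the \linkS4class{SimConfig}; supplies read length, insert
#'   distribution and coverage.
#' @param seed seed for the read layer; defaults to \code{config@seed + 1} so
#'   the genome and read streams are independent but jointly reproducible.
#' @return data.frame with one row per pair: \code{scaffold}, \code{pairId},
#'   \code{fragLen}, and per mate 0-based half-open reference coordinates
#'   \code{start1}, \code{end1}, \code{strand1}, \code{mapped1} (same for
#'   mate 2).
#' @export
simulateReadPairs <- function(sim, config = sim$config, seed = NULL) {
  if (is.null(seed)) seed <- config@seed + 1L
  set.seed(seed)
  R <- config@readLength
  out <- lapply(names(sim$donor), function(sc) {
    segs <- sim$segments[sim$segments$scaffold == sc, , drop = FALSE]
    Ld <- Biostrings::width(sim$donor[sc])
    nf <- round(config@coverage * Ld / (2 * R))
    if (nf == 0L) return(NULL)
    fl <- pmax(2L * R + 10L, round(rnorm(nf, config@insertMean,
                                         config@insertSd)))
    fl <- pmin(fl, Ld)
    st <- floor(runif(nf, 0, Ld - fl + 1))
    m1 <- liftReads(segs, st, R)
    m2 <- liftReads(segs, st + fl - R, R)
    data.frame(
      scaffold = sc, pairId = sprintf("%s_p%06d", sc, seq_len(nf)),
      fragLen = fl,
      start1 = m1$start, end1 = m1$end,
      strand1 = ifelse(m1$flip, "-", "+"), mapped1 = m1$mapped,
      start2 = m2$start, end2 = m2$end,
      strand2 = ifelse(m2$flip, "+", "-"), mapped2 = m2$mapped,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Vectorised midpoint liftover of reads of width R starting at donor
## positions rs. Returns reference start/end, whether the segment was
## inverted (flip) and whether the read maps at all.
liftReads <- function(segs, rs, R) {
  mid <- rs + R %/% 2L
  idx <- findInterval(mid, segs$donorStart)
  idx[idx < 1L] <- 1L
  mapped <- segs$mapped[idx]
  flip <- segs$strand[idx] == "-"
  off <- rs - segs$donorStart[idx]
  fwdStart <- segs$refStart[idx] + off
  invEnd <- segs$refEnd[idx] - off
  start <- ifelse(flip, invEnd - R, fwdStart)
  end <- start + R
  start[!mapped] <- NA_integer_
  end[!mapped] <- NA_integer_
  list(start = as.integer(start), end = as.integer(end),
       flip = flip, mapped = mapped)
}

#' Simulate haploid progeny genotypes by no-interference meiosis
#'
#' Crossovers form a Poisson process of rate 1 per Morgan along each linkage
#' group (no interference), so the recombination fraction between two markers
#' d cM apart follows Haldane's function, r = (1 - exp(-2d/100))/2. Groups
#' segregate independently. Heterokaryotic strains carry both nuclei and are
#' scored \code{"h"} at every marker; unreadable calls (\code{"-"}) are then
#' placed independently at \code{missingRate}.
#'
#' @param trueMap a \linkS4class{GeneticMap} giving marker positions in cM.
#' @param nProgeny number of single-spore isolates.
#' @param heterokaryonRate probability a strain is heterokaryotic.
#' @param missingRate per-call missing probability.
#' @param seed integer seed.
#' @return a \linkS4class{GenotypeMatrix}; \code{metadata$heterokaryons} holds
#'   the true heterokaryotic strain ids.
#' @examples
#' gm <- GeneticMap(data.frame(group = 1L, marker = c("M1", "M2"),
#'                             position = c(0, 10)))
#' g <- simulateMeiosis(gm, 20, seed = 1)
#' @export
simulateMeiosis <- function(trueMap, nProgeny, heterokaryonRate = 0,
                            missingRate = 0, seed = NULL) {
  stopifnot(is(trueMap, "GeneticMap"))
  nProgeny <- as.integer(nProgeny)
  if (is.na(nProgeny) || nProgeny < 0L) stop("nProgeny must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tb <- mapTable(trueMap)
  markers <- tb$marker
  mat <- matrix("-", nrow = nProgeny, ncol = length(markers),
                dimnames = list(if (nProgeny) sprintf("SSI%03d", seq_len(nProgeny)),
                                markers))
  if (nProgeny > 0L) {
    for (g in unique(tb$group)) {
      sub <- tb[tb$group == g, , drop = FALSE]
      m <- nrow(sub)
      alle <- matrix(0L, nProgeny, m)
      alle[, 1L] <- rbinom(nProgeny, 1L, 0.5)
      if (m > 1L) {
        r <- haldaneInv(diff(sub$position))
        for (k in 2L:m) {
          sw <- rbinom(nProgeny, 1L, r[k - 1L])
          alle[, k] <- (alle[, k - 1L] + sw) %% 2L
        }
      }
      mat[, sub$marker] <- ifelse(alle == 0L, "a", "b")
    }
    hets <- character(0)
    if (heterokaryonRate > 0) {
      isHet <- rbinom(nProgeny, 1L, heterokaryonRate) == 1L
      mat[isHet, ] <- "h"
      hets <- rownames(mat)[isHet]
    }
    if (missingRate > 0) {
      miss <- matrix(runif(length(mat)) < missingRate, nrow = nProgeny)
      mat[miss] <- "-"
    }
    return(GenotypeMatrix(mat, metadata = list(heterokaryons = hets)))
  }
  GenotypeMatrix(mat, metadata = list(heterokaryons = character(0)))
}
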