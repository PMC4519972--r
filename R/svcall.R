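## SV locus detection from discordant read-pair signatures.
##
## Signature table (leftmost mate first, reference frame):
##   +/-  (FR)  insert within mean +/- k*sd  -> concordant
##   +/-  (FR)  insert too large             -> del_like
##   +/-  (FR)  insert too small             -> ins_like
##   -/+  (RF, everted)                      -> dup_like (tandem duplication)
##   ++ or --   (same strand)                -> inv_like
##   one mate unmapped                       -> one_end_unmapped
## Overlapping clusters of conflicting implied types merge into one
## `complex` locus.

PAIR_SIGNATURES <- c("concordant", "del_like", "ins_like", "inv_like",
                     "dup_like", "one_end_unmapped", "unmapped")

#' Classify read pairs against an insert-size model
#'
#' Orients each pair in the reference frame (leftmost mate first) and assigns
#' a discordance signature. The reference-frame insert is the outer span of
#' the two mates; a forward/reverse pair is concordant when its insert lies
#' within \code{k} standard deviations of the model mean.
#'
#' @param pairs data.frame of aligned pairs as produced by
#'   [simulateReadPairs()] or [readAlignedPairs()].
#' @param model insert model list (\code{mean}, \code{sd}, \code{k}), e.g.
#'   from [fitInsertModel()].
#' @return the input with added columns \code{signature}, \code{insert}
#'   (outer reference span), and breakpoint bookkeeping columns \code{lo},
#'   \code{hi} (inner interval), \code{oL}, \code{oR} (outer interval).
#' @examples
#' p <- data.frame(scaffold = "s", pairId = "p1", fragLen = 505,
#'                 start1 = 0, end1 = 100, strand1 = "+", mapped1 = TRUE,
#'                 start2 = 405, end2 = 505, strand2 = "-", mapped2 = TRUE)
#' classifyPairs(p, list(mean = 505, sd = 30, k = 3))$signature
#' @export
classifyPairs <- function(pairs, model) {
  stopifnot(all(c("mean", "sd", "k") %in% names(model)))
  n <- nrow(pairs)
  sig <- rep("unmapped", n)
  both <- pairs$mapped1 & pairs$mapped2
  one <- xor(pairs$mapped1, pairs$mapped2)
  sig[one] <- "one_end_unmapped"

  ## orient: first = leftmost mate
  swap <- both & (pairs$start2 < pairs$start1 |
                  (pairs$start2 == pairs$start1 & pairs$end2 < pairs$end1))
  fS <- ifelse(swap, pairs$strand2, pairs$strand1)
  sS <- ifelse(swap, pairs$strand1, pairs$strand2)
  insert <- rep(NA_real_, n)
  insert[both] <- pmax(pairs$end1, pairs$end2)[both] -
    pmin(pairs$start1, pairs$start2)[both]

  lim <- model$k * model$sd
  fr <- both & fS == "+" & sS == "-"
  sig[fr & abs(insert - model$mean) <= lim] <- "concordant"
  sig[fr & insert > model$mean + lim] <- "del_like"
  sig[fr & insert < model$mean - lim] <- "ins_like"
  sig[both & fS == "-" & sS == "+"] <- "dup_like"
  sig[both & fS == sS] <- "inv_like"

  ## inner/outer intervals for clustering and breakpoint estimation
  lo <- hi <- oL <- oR <- rep(NA_real_, n)
  innerA <- pmin(pairs$end1, pairs$end2)
  innerB <- pmax(pairs$start1, pairs$start2)
  lo[both] <- pmin(innerA, innerB)[both]
  hi[both] <- pmax(innerA, innerB)[both]
  oL[both] <- pmin(pairs$start1, pairs$start2)[both]
  oR[both] <- pmax(pairs$end1, pairs$end2)[both]
  ## anchored mate of a half-mapped pair: expected mate window
  a1 <- one & pairs$mapped1
  a2 <- one & pairs$mapped2
  aS <- ifelse(a1, pairs$start1, pairs$start2)
  aE <- ifelse(a1, pairs$end1, pairs$end2)
  aStr <- ifelse(a1, pairs$strand1, pairs$strand2)
  plus <- one & aStr == "+"
  minus <- one & aStr == "-"
  lo[plus] <- aE[plus];  hi[plus] <- aS[plus] + model$mean
  hi[minus] <- aS[minus]; lo[minus] <- aE[minus] - model$mean
  oL[one] <- aS[one]; oR[one] <- aE[one]

  pairs$signature <- sig
  pairs$insert <- insert
  pairs$lo <- lo; pairs$hi <- hi; pairs$oL <- oL; pairs$oR <- oR
  pairs
}

#' Fit a robust insert-size model from concordantly oriented pairs
#'
#' Pre-filters to forward/reverse pairs with both mates mapped and estimates
#' location/scale by median and 1.4826 x MAD, so a moderate fraction of
#' SV-spanning (e.g. deletion-stretched) pairs does not bias the model.
#'
#' @param pairs aligned pair data.frame.
#' @param k concordance multiplier stored in the model (default 3).
#' @param minPairs minimum number of usable pairs (default 1000).
#' @return list with \code{mean}, \code{sd}, \code{k}.
#' @export
fitInsertModel <- function(pairs, k = 3, minPairs = 1000L) {
  both <- pairs$mapped1 & pairs$mapped2
  swap <- both & pairs$start2 < pairs$start1
  fS <- ifelse(swap, pairs$strand2, pairs$strand1)
  sS <- ifelse(swap, pairs$strand1, pairs$strand2)
  fr <- both & fS == "+" & sS == "-"
  ins <- (pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2))[fr]
  if (length(ins) < minPairs)
    stop("too few forward/reverse pairs to fit an insert model (",
         length(ins), " < ", minPairs, ")")
  list(mean = median(ins), sd = mad(ins), k = k)
}

## Chain intervals (sorted by lo) into clusters: a pair joins the open
## cluster when its interval comes within maxGap of the cluster's envelope.
clusterIntervals <- function(lo, hi, maxGap) {
  o <- order(lo, hi)
  cl <- integer(length(lo))
  cur <- 0L
  curMax <- -Inf
  for (i in o) {
    if (lo[i] > curMax + maxGap) {
      cur <- cur + 1L
      curMax <- hi[i]
    } else curMax <- max(curMax, hi[i])
    cl[i] <- cur
  }
  cl
}

## Breakpoint/type estimation for one same-signature cluster.
estimateLocus <- function(d, sig, model) {
  support <- nrow(d)
  lower <- FALSE
  if (sig == "del_like") {
    ## medians throughout: sporadic fragment-length tail pairs that join the
    ## cluster must not drag the breakpoint envelope
    len <- max(1, round(median(d$insert) - model$mean))
    ctr <- median((d$lo + d$hi) / 2)
    start <- round(ctr - len / 2); end <- start + len
    type <- "deletion"
  } else if (sig == "ins_like") {
    len <- max(1, round(model$mean - median(d$insert)))
    pos <- round(median((d$lo + d$hi) / 2))
    start <- pos; end <- pos
    type <- "insertion"
  } else if (sig == "inv_like") {
    pp <- d[d$strand1 == "+" & d$strand2 == "+", , drop = FALSE]
    mm <- d[d$strand1 == "-" & d$strand2 == "-", , drop = FALSE]
    start <- if (nrow(pp)) max(pp$lo) else min(d$lo)
    end <- if (nrow(mm)) min(mm$hi) else max(d$hi)
    if (end <= start) { start <- min(d$oL); end <- max(d$oR) }
    len <- end - start
    type <- "inversion"
  } else if (sig == "dup_like") {
    start <- min(d$oL); end <- max(d$oR)
    len <- end - start
    type <- "duplication"
  } else if (sig == "one_end_unmapped") {
    loA <- d$lo[is.finite(d$lo)]
    hiA <- d$hi[is.finite(d$hi)]
    pos <- round((max(loA) + min(hiA)) / 2)
    start <- pos; end <- pos
    len <- round(model$mean)   # only a lower bound is observable
    lower <- TRUE
    type <- "insertion"
  } else stop("unexpected signature: ", sig)
  data.frame(start = as.integer(max(0, start)), end = as.integer(max(0, end)),
             type = type, svLength = as.integer(len),
             support = as.integer(support), lowerBound = lower,
             stringsAsFactors = FALSE)
}

#' Call SV loci from classified read pairs
#'
#' Discordant pairs of the same signature whose breakpoint intervals fall
#' within \code{maxGap} of each other form clusters; clusters supported by
#' fewer than \code{minSupport} pairs are discarded ("more than 5 pairs" read
#' strictly: the default requires support >= 6). Surviving clusters become
#' loci typed by their signature, with length from the median implied size
#' change (deletion/insertion) or the estimated span (inversion/duplication).
#' Overlapping loci of conflicting types merge into one \code{complex} locus;
#' overlapping loci of the same type (e.g. an undersized-insert cluster plus
#' a one-end-unmapped cluster at the same insertion point) merge into one.
#'
#' @param pairs aligned pair data.frame.
#' @param model insert model (\code{mean}, \code{sd}, \code{k}).
#' @param minSupport minimum supporting pairs per cluster (default 6).
#' @param maxGap clustering slack in bp (default 100).
#' @return an \linkS4class{SVCallSet}, sorted by scaffold and start.
#' @export
callSVs <- function(pairs, model, minSupport = 6L, maxGap = 100L) {
  cls <- classifyPairs(pairs, model)
  disc <- cls[!cls$signature %in% c("concordant", "unmapped"), , drop = FALSE]
  cand <- list()
  for (sc in unique(disc$scaffold)) {
    dsc <- disc[disc$scaffold == sc, , drop = FALSE]
    for (sig in unique(dsc$signature)) {
      d <- dsc[dsc$signature == sig, , drop = FALSE]
      d <- d[is.finite(d$lo) & is.finite(d$hi), , drop = FALSE]
      if (!nrow(d)) next
      cl <- clusterIntervals(d$lo, d$hi, maxGap)
      for (ci in unique(cl)) {
        dd <- d[cl == ci, , drop = FALSE]
        if (nrow(dd) < minSupport) next
        loc <- estimateLocus(dd, sig, model)
        loc$scaffold <- sc
        loc$informative <- sig != "one_end_unmapped"
        cand[[length(cand) + 1L]] <- loc
      }
    }
  }
  loci <- mergeCandidateLoci(do.call(rbind, cand), maxGap = maxGap)
  newSVCallSet(loci, model)
}

## Merge candidate loci that overlap or fall within maxGap of each other;
## same type -> keep the informative estimate (summing support),
## conflicting types -> one complex locus.
mergeCandidateLoci <- function(cand, maxGap = 0L) {
  if (is.null(cand) || !nrow(cand)) return(cand)
  out <- list()
  for (sc in unique(cand$scaffold)) {
    d <- cand[cand$scaffold == sc, , drop = FALSE]
    ## inflate zero-width insertion points for the overlap test
    s <- d$start; e <- pmax(d$end, d$start + 1L)
    o <- order(s, e)
    d <- d[o, ]; s <- s[o]; e <- e[o]
    grp <- cumsum(c(1L, as.integer(s[-1] > cummax(e[-length(e)]) + maxGap)))
    for (g in unique(grp)) {
      dd <- d[grp == g, , drop = FALSE]
      if (nrow(dd) == 1L) { out[[length(out) + 1L]] <- dd; next }
      if (length(unique(dd$type)) == 1L) {
        keep <- dd[order(-dd$informative, -dd$support), ][1L, ]
        keep$support <- sum(dd$support)
        keep$lowerBound <- all(dd$lowerBound)
        out[[length(out) + 1L]] <- keep
      } else {
        st <- min(dd$start); en <- max(dd$end)
        out[[length(out) + 1L]] <- data.frame(
          start = st, end = en, type = "complex",
          svLength = as.integer(max(1L, en - st)),
          support = sum(dd$support), lowerBound = FALSE,
          scaffold = sc, informative = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Construct an SVCallSet from a 0-based locus table
#'
#' @param loci data.frame with columns \code{scaffold}, \code{start},
#'   \code{end} (0-based half-open), \code{type}, \code{svLength},
#'   \code{support} and optionally \code{lowerBound}.
#' @param insertModel insert-size model list (\code{mean}, \code{sd},
#'   \code{k}).
#' @return an \linkS4class{SVCallSet}.
#' @export
SVCallSet <- function(loci, insertModel = list(mean = NA_real_,
                                               sd = NA_real_, k = NA_real_)) {
  if (!is.null(loci) && nrow(loci) && is.null(loci$lowerBound))
    loci$lowerBound <- FALSE
  newSVCallSet(loci, insertModel)
}

## Build the S4 container from a 0-based candidate data.frame.
newSVCallSet <- function(loci, model) {
  if (is.null(loci) || !nrow(loci)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = character(0), svLength = integer(0), support = integer(0),
      lowerBound = logical(0))
    return(new("SVCallSet", loci = gr,
               insertModel = model[c("mean", "sd", "k")]))
  }
  loci <- loci[order(loci$scaffold, loci$start, loci$type), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = loci$scaffold,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    type = loci$type, svLength = loci$svLength, support = loci$support,
    lowerBound = loci$lowerBound)
  new("SVCallSet", loci = gr, insertModel = model[c("mean", "sd", "k")])
}

#' Per-class roll-up of an SV call set
#'
#' @param calls an \linkS4class{SVCallSet}.
#' @return see [svSummaryTable()]; additionally attribute
#'   \code{nScaffolds} = number of scaffolds carrying at least one locus.
#' @export
summarizeCalls <- function(calls) {
  df <- svCallsDf(calls)
  counts <- lengths_ <- setNames(integer(length(SV_TYPES)), SV_TYPES)
  if (nrow(df)) {
    tb <- table(factor(df$type, levels = SV_TYPES))
    counts[names(tb)] <- as.integer(tb)
    ln <- tapply(df$svLength, factor(df$type, levels = SV_TYPES), sum)
    lengths_[names(ln)] <- ifelse(is.na(ln), 0L, as.integer(ln))
  }
  out <- svSummaryTable(counts, lengths_)
  attr(out, "nScaffolds") <- length(unique(df$scaffold))
  out
}

#' SV class summary arithmetic
#'
#' Computes the per-class share and totals of an SV spectrum: rate =
#' 100 x class count / total count (2 decimals), totals are exact sums. An
#' empty spectrum reports zero rates.
#'
#' @param counts named integer vector of per-class locus counts.
#' @param lengths named numeric vector of per-class total lengths (bp), in
#'   the same order.
#' @return data.frame with one row per class plus a \code{total} row; columns
#'   \code{type}, \code{count}, \code{ratePct}, \code{lengthBp}.
#' @examples
#' svSummaryTable(c(insertion = 559, deletion = 371, duplication = 11,
#'                  inversion = 1, complex = 1),
#'                c(160549, 448893, 88643, 47707, 1682))
#' @export
svSummaryTable <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  total <- sum(counts)
  rate <- if (total > 0) round(100 * counts / total, 2) else
    rep(0, length(counts))
  data.frame(
    type = c(names(counts), "total"),
    count = c(as.integer(counts), as.integer(total)),
    ratePct = c(as.numeric(rate), if (total > 0) 100 else 0),
    lengthBp = c(as.numeric(lengths), sum(lengths)),
    stringsAsFactors = FALSE)
}
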