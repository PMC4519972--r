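## Co-dominant marker design from SV loci. Primer thermodynamics are out of
## scope: the outer edges of the two flanking windows stand in for primer
## sites, which preserves the amplicon-size arithmetic that makes a marker
## co-dominant (one band per parent, both bands in the heterokaryon).

MARKER_REJECT_REASONS <- c("length", "gap", "flank_out", "non_specific",
                           "no_unique_product", "indistinguishable")

#' Select SV loci eligible for marker design
#'
#' A locus is a marker candidate when its SV length lies in
#' \code{[minLen, maxLen]} (bounds inclusive), the locus plus \code{flank} bp
#' on each side fits on the scaffold, and that whole window is free of
#' N/gap characters.
#'
#' @param calls an \linkS4class{SVCallSet}.
#' @param reference \code{DNAStringSet} of the reference genome.
#' @param minLen,maxLen SV length window in bp (defaults 200 and 800).
#' @param flank flanking window width in bp (default 300).
#' @return data.frame with one row per locus: \code{id}, \code{scaffold},
#'   \code{start}, \code{end} (0-based half-open), \code{type},
#'   \code{svLength}, \code{status} (\code{candidate}/\code{rejected}),
#'   \code{reason}, \code{flank}.
#' @export
filterCandidateLoci <- function(calls, reference, minLen = 200L,
                                maxLen = 800L, flank = 300L) {
  df <- svCallsDf(calls)
  miss <- setdiff(unique(df$scaffold), names(reference))
  if (length(miss))
    stop("missing scaffold sequence: ", paste(miss, collapse = ", "))
  n <- nrow(df)
  df$id <- sprintf("SV%03d", seq_len(n))
  df$flank <- rep(as.integer(flank), n)
  df$status <- rep("candidate", n)
  df$reason <- rep(NA_character_, n)
  if (!n) return(df)
  scafLen <- setNames(Biostrings::width(reference), names(reference))
  for (i in seq_len(n)) {
    if (df$svLength[i] < minLen || df$svLength[i] > maxLen) {
      df$status[i] <- "rejected"; df$reason[i] <- "length"; next
    }
    ws <- df$start[i] - flank
    we <- df$end[i] + flank
    if (ws < 0L || we > scafLen[[df$scaffold[i]]]) {
      df$status[i] <- "rejected"; df$reason[i] <- "flank_out"; next
    }
    win <- Biostrings::subseq(reference[[df$scaffold[i]]], ws + 1L, we)
    if (Biostrings::countPattern("N", win, fixed = TRUE) > 0L ||
        Biostrings::countPattern("-", win, fixed = TRUE) > 0L) {
      df$status[i] <- "rejected"; df$reason[i] <- "gap"
    }
  }
  df
}

## Count genome-wide occurrences of a primer-tip sequence on both strands.
countTipHits <- function(tip, genome) {
  pat <- Biostrings::DNAString(tip)
  sum(Biostrings::vcountPattern(pat, genome)) +
    sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), genome))
}

#' Predict parental amplicon sizes for marker candidates
#'
#' The primer sites are the \code{tip} bp at the outer edges of the two
#' flanks. Size in the reference-role parent is flank + locus span + flank;
#' the donor-role size is the same interval lifted through the variant
#' segments. A candidate is rejected \code{non_specific} when either tip
#' occurs more than once (either strand) in either genome, and
#' \code{no_unique_product} when a tip does not lift to exactly one
#' forward-strand donor position (deleted, duplicated or inverted site).
#'
#' @param candidates data.frame from [filterCandidateLoci()].
#' @param reference,donor \code{DNAStringSet} genomes.
#' @param segments liftover table from [applyVariants()] /
#'   [simulateParentalGenomes()].
#' @param tip primer-site width in bp (default 20).
#' @return the input with \code{sizeA}, \code{sizeB} columns filled for
#'   surviving candidates and \code{status}/\code{reason} updated.
#' @export
predictAmplicons <- function(candidates, reference, donor, segments,
                             tip = 20L) {
  df <- candidates
  df$sizeA <- rep(NA_integer_, nrow(df))
  df$sizeB <- rep(NA_integer_, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$status[i] != "candidate") next
    f <- df$flank[i]
    ws <- df$start[i] - f
    we <- df$end[i] + f
    df$sizeA[i] <- we - ws
    sc <- df$scaffold[i]
    leftTip <- as.character(Biostrings::subseq(reference[[sc]], ws + 1L,
                                               ws + tip))
    rightTip <- as.character(Biostrings::subseq(reference[[sc]], we - tip + 1L,
                                                we))
    if (countTipHits(leftTip, reference) != 1L ||
        countTipHits(rightTip, reference) != 1L) {
      df$status[i] <- "rejected"; df$reason[i] <- "non_specific"; next
    }
    da <- refToDonorPos(segments, sc, ws)
    db <- refToDonorPos(segments, sc, we - 1L)
    okA <- length(da) == 1L && attr(da, "strand") == "+"
    okB <- length(db) == 1L && attr(db, "strand") == "+"
    if (!okA || !okB || db[1L] <= da[1L]) {
      df$status[i] <- "rejected"; df$reason[i] <- "no_unique_product"; next
    }
    df$sizeB[i] <- db[1L] + 1L - da[1L]
    if (countTipHits(leftTip, donor) != 1L ||
        countTipHits(rightTip, donor) != 1L) {
      df$status[i] <- "rejected"; df$reason[i] <- "non_specific"
    }
  }
  df
}

#' Score co-dominance of predicted amplicon pairs
#'
#' A marker is effective when its two parental products are resolvable on a
#' gel: \code{|sizeA - sizeB| >= max(absMin, relMin * min(sizeA, sizeB))}.
#' The heterokaryon profile is by construction the union of the two bands.
#'
#' @param sizeA,sizeB predicted amplicon sizes (bp), vectorised.
#' @param absMin absolute minimum size difference in bp (default 20).
#' @param relMin relative minimum difference (default 0.05 of the smaller
#'   product).
#' @return character vector: \code{"effective"} or \code{"indistinguishable"}.
#' @examples
#' scoreCodominance(1000, 600)
#' scoreCodominance(500, 520)   # 20 bp but < 5% of 500 -> indistinguishable
#' @export
scoreCodominance <- function(sizeA, sizeB, absMin = 20, relMin = 0.05) {
  need <- pmax(absMin, relMin * pmin(sizeA, sizeB))
  ifelse(abs(sizeA - sizeB) >= need, "effective", "indistinguishable")
}

#' Design co-dominant SV markers from a call set
#'
#' Composes [filterCandidateLoci()], [predictAmplicons()] and
#' [scoreCodominance()]: every locus ends up \code{effective},
#' \code{candidate} (never reached scoring) or \code{rejected} with a single
#' reason, so the attrition bookkeeping adds up exactly.
#'
#' @inheritParams filterCandidateLoci
#' @inheritParams predictAmplicons
#' @param absMin,relMin gel-resolvability thresholds, see
#'   [scoreCodominance()].
#' @return marker table data.frame (one row per SV locus).
#' @export
designMarkers <- function(calls, reference, donor, segments,
                          minLen = 200L, maxLen = 800L, flank = 300L,
                          tip = 20L, absMin = 20, relMin = 0.05) {
  df <- filterCandidateLoci(calls, reference, minLen = minLen,
                            maxLen = maxLen, flank = flank)
  df <- predictAmplicons(df, reference, donor, segments, tip = tip)
  cand <- df$status == "candidate"
  if (any(cand)) {
    verdict <- scoreCodominance(df$sizeA[cand], df$sizeB[cand],
                                absMin = absMin, relMin = relMin)
    df$status[cand] <- ifelse(verdict == "effective", "effective", "rejected")
    df$reason[cand][verdict != "effective"] <- "indistinguishable"
  }
  df
}

#' Extract the effective markers of a marker table
#'
#' @param markers data.frame from [designMarkers()].
#' @return the effective-row subset.
#' @export
effectiveMarkers <- function(markers) {
  markers[markers$status == "effective", , drop = FALSE]
}

#' Write marker flank regions as FASTA
#'
#' One record per non-rejected marker covering locus +/- flank on the
#' reference.
#'
#' @param markers marker table.
#' @param reference reference \code{DNAStringSet}.
#' @param path output FASTA path.
#' @export
writeMarkerFlanksFasta <- function(markers, reference, path) {
  keep <- markers[markers$status != "rejected" |
                    markers$reason %in% "indistinguishable", , drop = FALSE]
  if (!nrow(keep)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(keep)), function(i) {
    as.character(Biostrings::subseq(reference[[keep$scaffold[i]]],
                                    keep$start[i] - keep$flank[i] + 1L,
                                    keep$end[i] + keep$flank[i]))
  }, character(1)))
  names(seqs) <- sprintf("%s %s:%d-%d", keep$id, keep$scaffold,
                         keep$start - keep$flank, keep$end + keep$flank)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
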