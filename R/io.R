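## Interchange formats: FASTA via Biostrings, SAM/BAM via Rsamtools, plus
## plain TSV writers/readers for the pipeline's tabular stage outputs.

#' Write the simulated genomes as FASTA
#'
#' @param sim output of [simulateParentalGenomes()].
#' @param dir output directory (created if needed).
#' @return paths of the two FASTA files, invisibly.
#' @export
writeGenomesFasta <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pRef <- file.path(dir, "reference.fasta")
  pDon <- file.path(dir, "donor.fasta")
  Biostrings::writeXStringSet(sim$reference, pRef)
  Biostrings::writeXStringSet(sim$donor, pDon)
  invisible(c(reference = pRef, donor = pDon))
}

#' Write / read the simulator's truth variant table
#'
#' @param variants truth data.frame from [simulateParentalGenomes()].
#' @param path TSV path.
#' @export
writeVariantsTsv <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVariantsTsv
#' @export
readVariantsTsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$seq[is.na(d$seq)] <- ""
  d
}

#' Write / read aligned pairs as TSV
#'
#' The simulator's native tabular pair format: one row per pair with 0-based
#' half-open reference coordinates of both mates.
#'
#' @param pairs pair data.frame from [simulateReadPairs()].
#' @param path TSV path.
#' @export
writePairsTsv <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePairsTsv
#' @export
readPairsTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write aligned pairs as SAM
#'
#' Emits a minimal, valid SAM file (two records per pair) with correct FLAG
#' orientation bits, 1-based POS and signed TLEN. Sequences and qualities are
#' omitted (\code{*}): the simulator models alignment geometry, not base
#' calls.
#'
#' @param pairs pair data.frame from [simulateReadPairs()].
#' @param refLengths named vector of reference scaffold lengths.
#' @param path output SAM path.
#' @param readLength read length in bp (for the CIGAR).
#' @export
writePairsSam <- function(pairs, refLengths, path, readLength) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                   as.integer(refLengths)))
  rec <- function(qname, flag, rname, pos, cigar, rnext, pnext, tlen) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*",
            qname, flag, rname, pos, ifelse(bitwAnd(flag, 4L) > 0L, 0L, 60L),
            cigar, rnext, pnext, tlen)
  }
  flagOf <- function(selfMapped, selfRev, mateMapped, mateRev, first) {
    1L +
      ifelse(selfMapped, 0L, 4L) + ifelse(mateMapped, 0L, 8L) +
      ifelse(selfMapped & selfRev, 16L, 0L) +
      ifelse(mateMapped & mateRev, 32L, 0L) +
      ifelse(first, 64L, 128L)
  }
  p <- pairs
  tlen <- ifelse(p$mapped1 & p$mapped2,
                 pmax(p$end1, p$end2) - pmin(p$start1, p$start2), 0L)
  sgn1 <- ifelse(!p$mapped1 | !p$mapped2, 0L,
                 ifelse(p$start1 <= p$start2, tlen, -tlen))
  cig <- sprintf("%dM", readLength)
  l1 <- rec(p$pairId,
            flagOf(p$mapped1, p$strand1 == "-", p$mapped2, p$strand2 == "-",
                   TRUE),
            ifelse(p$mapped1, p$scaffold, "*"),
            ifelse(p$mapped1, p$start1 + 1L, 0L),
            ifelse(p$mapped1, cig, "*"),
            ifelse(p$mapped2, "=", "*"),
            ifelse(p$mapped2, p$start2 + 1L, 0L), sgn1)
  l2 <- rec(p$pairId,
            flagOf(p$mapped2, p$strand2 == "-", p$mapped1, p$strand1 == "-",
                   FALSE),
            ifelse(p$mapped2, p$scaffold, "*"),
            ifelse(p$mapped2, p$start2 + 1L, 0L),
            ifelse(p$mapped2, cig, "*"),
            ifelse(p$mapped1, "=", "*"),
            ifelse(p$mapped1, p$start1 + 1L, 0L), -sgn1)
  writeLines(c(hdr, l1, l2), path)
  invisible(path)
}

#' Read aligned pairs from SAM/BAM or the pair TSV
#'
#' Dispatches on the file extension: \code{.tsv} is read back directly;
#' \code{.bam} (or \code{.sam}, converted on the fly) is parsed with
#' Rsamtools and mate records are re-joined by query name. \code{fragLen} is
#' not recoverable from external alignments and is reported as \code{NA};
#' the SV caller does not use it.
#'
#' @param path input path (.tsv, .sam or .bam).
#' @return pair data.frame in the layout of [simulateReadPairs()].
#' @export
readAlignedPairs <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") return(readPairsTsv(path))
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    path <- bam
  } else if (ext != "bam") stop("unsupported pair format: .", ext)
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "qwidth")))[[1]]
  first <- bitwAnd(b$flag, 64L) > 0L
  mapped <- bitwAnd(b$flag, 4L) == 0L
  d <- data.frame(qname = b$qname, first = first, mapped = mapped,
                  rname = as.character(b$rname),
                  start = ifelse(mapped, b$pos - 1L, NA_integer_),
                  width = ifelse(is.na(b$qwidth), 0L, b$qwidth),
                  strand = ifelse(bitwAnd(b$flag, 16L) > 0L, "-", "+"),
                  stringsAsFactors = FALSE)
  d1 <- d[d$first, ]
  d2 <- d[!d$first, ]
  m <- match(d1$qname, d2$qname)
  d2 <- d2[m, ]
  sc <- ifelse(is.na(d1$rname), d2$rname, d1$rname)
  data.frame(scaffold = sc, pairId = d1$qname, fragLen = NA_integer_,
             start1 = d1$start, end1 = d1$start + d1$width,
             strand1 = d1$strand, mapped1 = d1$mapped,
             start2 = d2$start, end2 = d2$start + d2$width,
             strand2 = d2$strand, mapped2 = d2$mapped,
             stringsAsFactors = FALSE)
}

#' Write an SV call set as BED-like TSV
#'
#' Columns: scaffold, start, end (0-based half-open, BED convention), type,
#' svLength, support.
#'
#' @param calls an \linkS4class{SVCallSet}.
#' @param path output path.
#' @export
writeCallsBed <- function(calls, path) {
  df <- svCallsDf(calls)
  write.table(df[, c("scaffold", "start", "end", "type", "svLength",
                     "support")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the anchoring result as an AGP-like super-scaffold layout
#'
#' One line per scaffold, ordered within each linkage group by the group's
#' marker order: superScaffold (one per group), rank, scaffold, length,
#' orientation.
#'
#' @param anchoring result of [anchorScaffolds()].
#' @param map the \linkS4class{GeneticMap} (for within-group scaffold order).
#' @param markerInfo marker coordinates (for ordering scaffolds by their
#'   first marker's cM position).
#' @param path output path.
#' @export
writeSuperScaffolds <- function(anchoring, map, markerInfo, path) {
  tb <- merge(mapTable(map), markerInfo, by = "marker")
  an <- anchoring$anchors
  rows <- list()
  for (g in sort(unique(an$group))) {
    sg <- an[an$group == g, , drop = FALSE]
    firstCm <- vapply(sg$scaffold, function(s)
      min(tb$position[tb$scaffold == s & tb$group == g]), numeric(1))
    sg <- sg[order(firstCm), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      superScaffold = sprintf("LG%02d", g), rank = seq_len(nrow(sg)),
      scaffold = sg$scaffold, lengthBp = sg$lengthBp,
      orientation = sg$orientation, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
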