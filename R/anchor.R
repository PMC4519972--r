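## Scaffold anchoring: every marker has both a genetic position (cM) and a
## physical position on its source scaffold (bp), so scaffolds can be
## assigned to linkage groups, oriented, and screened for interleaving
## conflicts and recombination-rate outliers.

#' Anchor scaffolds to linkage groups
#'
#' Each scaffold joins the linkage group containing the majority of its
#' mapped markers (ties break to the lowest group id). Orientation is the
#' sign of the Spearman rank correlation between the markers' cM and bp
#' positions; scaffolds with fewer than two distinctly placed markers are
#' \code{undetermined}.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param markerInfo data.frame with columns \code{marker}, \code{scaffold},
#'   \code{bp} (physical position of the marker on its scaffold).
#' @param scaffoldLengths named vector of scaffold lengths in bp (e.g. from
#'   the assembly FASTA); lengths, not marker spans, enter the size totals.
#' @return list with \code{anchors} (data.frame: scaffold, lengthBp, group,
#'   nMarkers, orientation) and \code{perGroup} (data.frame: group,
#'   nScaffolds, anchoredBp).
#' @export
anchorScaffolds <- function(map, markerInfo, scaffoldLengths) {
  tb <- mapTable(map)
  mi <- merge(tb, markerInfo, by = "marker")
  if (nrow(mi) < nrow(tb)) {
    miss <- setdiff(tb$marker, markerInfo$marker)
    stop("marker(s) missing scaffold coordinates: ",
         paste(miss, collapse = ", "))
  }
  anchors <- do.call(rbind, lapply(split(mi, mi$scaffold), function(d) {
    votes <- table(d$group)
    grp <- min(as.integer(names(votes)[votes == max(votes)]))  # ties -> lowest id
    dg <- d[d$group == grp, , drop = FALSE]
    ori <- "undetermined"
    if (nrow(dg) >= 2L && length(unique(dg$bp)) > 1L &&
        length(unique(dg$position)) > 1L) {
      rho <- cor(dg$position, dg$bp, method = "spearman")
      if (!is.na(rho) && rho != 0) ori <- if (rho > 0) "+" else "-"
    }
    sc <- d$scaffold[1L]
    if (!sc %in% names(scaffoldLengths))
      stop("no length for scaffold ", sc)
    data.frame(scaffold = sc, lengthBp = as.numeric(scaffoldLengths[[sc]]),
               group = grp, nMarkers = nrow(dg), orientation = ori,
               stringsAsFactors = FALSE)
  }))
  rownames(anchors) <- NULL
  groups <- sort(unique(anchors$group))
  perGroup <- data.frame(
    group = groups,
    nScaffolds = vapply(groups, function(g) sum(anchors$group == g),
                        integer(1)),
    anchoredBp = vapply(groups, function(g)
      sum(anchors$lengthBp[anchors$group == g]), numeric(1)))
  list(anchors = anchors, perGroup = perGroup)
}

#' Detect scaffold interleaving conflicts on the map
#'
#' Reports every maximal run of consecutive markers from one scaffold that
#' sits strictly between two markers of a different, common scaffold within
#' one linkage group (the classic "foreign marker between two same-scaffold
#' neighbours" pattern), together with the cM gap between the flanking
#' markers.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param markerInfo data.frame with \code{marker}, \code{scaffold} columns.
#' @return data.frame: \code{group}, \code{scaffoldOuter},
#'   \code{scaffoldInner}, \code{innerMarkers}, \code{leftMarker},
#'   \code{rightMarker}, \code{gapCm}. Zero rows when all scaffolds are
#'   contiguous on the map.
#' @export
detectConflicts <- function(map, markerInfo) {
  tb <- mapTable(map)
  mi <- merge(tb, markerInfo[, c("marker", "scaffold")], by = "marker")
  mi <- mi[order(mi$group, mi$position, mi$marker), ]
  out <- list()
  for (g in unique(mi$group)) {
    d <- mi[mi$group == g, , drop = FALSE]
    sc <- d$scaffold
    n <- length(sc)
    if (n < 3L) next
    ## maximal single-scaffold runs
    runEnd <- c(which(sc[-1] != sc[-n]), n)
    runStart <- c(1L, head(runEnd, -1L) + 1L)
    for (k in seq_along(runStart)) {
      i <- runStart[k]; j <- runEnd[k]
      if (i == 1L || j == n) next
      if (sc[i - 1L] == sc[j + 1L] && sc[i - 1L] != sc[i]) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, scaffoldOuter = sc[i - 1L], scaffoldInner = sc[i],
          innerMarkers = paste(d$marker[i:j], collapse = ","),
          leftMarker = d$marker[i - 1L], rightMarker = d$marker[j + 1L],
          gapCm = d$position[j + 1L] - d$position[i - 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(group = integer(0), scaffoldOuter = character(0),
                      scaffoldInner = character(0),
                      innerMarkers = character(0), leftMarker = character(0),
                      rightMarker = character(0), gapCm = numeric(0)))
  do.call(rbind, out)
}

#' Genome-scale map statistics
#'
#' Coverage is 100 x anchored size / genome size; kb/cM is anchored size over
#' map length; the reduced scaffold count assumes each group's anchored
#' scaffolds merge into one super-scaffold: original - anchored + number of
#' groups holding at least one scaffold.
#'
#' @param mapLengthCm total map length in cM.
#' @param anchoredBp total size of anchored scaffolds in bp.
#' @param nAnchored number of anchored scaffolds.
#' @param nGroupsWithScaffolds number of groups holding >= 1 scaffold.
#' @param genomeSizeBp assembly size in bp.
#' @param originalScaffolds scaffold count of the draft assembly.
#' @return list: \code{mapLengthCm}, \code{anchoredKb}, \code{nAnchored},
#'   \code{coveragePct}, \code{kbPerCm}, \code{reducedScaffolds}.
#' @examples
#' genomeStats(411.601, 19647e3, 43, 10, 37.2e6, 302)
#' @export
genomeStats <- function(mapLengthCm, anchoredBp, nAnchored,
                        nGroupsWithScaffolds, genomeSizeBp,
                        originalScaffolds) {
  if (nAnchored > originalScaffolds)
    stop("anchored scaffolds exceed the assembly's scaffold count")
  list(mapLengthCm = mapLengthCm,
       anchoredKb = anchoredBp / 1e3,
       nAnchored = nAnchored,
       coveragePct = 100 * anchoredBp / genomeSizeBp,
       kbPerCm = (anchoredBp / 1e3) / mapLengthCm,
       reducedScaffolds = originalScaffolds - nAnchored +
         nGroupsWithScaffolds)
}

#' @describeIn genomeStats compute the statistics from a map and anchoring
#'   result.
#' @param map a \linkS4class{GeneticMap}.
#' @param anchoring result of [anchorScaffolds()].
#' @export
genomeStatsFromMap <- function(map, anchoring, genomeSizeBp,
                               originalScaffolds) {
  ms <- mapSummary(map)
  genomeStats(ms$totalLengthCm, sum(anchoring$anchors$lengthBp),
              nrow(anchoring$anchors), nrow(anchoring$perGroup),
              genomeSizeBp, originalScaffolds)
}

#' Scan marker intervals for recombination hotspots and coldspots
#'
#' Considers every pair of map-adjacent markers on the same scaffold, with a
#' genetic span (cM) and a physical span (bp, from the marker coordinates).
#' An interval is \code{hot} when its cM/kb rate reaches
#' \code{hotFactor} x the genome mean rate and \code{cold} when it falls to
#' \code{coldFactor} x the mean or below.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param markerInfo data.frame with \code{marker}, \code{scaffold},
#'   \code{bp}.
#' @param meanCmPerKb genome-average rate; by default the total map length
#'   divided by the total anchored size implied by \code{markerInfo} spans is
#'   not used -- supply e.g. \code{1/47.7} or the value from
#'   [genomeStats()].
#' @param hotFactor,coldFactor rate multipliers (defaults 3 and 1/3).
#' @return data.frame: \code{group}, \code{fromMarker}, \code{toMarker},
#'   \code{cm}, \code{kb}, \code{cmPerKb}, \code{ratio}, \code{label}.
#' @export
recombinationScan <- function(map, markerInfo, meanCmPerKb,
                              hotFactor = 3, coldFactor = 1 / 3) {
  tb <- mapTable(map)
  mi <- merge(tb, markerInfo, by = "marker")
  mi <- mi[order(mi$group, mi$position, mi$marker), ]
  out <- list()
  for (g in unique(mi$group)) {
    d <- mi[mi$group == g, , drop = FALSE]
    if (nrow(d) < 2L) next
    for (i in seq_len(nrow(d) - 1L)) {
      if (d$scaffold[i] != d$scaffold[i + 1L]) next
      cm <- d$position[i + 1L] - d$position[i]
      kb <- abs(d$bp[i + 1L] - d$bp[i]) / 1e3
      if (kb == 0) next
      rate <- cm / kb
      ratio <- rate / meanCmPerKb
      label <- if (ratio >= hotFactor) "hot" else
        if (ratio <= coldFactor) "cold" else "normal"
      out[[length(out) + 1L]] <- data.frame(
        group = g, fromMarker = d$marker[i], toMarker = d$marker[i + 1L],
        cm = cm, kb = kb, cmPerKb = rate, ratio = ratio, label = label,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = integer(0), fromMarker = character(0),
                      toMarker = character(0), cm = numeric(0),
                      kb = numeric(0), cmPerKb = numeric(0),
                      ratio = numeric(0), label = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count annotated genes on anchored scaffolds
#'
#' @param anchoring result of [anchorScaffolds()] (or any data.frame with a
#'   \code{scaffold} column in \code{$anchors}).
#' @param annotation a GFF3 file path or a \code{GRanges}; features with
#'   \code{type == "gene"} are counted.
#' @param validScaffolds optional character vector of known scaffold ids; an
#'   annotation naming other scaffolds is an error.
#' @return list: \code{nGenes} (on anchored scaffolds), \code{totalGenes},
#'   \code{fractionPct}.
#' @export
geneContent <- function(anchoring, annotation, validScaffolds = NULL) {
  gr <- if (is.character(annotation))
    rtracklayer::import(annotation, format = "gff3") else annotation
  if (length(gr)) gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  sc <- as.character(GenomicRanges::seqnames(gr))
  if (!is.null(validScaffolds)) {
    bad <- setdiff(unique(sc), validScaffolds)
    if (length(bad))
      stop("annotation scaffold id(s) not in the genome: ",
           paste(bad, collapse = ", "))
  }
  anchored <- unique(anchoring$anchors$scaffold)
  nGenes <- sum(sc %in% anchored)
  total <- length(gr)
  list(nGenes = nGenes, totalGenes = total,
       fractionPct = if (total > 0) 100 * nGenes / total else 0)
}
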