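## Genotype-matrix QC: heterokaryon screening, population filtering,
## segregation tests, and the TSV / MAPMAKER-raw interchange formats.

#' Classify strains as homokaryotic or heterokaryotic
#'
#' A strain showing the two-band code \code{"h"} at any screening marker is
#' heterokaryotic; a strain with \code{"-"} at every screening marker cannot
#' be determined; everything else is homokaryotic. The result is invariant to
#' strain and marker order.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param screeningMarkers marker ids used for screening (the wet-lab
#'   equivalent used three SCAR markers; any markers may serve).
#' @return list with character vectors \code{homokaryons},
#'   \code{heterokaryons}, \code{undetermined}.
#' @export
classifyStrains <- function(gm, screeningMarkers) {
  stopifnot(is(gm, "GenotypeMatrix"))
  unknown <- setdiff(screeningMarkers, markerNames(gm))
  if (length(unknown))
    stop("unknown screening marker id: ", paste(unknown, collapse = ", "))
  s <- scores(gm)[, screeningMarkers, drop = FALSE]
  isHet <- apply(s == "h", 1L, any)
  allMiss <- apply(s == "-", 1L, all)
  list(homokaryons = rownames(s)[!isHet & !allMiss],
       heterokaryons = rownames(s)[isHet],
       undetermined = rownames(s)[allMiss & !isHet])
}

#' Restrict a genotype matrix to the homokaryotic mapping population
#'
#' Drops heterokaryotic and undetermined strains. Any residual \code{"h"}
#' call in a retained strain is treated as a scoring error and coerced to
#' \code{"-"}; the number of coercions is reported as a warning and stored in
#' \code{metadata$coercedH}.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param screeningMarkers marker ids used to classify strains; default all
#'   markers (a strain is then heterokaryotic if it shows \code{"h"}
#'   anywhere).
#' @return the filtered \linkS4class{GenotypeMatrix}.
#' @export
filterPopulation <- function(gm, screeningMarkers = markerNames(gm)) {
  cls <- classifyStrains(gm, screeningMarkers)
  if (!length(cls$homokaryons))
    stop("no homokaryotic strains remain after filtering")
  s <- scores(gm)[cls$homokaryons, , drop = FALSE]
  nH <- sum(s == "h")
  if (nH > 0L) {
    warning(nH, " residual 'h' call(s) in homokaryotic strains coerced to '-'")
    s[s == "h"] <- "-"
  }
  md <- gm@metadata
  md$coercedH <- nH
  md$excluded <- list(heterokaryons = cls$heterokaryons,
                      undetermined = cls$undetermined)
  GenotypeMatrix(s, metadata = md)
}

#' Chi-square test of 1:1 segregation
#'
#' Tests each marker's a:b ratio against the 1:1 expectation of a haploid
#' single-spore population (1 df); missing and \code{"h"} calls are excluded.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param markers markers to test (default all).
#' @param minCalls minimum scored calls per marker (default 10).
#' @return data.frame: \code{marker}, \code{nA}, \code{nB}, \code{chisq},
#'   \code{p}.
#' @examples
#' m <- matrix(rep(c("a", "b"), each = 6), ncol = 1,
#'             dimnames = list(sprintf("S%02d", 1:12), "M1"))
#' segregationTest(GenotypeMatrix(m))
#' @export
segregationTest <- function(gm, markers = markerNames(gm), minCalls = 10L) {
  s <- scores(gm)[, markers, drop = FALSE]
  nA <- colSums(s == "a")
  nB <- colSums(s == "b")
  n <- nA + nB
  if (any(n < minCalls))
    stop("too few scored calls (< ", minCalls, ") for marker(s): ",
         paste(markers[n < minCalls], collapse = ", "))
  exp_ <- n / 2
  chisq <- (nA - exp_)^2 / exp_ + (nB - exp_)^2 / exp_
  data.frame(marker = markers, nA = as.integer(nA), nB = as.integer(nB),
             chisq = as.numeric(chisq),
             p = pchisq(as.numeric(chisq), df = 1, lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag markers with poor data quality
#'
#' Markers are flagged (never dropped automatically) when more than
#' \code{maxMissing} of their calls are missing or when their 1:1 segregation
#' p-value falls below \code{minSegP}.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param maxMissing maximum tolerated missing fraction (default 0.2).
#' @param minSegP segregation-distortion p-value floor (default 1e-3).
#' @return data.frame: \code{marker}, \code{missingFrac}, \code{segP},
#'   \code{flagged}.
#' @export
flagMarkers <- function(gm, maxMissing = 0.2, minSegP = 1e-3) {
  s <- scores(gm)
  missingFrac <- colMeans(s == "-")
  seg <- segregationTest(gm, minCalls = 1L)
  data.frame(marker = colnames(s), missingFrac = as.numeric(missingFrac),
             segP = seg$p,
             flagged = missingFrac > maxMissing | seg$p < minSegP,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write the genotype TSV format
#'
#' Tab-separated text: header row of marker ids, first column \code{strain},
#' cells in \code{\{a, b, h, -\}}. \code{readGenotypeMatrix()} and
#' \code{writeGenotypeMatrix()} are exact inverses.
#'
#' @param path file path.
#' @return \code{readGenotypeMatrix()}: a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeMatrix <- function(path) {
  d <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (colnames(d)[1] != "strain") stop("first column must be 'strain'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$strain
  GenotypeMatrix(m)
}

#' @rdname readGenotypeMatrix
#' @param gm a \linkS4class{GenotypeMatrix} to write.
#' @export
writeGenotypeMatrix <- function(gm, path) {
  s <- scores(gm)
  d <- data.frame(strain = rownames(s), s, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a genotype matrix in MAPMAKER/EXP raw format
#'
#' Codes the haploid a/b calls as backcross alleles (\code{A}/\code{H});
#' \code{"h"} and \code{"-"} become missing (\code{-}). The header declares a
#' backcross data type, which is the likelihood-equivalent encoding for a
#' haploid single-spore population.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @export
writeMapmakerRaw <- function(gm, path) {
  s <- scores(gm)
  code <- matrix("-", nrow(s), ncol(s))
  code[s == "a"] <- "A"
  code[s == "b"] <- "H"
  lines <- c("data type f2 backcross",
             sprintf("%d %d 0", nrow(s), ncol(s)),
             vapply(seq_len(ncol(s)), function(j)
               sprintf("*%s %s", colnames(s)[j],
                       paste(code[, j], collapse = "")), character(1)))
  writeLines(lines, path)
  invisible(path)
}
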