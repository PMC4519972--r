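## Central S4 classes. Validity enforces the structural invariants; all
## constructors are exported camelCase functions.

SV_TYPES <- c("insertion", "deletion", "duplication", "inversion", "complex")
GT_CODES <- c("a", "b", "h", "-")

#' Simulation configuration
#'
#' Parameters of the two-genome / read-pair / meiosis simulator. Defaults
#' emulate the mapping experiment the package is modelled on: a 505 bp
#' paired-end insert library, 235 single-spore isolates of which roughly 18\%
#' are heterokaryotic, and an SV spectrum dominated by sub-kilobase insertions
#' and deletions.
#'
#' @slot scaffoldLengths integer vector, scaffold lengths in bp.
#' @slot svCounts named integer vector over the five SV classes.
#' @slot svLengthRanges named list of \code{c(min, max)} bp per SV class.
#' @slot snpRate per-base substitution rate between the parents.
#' @slot readLength read length in bp.
#' @slot insertMean,insertSd fragment (insert) size distribution in bp.
#' @slot coverage haploid sequence coverage of the donor genome.
#' @slot nProgeny number of single-spore isolates to simulate.
#' @slot heterokaryonRate probability a progeny strain is heterokaryotic.
#' @slot missingRate probability an individual call is unreadable (\code{"-"}).
#' @slot minVariantGap minimum bp between planted variants (keeps their
#'   read-pair signatures and marker flanks from interfering).
#' @slot seed integer seed fixing all randomness.
#' @exportClass SimConfig
setClass("SimConfig", slots = c(
  scaffoldLengths  = "integer",
  svCounts         = "integer",
  svLengthRanges   = "list",
  snpRate          = "numeric",
  readLength       = "integer",
  insertMean       = "numeric",
  insertSd         = "numeric",
  coverage         = "numeric",
  nProgeny         = "integer",
  heterokaryonRate = "numeric",
  missingRate      = "numeric",
  minVariantGap    = "integer",
  seed             = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@scaffoldLengths) < 1L || any(object@scaffoldLengths <= 0L))
    msg <- c(msg, "scaffoldLengths must be positive")
  if (!identical(sort(names(object@svCounts)), sort(SV_TYPES)))
    msg <- c(msg, "svCounts must be named by the five SV classes")
  if (any(object@svCounts < 0L))
    msg <- c(msg, "svCounts must be non-negative")
  if (!all(SV_TYPES %in% names(object@svLengthRanges)))
    msg <- c(msg, "svLengthRanges must cover the five SV classes")
  if (object@insertMean <= 2 * object@readLength)
    msg <- c(msg, "insertMean must exceed twice the read length")
  if (object@insertSd <= 0) msg <- c(msg, "insertSd must be positive")
  if (object@snpRate < 0 || object@snpRate >= 1)
    msg <- c(msg, "snpRate must be in [0, 1)")
  if (object@coverage < 0) msg <- c(msg, "coverage must be non-negative")
  if (object@nProgeny < 0L) msg <- c(msg, "nProgeny must be non-negative")
  if (object@heterokaryonRate < 0 || object@heterokaryonRate > 1)
    msg <- c(msg, "heterokaryonRate must be in [0, 1]")
  if (object@missingRate < 0 || object@missingRate > 1)
    msg <- c(msg, "missingRate must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param scaffoldLengths scaffold lengths in bp.
#' @param svCounts named vector of planted SV counts per class
#'   (\code{insertion}, \code{deletion}, \code{duplication}, \code{inversion},
#'   \code{complex}); missing classes default to 0.
#' @param svLengthRanges named list of \code{c(min, max)} SV lengths in bp.
#' @param snpRate per-base SNP rate between the two parents.
#' @param readLength,insertMean,insertSd,coverage sequencing library model.
#' @param nProgeny,heterokaryonRate,missingRate mapping-population model.
#' @param minVariantGap minimum spacing between planted variants (bp).
#' @param seed integer seed; fixes all randomness downstream.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(scaffoldLengths = rep(50000L, 2), seed = 1)
#' @export
simConfig <- function(scaffoldLengths = rep(300000L, 10),
                      svCounts = c(insertion = 30, deletion = 30,
                                   duplication = 10, inversion = 8, complex = 2),
                      svLengthRanges = list(
                        insertion   = c(120L, 400L),
                        deletion    = c(200L, 1500L),
                        duplication = c(800L, 3000L),
                        inversion   = c(500L, 5000L),
                        complex     = c(300L, 800L)),
                      snpRate = 0.001,
                      readLength = 100L, insertMean = 505, insertSd = 50,
                      coverage = 30,
                      nProgeny = 235L, heterokaryonRate = 43 / 235,
                      missingRate = 0.02,
                      minVariantGap = 2000L, seed = 1L) {
  counts <- setNames(integer(length(SV_TYPES)), SV_TYPES)
  svCounts <- unlist(svCounts)
  if (length(svCounts)) {
    bad <- setdiff(names(svCounts), SV_TYPES)
    if (length(bad)) stop("unknown SV class in svCounts: ", paste(bad, collapse = ", "))
    counts[names(svCounts)] <- as.integer(svCounts)
  }
  new("SimConfig",
      scaffoldLengths = as.integer(scaffoldLengths),
      svCounts = counts,
      svLengthRanges = lapply(svLengthRanges, as.integer),
      snpRate = snpRate,
      readLength = as.integer(readLength),
      insertMean = insertMean, insertSd = insertSd,
      coverage = coverage,
      nProgeny = as.integer(nProgeny),
      heterokaryonRate = heterokaryonRate,
      missingRate = missingRate,
      minVariantGap = as.integer(minVariantGap),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", length(object@scaffoldLengths), "scaffolds,",
      sum(object@scaffoldLengths), "bp total\n")
  cat("  SVs:", paste(names(object@svCounts), object@svCounts,
                      sep = "=", collapse = " "), "\n")
  cat(sprintf("  library: %d bp reads, insert %g +/- %g bp, %gx coverage\n",
              object@readLength, object@insertMean, object@insertSd,
              object@coverage))
  cat(sprintf("  population: %d progeny, het rate %.3f, missing %.3f, seed %d\n",
              object@nProgeny, object@heterokaryonRate, object@missingRate,
              object@seed))
})

#' Set of called SV loci
#'
#' Container for SV loci detected between the reference-role and donor-role
#' strains. Loci live in a \code{GRanges} (1-based, as usual for that class;
#' zero-width ranges mark insertion points) with metadata columns
#' \code{type}, \code{svLength}, \code{support} and \code{lowerBound}.
#'
#' @slot loci \code{GRanges} of loci, sorted by scaffold and start.
#' @slot insertModel list with the insert-size model used (\code{mean},
#'   \code{sd}, \code{k}).
#' @exportClass SVCallSet
setClass("SVCallSet", slots = c(loci = "GRanges", insertModel = "list"))

setValidity("SVCallSet", function(object) {
  mc <- S4Vectors::mcols(object@loci)
  need <- c("type", "svLength", "support", "lowerBound")
  if (!all(need %in% colnames(mc)))
    return(paste("loci must carry metadata columns:", paste(need, collapse = ", ")))
  if (length(object@loci)) {
    if (!all(mc$type %in% SV_TYPES)) return("unknown SV type")
    if (any(mc$svLength <= 0)) return("svLength must be positive")
    if (any(mc$support < 1)) return("support must be >= 1")
  }
  TRUE
})

#' @rdname SVCallSet-class
#' @param x,object an \code{SVCallSet}
#' @export
setMethod("length", "SVCallSet", function(x) length(x@loci))

#' Accessors for SVCallSet
#' @rdname SVCallSet-class
#' @export
setGeneric("svLoci", function(x) standardGeneric("svLoci"))

#' @rdname SVCallSet-class
#' @export
setMethod("svLoci", "SVCallSet", function(x) x@loci)

#' @rdname SVCallSet-class
#' @export
setGeneric("insertModel", function(x) standardGeneric("insertModel"))

#' @rdname SVCallSet-class
#' @export
setMethod("insertModel", "SVCallSet", function(x) x@insertModel)

setMethod("show", "SVCallSet", function(object) {
  cat("SVCallSet with", length(object), "loci on",
      length(unique(as.character(GenomicRanges::seqnames(object@loci)))),
      "scaffolds\n")
  tab <- table(factor(S4Vectors::mcols(object@loci)$type, levels = SV_TYPES))
  cat(" ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  im <- object@insertModel
  if (length(im))
    cat(sprintf("  insert model: mean %.1f, sd %.1f, k %.1f\n",
                im$mean, im$sd, im$k))
})

#' Convert calls to a 0-based half-open data.frame
#'
#' @param x an \code{SVCallSet}.
#' @return data.frame with columns \code{scaffold}, \code{start}, \code{end}
#'   (0-based half-open), \code{type}, \code{svLength}, \code{support},
#'   \code{lowerBound}.
#' @export
svCallsDf <- function(x) {
  stopifnot(is(x, "SVCallSet"))
  gr <- x@loci
  data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    type = S4Vectors::mcols(gr)$type,
    svLength = S4Vectors::mcols(gr)$svLength,
    support = S4Vectors::mcols(gr)$support,
    lowerBound = S4Vectors::mcols(gr)$lowerBound,
    stringsAsFactors = FALSE)
}

#' Genotype score matrix
#'
#' Strains x markers character matrix over the banding alphabet:
#' \code{"a"} (reference-parent band), \code{"b"} (donor-parent band),
#' \code{"h"} (both bands, heterokaryon), \code{"-"} (unclear/missing).
#'
#' @slot scores character matrix, rownames = strain ids, colnames = marker ids.
#' @slot metadata list of free-form provenance (e.g. simulation truth).
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", slots = c(scores = "matrix", metadata = "list"))

setValidity("GenotypeMatrix", function(object) {
  s <- object@scores
  if (!is.character(s)) return("scores must be a character matrix")
  if (ncol(s) > 0 && (is.null(colnames(s)) || anyDuplicated(colnames(s))))
    return("marker ids (colnames) must be present and unique")
  if (nrow(s) > 0 && (is.null(rownames(s)) || anyDuplicated(rownames(s))))
    return("strain ids (rownames) must be present and unique")
  if (length(s) && !all(s %in% GT_CODES))
    return("genotype codes must be in {a, b, h, -}")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param scores character matrix of codes in \code{\{a, b, h, -\}} with strain
#'   rownames and marker colnames.
#' @param metadata optional list of provenance information.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(scores, metadata = list()) {
  new("GenotypeMatrix", scores = scores, metadata = metadata)
}

#' @describeIn GenotypeMatrix the raw character matrix
#' @param x,object a \code{GenotypeMatrix}
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname GenotypeMatrix
#' @export
setMethod("scores", "GenotypeMatrix", function(x) x@scores)

#' @describeIn GenotypeMatrix strain identifiers
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' @rdname GenotypeMatrix
#' @export
setMethod("strainNames", "GenotypeMatrix", function(x) rownames(x@scores))

#' @describeIn GenotypeMatrix marker identifiers
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname GenotypeMatrix
#' @export
setMethod("markerNames", "GenotypeMatrix", function(x) colnames(x@scores))

#' @rdname GenotypeMatrix
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@scores))

#' @rdname GenotypeMatrix
#' @param i,j,drop standard matrix subsetting arguments (drop is ignored).
#' @param ... unused
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  s <- x@scores[i, j, drop = FALSE]
  new("GenotypeMatrix", scores = s, metadata = x@metadata)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@scores), "strains x",
      ncol(object@scores), "markers\n")
  if (length(object@scores)) {
    tab <- table(factor(object@scores, levels = GT_CODES))
    tot <- sum(tab)
    cat("  codes:", paste(sprintf("%s=%.1f%%", names(tab), 100 * tab / tot),
                          collapse = " "), "\n")
  }
})

#' Genetic linkage map
#'
#' Ordered linkage groups with cumulative Kosambi positions, plus markers
#' that could not be linked to any group.
#'
#' @slot table data.frame with columns \code{group} (integer), \code{marker},
#'   \code{position} (cM, non-decreasing within groups).
#' @slot unlinked character vector of unlinked marker ids.
#' @slot metadata list (e.g. population size, parameters used).
#' @exportClass GeneticMap
setClass("GeneticMap", slots = c(table = "data.frame",
                                 unlinked = "character",
                                 metadata = "list"))

setValidity("GeneticMap", function(object) {
  tb <- object@table
  need <- c("group", "marker", "position")
  if (!all(need %in% colnames(tb)))
    return("table must have columns group, marker, position")
  if (nrow(tb)) {
    if (anyDuplicated(tb$marker)) return("marker ids must be unique")
    byg <- split(tb$position, tb$group)
    if (any(vapply(byg, function(p) any(diff(p) < -1e-9), logical(1))))
      return("positions must be non-decreasing within each group")
    if (any(intersect(tb$marker, object@unlinked) != ""))
      return("a marker cannot be both mapped and unlinked")
  }
  TRUE
})

#' Construct a GeneticMap
#'
#' @param table data.frame with columns \code{group}, \code{marker},
#'   \code{position} (cM).
#' @param unlinked character vector of unlinked markers.
#' @param metadata optional list.
#' @return A \linkS4class{GeneticMap}.
#' @examples
#' gm <- GeneticMap(data.frame(group = 1L, marker = c("M1", "M2"),
#'                             position = c(0, 12.5)))
#' @export
GeneticMap <- function(table, unlinked = character(), metadata = list()) {
  table <- table[order(table$group, table$position, table$marker), ,
                 drop = FALSE]
  rownames(table) <- NULL
  new("GeneticMap", table = table, unlinked = unlinked, metadata = metadata)
}

#' @describeIn GeneticMap the (group, marker, position) table
#' @param x,object a \code{GeneticMap}
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname GeneticMap
#' @export
setMethod("mapTable", "GeneticMap", function(x) x@table)

#' @describeIn GeneticMap unlinked marker ids
#' @export
setGeneric("unlinkedMarkers", function(x) standardGeneric("unlinkedMarkers"))

#' @rdname GeneticMap
#' @export
setMethod("unlinkedMarkers", "GeneticMap", function(x) x@unlinked)

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  ng <- length(unique(tb$group))
  cat("GeneticMap:", ng, "linkage groups,", nrow(tb), "markers,",
      length(object@unlinked), "unlinked\n")
  if (nrow(tb)) {
    len <- vapply(split(tb$position, tb$group), function(p) max(p) - min(p),
                  numeric(1))
    cat(sprintf("  total length %.3f cM (groups %s)\n", sum(len),
                paste(sprintf("%.1f", len), collapse = ", ")))
  }
})
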