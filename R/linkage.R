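## Linkage map construction: two-point recombination statistics, LOD
## grouping, greedy seriation with ripple refinement, Kosambi distances.
## Two-point analysis is fully determined for haploid co-dominant data, so
## every quantity here has a closed form that the tests exercise directly.

#' Kosambi and Haldane map functions
#'
#' \code{kosambi()} maps a recombination fraction to centiMorgans under
#' partial interference, d = 25 ln((1+2r)/(1-2r)); \code{kosambiInv()} is its
#' exact inverse, r = tanh(d/50)/2. \code{haldane()}/\code{haldaneInv()} are
#' the no-interference equivalents d = -50 ln(1-2r) and
#' r = (1 - exp(-d/50))/2.
#'
#' @param r recombination fraction in [0, 0.5); values at or above 0.5 map to
#'   \code{Inf} with a warning.
#' @param d map distance in cM.
#' @return numeric vector (cM or recombination fraction).
#' @examples
#' kosambi(0.25)        # 25 * log(3) ~ 27.465
#' kosambiInv(kosambi(0.1))
#' @export
kosambi <- function(r) {
  if (any(r < 0, na.rm = TRUE)) stop("r must be >= 0")
  bad <- r >= 0.5
  if (any(bad, na.rm = TRUE))
    warning("r >= 0.5 corresponds to infinite map distance")
  d <- 25 * log((1 + 2 * r) / (1 - 2 * r))
  d[bad] <- Inf
  d
}

#' @rdname kosambi
#' @export
kosambiInv <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0")
  tanh(d / 50) / 2
}

#' @rdname kosambi
#' @export
haldane <- function(r) {
  if (any(r < 0, na.rm = TRUE)) stop("r must be >= 0")
  bad <- r >= 0.5
  d <- -50 * log(1 - 2 * r)
  d[bad] <- Inf
  d
}

#' @rdname kosambi
#' @export
haldaneInv <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0")
  (1 - exp(-d / 50)) / 2
}

#' Two-point linkage statistics for a marker pair
#'
#' Over the strains scored \code{a} or \code{b} at both markers, counts
#' recombinants R (rows where the alleles differ), estimates r = R/n capped
#' at 0.5, and computes the LOD against free recombination:
#' \deqn{LOD = R \log_{10}(2\hat r) + (n-R) \log_{10}(2(1-\hat r))}
#' with LOD = n log10(2) when R = 0. The statistic is symmetric under pair
#' swap and under a global a/b relabelling of either marker.
#'
#' @param colI,colJ character vectors of genotype codes for the two markers.
#' @return list: \code{n}, \code{R}, \code{rf}, \code{lod}.
#' @export
twoPoint <- function(colI, colJ) {
  ok <- colI %in% c("a", "b") & colJ %in% c("a", "b")
  n <- sum(ok)
  if (n == 0L) stop("no informative strains for this marker pair")
  R <- sum(colI[ok] != colJ[ok])
  rf <- min(R / n, 0.5)
  lod <- if (R == 0L) n * log10(2) else
    R * log10(2 * rf) + (n - R) * log10(2 * (1 - rf))
  list(n = n, R = as.integer(R), rf = rf, lod = lod)
}

#' All-pairs two-point table
#'
#' Vectorised computation of informative counts, recombinant counts,
#' recombination fractions and LOD scores for every marker pair.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (homokaryon-filtered).
#' @return list of marker x marker matrices \code{n}, \code{R}, \code{rf},
#'   \code{lod} (diagonal: rf 0, lod n log10 2).
#' @export
twoPointTable <- function(gm) {
  s <- scores(gm)
  X <- matrix(NA_real_, nrow(s), ncol(s), dimnames = dimnames(s))
  X[s == "a"] <- 0
  X[s == "b"] <- 1
  M <- !is.na(X)
  A <- X; A[!M] <- 0
  Mn <- M * 1
  n <- crossprod(Mn)
  eq <- crossprod(A) + crossprod(Mn - A)
  R <- n - eq
  rf <- ifelse(n > 0, pmin(R / n, 0.5), NA_real_)
  lod <- matrix(0, ncol(s), ncol(s), dimnames = dimnames(n))
  pos <- n > 0
  lod[pos] <- ifelse(R[pos] == 0, n[pos] * log10(2),
                     R[pos] * log10(pmax(2 * rf[pos], .Machine$double.xmin)) +
                       (n[pos] - R[pos]) * log10(2 * (1 - rf[pos])))
  list(n = n, R = R, rf = rf, lod = lod)
}

#' Partition markers into linkage groups
#'
#' Builds a graph with an edge for every marker pair reaching
#' \code{lodThreshold} (and, optionally, whose recombination fraction does
#' not exceed \code{maxRf}) and takes connected components. Components of
#' size one are reported as unlinked. Raising the threshold only refines the
#' partition.
#'
#' The \code{maxRf} co-requirement is off by default (\code{0.5}); with many
#' markers and large populations it guards against sporadic spurious linkage
#' between chromosomes (see the methods vignette).
#'
#' @param tp two-point table from [twoPointTable()].
#' @param lodThreshold LOD threshold (default 3.0).
#' @param maxRf maximum recombination fraction for linkage (default 0.5 =
#'   disabled).
#' @return list: \code{groups} (list of character vectors, ordered by
#'   decreasing size) and \code{unlinked} (character vector).
#' @export
groupMarkers <- function(tp, lodThreshold = 3.0, maxRf = 0.5) {
  markers <- colnames(tp$lod)
  adj <- tp$lod >= lodThreshold & tp$rf <= maxRf
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  byComp <- split(markers, comp$membership)
  sizes <- lengths(byComp)
  groups <- byComp[sizes >= 2L]
  groups <- groups[order(-lengths(groups), vapply(groups, min, character(1)))]
  names(groups) <- NULL
  list(groups = lapply(groups, unname),
       unlinked = sort(as.character(unlist(byComp[sizes == 1L],
                                           use.names = FALSE))))
}

## Sum of adjacent recombination fractions: the seriation objective.
sarf <- function(ord, rf) {
  if (length(ord) < 2L) return(0)
  sum(rf[cbind(ord[-length(ord)], ord[-1L])])
}

#' Order the markers of one linkage group
#'
#' Seriation by the classic framework-and-try strategy: a framework order is
#' either supplied (e.g. markers with known physical positions) or seeded
#' from the most confidently linked triple; the remaining markers are then
#' inserted one at a time, each at the slot minimising the sum of adjacent
#' recombination fractions; a window-3 permutation pass ("ripple") runs until
#' no improvement. The returned order is canonicalised so the first marker id
#' sorts before the last (an order and its reversal are equivalent).
#'
#' @param markers character vector of the group's marker ids (>= 2).
#' @param tp two-point table from [twoPointTable()].
#' @param framework optional character vector giving a known relative order
#'   of a subset of \code{markers}.
#' @return character vector: the ordered markers.
#' @export
orderGroup <- function(markers, tp, framework = NULL) {
  if (length(markers) < 2L) stop("a linkage group needs at least 2 markers")
  rf <- tp$rf[markers, markers, drop = FALSE]
  lod <- tp$lod[markers, markers, drop = FALSE]
  if (length(markers) == 2L) return(canonicalOrder(sort(markers)))

  if (!is.null(framework)) {
    ord <- intersect(framework, markers)
    if (length(ord) < 2L) ord <- NULL
  } else ord <- NULL
  if (is.null(ord)) {
    ## seed: best-LOD pair plus its strongest partner, ordered exhaustively
    l2 <- lod; diag(l2) <- -Inf
    ij <- which(l2 == max(l2), arr.ind = TRUE)[1L, ]
    seed <- markers[ij]
    if (length(markers) > 2L) {
      rest <- setdiff(markers, seed)
      third <- rest[which.max(pmax(lod[rest, seed[1]], lod[rest, seed[2]]))]
      seed <- c(seed, third)
      perms <- list(seed, seed[c(1, 3, 2)], seed[c(2, 1, 3)])
      seed <- perms[[which.min(vapply(perms, sarf, numeric(1), rf = rf))]]
    }
    ord <- seed
  }
  remaining <- setdiff(markers, ord)
  if (length(remaining)) {
    ## place strongly linked markers first
    strength <- apply(lod[remaining, ord, drop = FALSE], 1L, max)
    remaining <- remaining[order(-strength, remaining)]
    for (m in remaining) {
      cands <- lapply(seq_len(length(ord) + 1L), function(k)
        append(ord, m, after = k - 1L))
      obj <- vapply(cands, sarf, numeric(1), rf = rf)
      ord <- cands[[which.min(obj)]]
    }
  }
  ord <- ripple(ord, rf, window = 3L)
  canonicalOrder(ord)
}

## Window-w permutation polishing until no improvement.
ripple <- function(ord, rf, window = 3L) {
  if (length(ord) <= window) {
    perms <- permutationsOf(length(ord))
    objs <- apply(perms, 1L, function(p) sarf(ord[p], rf))
    return(ord[perms[which.min(objs), ]])
  }
  wperms <- permutationsOf(window)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(length(ord) - window + 1L)) {
      idx <- i:(i + window - 1L)
      best <- sarf(ord, rf)
      for (p in seq_len(nrow(wperms))) {
        cand <- ord
        cand[idx] <- ord[idx][wperms[p, ]]
        o <- sarf(cand, rf)
        if (o < best - 1e-12) {
          ord <- cand; best <- o; improved <- TRUE
        }
      }
    }
  }
  ord
}

## All permutations of 1..n (n small), one per row.
permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutationsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

canonicalOrder <- function(ord) {
  if (ord[length(ord)] < ord[1L]) rev(ord) else ord
}

#' Build a genetic map from a filtered genotype matrix
#'
#' Composes the full chain: two-point table, LOD grouping, per-group
#' ordering, Kosambi distances between adjacent markers, cumulative
#' positions. Groups are numbered by decreasing marker count, then decreasing
#' length.
#'
#' @param gm homokaryon-filtered \linkS4class{GenotypeMatrix}.
#' @param lodThreshold LOD grouping threshold (default 3.0).
#' @param maxRf optional recombination-fraction co-requirement for linkage
#'   (default 0.5 = disabled); see [groupMarkers()].
#' @param frameworks optional list of framework marker orders passed to
#'   [orderGroup()] (each is matched to the group containing its markers).
#' @return a \linkS4class{GeneticMap}; \code{metadata} records the population
#'   size and parameters.
#' @export
buildMap <- function(gm, lodThreshold = 3.0, maxRf = 0.5, frameworks = NULL) {
  tp <- twoPointTable(gm)
  grp <- groupMarkers(tp, lodThreshold = lodThreshold, maxRf = maxRf)
  rows <- list()
  info <- list()
  for (g in grp$groups) {
    fw <- NULL
    if (!is.null(frameworks)) {
      hit <- vapply(frameworks, function(f) length(intersect(f, g)) >= 2L,
                    logical(1))
      if (any(hit)) fw <- frameworks[[which(hit)[1L]]]
    }
    ord <- orderGroup(g, tp, framework = fw)
    adjRf <- tp$rf[cbind(ord[-length(ord)], ord[-1L])]
    pos <- cumsum(c(0, kosambi(pmin(adjRf, 0.4999))))
    info[[length(info) + 1L]] <- list(markers = ord, pos = pos)
  }
  ## group numbering: descending marker count, then descending length
  if (length(info)) {
    nm <- vapply(info, function(x) length(x$markers), integer(1))
    ln <- vapply(info, function(x) max(x$pos), numeric(1))
    o <- order(-nm, -ln)
    info <- info[o]
    rows <- lapply(seq_along(info), function(i)
      data.frame(group = i, marker = info[[i]]$markers,
                 position = info[[i]]$pos, stringsAsFactors = FALSE))
  }
  tb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = integer(0), marker = character(0),
               position = numeric(0))
  GeneticMap(tb, unlinked = grp$unlinked,
             metadata = list(n = nrow(scores(gm)),
                             lodThreshold = lodThreshold, maxRf = maxRf))
}

#' Per-group and overall map summary
#'
#' Mirrors the usual linkage-group summary table: per group the map length
#' (GD, cM), marker count and average marker spacing (GD divided by the
#' marker count); plus a total row. The overall mean spacing is total length
#' divided by total marker count (3 decimals).
#'
#' @param map a \linkS4class{GeneticMap}.
#' @return list with \code{perGroup} (data.frame: group, lengthCm, nMarkers,
#'   avgSpacing), \code{totalLengthCm}, \code{totalMarkers},
#'   \code{meanSpacingCm}.
#' @export
mapSummary <- function(map) {
  tb <- mapTable(map)
  groups <- sort(unique(tb$group))
  len <- vapply(groups, function(g) {
    p <- tb$position[tb$group == g]; max(p) - min(p)
  }, numeric(1))
  nm <- vapply(groups, function(g) sum(tb$group == g), integer(1))
  per <- data.frame(group = groups, lengthCm = len, nMarkers = nm,
                    avgSpacing = round(len / nm, 2))
  list(perGroup = per,
       totalLengthCm = sum(len),
       totalMarkers = sum(nm),
       meanSpacingCm = round(sum(len) / sum(nm), 3))
}
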