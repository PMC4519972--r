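## Independent oracles and small fixture builders used across the suite.

## Independent re-implementation of variant application working on base
## character vectors; deliberately shares no code with applyVariants().
oracleApplyVariants <- function(reference, variants, snps = NULL) {
  out <- lapply(names(reference), function(sc) {
    ch <- strsplit(as.character(reference[[sc]]), "")[[1]]
    if (!is.null(snps)) {
      sn <- snps[snps$scaffold == sc, , drop = FALSE]
      if (nrow(sn)) ch[sn$pos + 1L] <- sn$alt
    }
    vs <- variants[variants$scaffold == sc, , drop = FALSE]
    vs <- vs[order(-vs$start), , drop = FALSE]   # apply right-to-left
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (i in seq_len(nrow(vs))) {
      v <- vs[i, ]
      before <- if (v$start > 0) ch[1:v$start] else character(0)
      after <- if (v$end < length(ch)) ch[(v$end + 1L):length(ch)] else character(0)
      block <- if (v$end > v$start) ch[(v$start + 1L):v$end] else character(0)
      mid <- switch(v$type,
        deletion = character(0),
        insertion = strsplit(v$seq, "")[[1]],
        duplication = c(block, block),
        inversion = rev(unname(comp[block])),
        complex = strsplit(v$seq, "")[[1]])
      ch <- c(before, mid, after)
    }
    paste(ch, collapse = "")
  })
  names(out) <- names(reference)
  out
}

## Exhaustive minimum of the sum-of-adjacent-rf ordering objective.
bruteForceSarf <- function(markers, rf) {
  best <- Inf
  recurse <- function(prefix, rest, obj) {
    if (obj >= best) return()
    if (!length(rest)) { best <<- min(best, obj); return() }
    for (m in rest) {
      add <- if (length(prefix)) rf[prefix[length(prefix)], m] else 0
      recurse(c(prefix, m), setdiff(rest, m), obj + add)
    }
  }
  recurse(character(0), markers, 0)
  best
}

## Objective of a specific order (matches the package's definition).
orderObjective <- function(ord, rf) {
  if (length(ord) < 2) return(0)
  sum(rf[cbind(ord[-length(ord)], ord[-1])])
}

## GenotypeMatrix from per-strain code strings, e.g. c(S1 = "ab-h").
gtFromStrings <- function(rows, markers = NULL) {
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  if (is.null(markers)) markers <- sprintf("M%02d", seq_len(ncol(m)))
  colnames(m) <- markers
  GenotypeMatrix(m)
}

## Small well-separated SV scenario used by caller tests.
svTestConfig <- function(seed) {
  simConfig(
    scaffoldLengths = rep(60000L, 3),
    svCounts = c(deletion = 4, insertion = 4, duplication = 2, inversion = 2),
    svLengthRanges = list(insertion = c(200L, 280L), deletion = c(250L, 700L),
                          duplication = c(800L, 1500L),
                          inversion = c(400L, 2000L), complex = c(300L, 500L)),
    snpRate = 0.001, coverage = 30, insertSd = 50, seed = seed)
}

## Match calls against a truth table: a call matches a true variant when the
## types agree and the called start lies within tol bp of the true locus.
matchCalls <- function(calls, variants, tol) {
  df <- svCallsDf(calls)
  hits <- logical(nrow(variants))
  matched <- logical(nrow(df))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    j <- which(!matched & df$scaffold == v$scaffold & df$type == v$type &
                 abs(df$start - v$start) <= tol)
    if (length(j)) { hits[i] <- TRUE; matched[j[1]] <- TRUE }
  }
  list(recall = mean(hits), precision = mean(matched),
       nCalls = nrow(df), nTrue = nrow(variants))
}
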