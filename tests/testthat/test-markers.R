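## Controlled two-genome scenario: one deletion, one insertion, one
## inversion, one tandem duplication at known coordinates.
markerScenario <- function(seed = 41) {
  set.seed(seed)
  ref <- Biostrings::DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), 40000, TRUE), collapse = ""), "s1"))
  vars <- data.frame(
    scaffold = "s1",
    start = c(5000L, 12000L, 20000L, 30000L),
    end = c(5400L, 12000L, 20400L, 30900L),
    type = c("deletion", "insertion", "inversion", "duplication"),
    length = c(400L, 250L, 400L, 900L),
    seq = c("", paste(sample(c("A", "C", "G", "T"), 250, TRUE),
                      collapse = ""), "", ""),
    stringsAsFactors = FALSE)
  ad <- applyVariants(ref, vars)
  list(ref = ref, donor = ad$donor, segments = ad$segments, vars = vars)
}

lociFromVars <- function(vars) {
  data.frame(scaffold = vars$scaffold, start = vars$start, end = vars$end,
             type = vars$type, svLength = vars$length,
             support = 10L, stringsAsFactors = FALSE)
}

test_that("locus selection applies the inclusive length window and flank rules", {
  sc <- markerScenario()
  loci <- data.frame(scaffold = "s1",
                     start = c(5000, 9000, 13000, 17000, 39900),
                     end = c(5199, 9200, 13800, 17801, 39950),
                     type = "deletion",
                     svLength = c(199L, 200L, 800L, 801L, 50L),
                     support = 10L, stringsAsFactors = FALSE)
  calls <- SVCallSet(loci)
  df <- filterCandidateLoci(calls, sc$ref)
  expect_equal(df$status,
               c("rejected", "candidate", "candidate", "rejected", "rejected"))
  expect_equal(df$reason, c("length", NA, NA, "length", "length"))
  nearEnd <- SVCallSet(data.frame(scaffold = "s1", start = 39650, end = 39900,
                                  type = "deletion", svLength = 250L,
                                  support = 10L))
  expect_equal(filterCandidateLoci(nearEnd, sc$ref)$reason, "flank_out")
})

test_that("an N inside the flank window rejects the locus as gapped", {
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  substr(base, 2100, 2100) <- "N"   # inside the left flank of the locus below
  ref <- Biostrings::DNAStringSet(setNames(base, "s1"))
  calls <- SVCallSet(data.frame(scaffold = "s1", start = 2300, end = 2600,
                                type = "deletion", svLength = 300L,
                                support = 10L))
  df <- filterCandidateLoci(calls, ref)
  expect_equal(df$reason, "gap")
})

test_that("amplicon sizes follow the liftover arithmetic", {
  sc <- markerScenario()
  calls <- SVCallSet(lociFromVars(sc$vars))
  mk <- predictAmplicons(filterCandidateLoci(calls, sc$ref, maxLen = 1000L),
                         sc$ref, sc$donor, sc$segments)
  mk <- mk[order(mk$start), ]
  ## deletion: 300 + 400 + 300 on the reference, 400 bp shorter in the donor
  expect_equal(mk$sizeA[1], 1000L)
  expect_equal(mk$sizeB[1], 600L)
  ## insertion point: 600 bp reference product gains the 250 bp insert
  expect_equal(mk$sizeA[2], 600L)
  expect_equal(mk$sizeB[2], 850L)
  ## inversion conserves length -> equal products
  expect_equal(mk$sizeA[3], 1000L)
  expect_equal(mk$sizeB[3], mk$sizeA[3])
  ## tandem duplication: donor product gains one copy
  expect_equal(mk$sizeA[4], 1500L)
  expect_equal(mk$sizeB[4], 2400L)
})

test_that("a primer site inside a duplicated span is not unique in the donor", {
  sc <- markerScenario()
  ## locus wholly inside the duplicated region: both tips map twice
  calls <- SVCallSet(data.frame(scaffold = "s1", start = 30400, end = 30700,
                                type = "deletion", svLength = 300L,
                                support = 10L))
  mk <- predictAmplicons(filterCandidateLoci(calls, sc$ref), sc$ref,
                         sc$donor, sc$segments)
  expect_equal(mk$status, "rejected")
  expect_true(mk$reason %in% c("no_unique_product", "non_specific"))
})

test_that("co-dominance scoring uses the larger of the absolute and relative bounds", {
  expect_equal(scoreCodominance(1000, 600), "effective")
  expect_equal(scoreCodominance(1000, 1000), "indistinguishable")
  ## at size 500 the 5% relative bound (25 bp) dominates the 20 bp absolute
  deltas <- 0:100
  verdicts <- scoreCodominance(rep(500, 101), 500 + deltas)
  expect_equal(verdicts == "effective", deltas >= 25)
  ## at size 200 the absolute bound dominates
  expect_equal(scoreCodominance(200, 215), "indistinguishable")
  expect_equal(scoreCodominance(200, 220), "effective")
})

test_that("marker attrition bookkeeping partitions all loci and bands behave co-dominantly", {
  sc <- markerScenario()
  mk <- designMarkers(SVCallSet(lociFromVars(sc$vars)), sc$ref, sc$donor,
                      sc$segments, maxLen = 1000L)
  expect_equal(nrow(mk), 4L)
  expect_true(all(mk$status %in% c("effective", "rejected")))
  expect_true(all(is.na(mk$reason) == (mk$status == "effective")))
  eff <- effectiveMarkers(mk)
  ## the inversion is rejected as non-co-dominant by size; the rest survive
  expect_equal(sort(eff$type), c("deletion", "duplication", "insertion"))
  ## Fig-style band model: parent A one band, parent B a different band,
  ## heterokaryon both
  expect_true(all(eff$sizeA != eff$sizeB))
  bandsHet <- Map(function(a, b) sort(c(a, b)), eff$sizeA, eff$sizeB)
  expect_true(all(lengths(bandsHet) == 2L))
})

test_that("marker design on a full simulation recovers true size differences", {
  cfg <- svTestConfig(37)
  sim <- simulateParentalGenomes(cfg)
  pairs <- simulateReadPairs(sim, cfg)
  model <- fitInsertModel(pairs)
  calls <- callSVs(pairs, model)
  mk <- designMarkers(calls, sim$reference, sim$donor, sim$segments)
  eff <- effectiveMarkers(mk)
  expect_gt(nrow(eff), 0L)
  for (i in seq_len(nrow(eff))) {
    v <- sim$variants[sim$variants$scaffold == eff$scaffold[i] &
                        abs(sim$variants$start - eff$start[i]) <= 505, ]
    expect_equal(nrow(v), 1L)
    expected <- switch(v$type,
                       deletion = -v$length, insertion = v$length,
                       duplication = v$length, 0L)
    expect_equal(eff$sizeB[i] - eff$sizeA[i], expected)
  }
})
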