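test_that("zero-variant, zero-SNP config reproduces the reference exactly", {
  cfg <- simConfig(scaffoldLengths = c(8000L, 5000L), svCounts = c(),
                   snpRate = 0, coverage = 5, seed = 3)
  sim <- simulateParentalGenomes(cfg)
  expect_identical(as.character(sim$donor), as.character(sim$reference))
  expect_equal(nrow(sim$variants), 0L)
  ## one mapped "+" segment per scaffold
  expect_true(all(sim$segments$strand == "+" & sim$segments$mapped))
  expect_equal(nrow(sim$segments), 2L)
})

test_that("deletions shrink the donor by exactly their total length", {
  cfg <- simConfig(scaffoldLengths = rep(40000L, 4),
                   svCounts = c(deletion = 10),
                   svLengthRanges = list(insertion = c(1L, 1L),
                                         deletion = c(500L, 500L),
                                         duplication = c(1L, 1L),
                                         inversion = c(1L, 1L),
                                         complex = c(1L, 1L)),
                   snpRate = 0, seed = 11)
  sim <- simulateParentalGenomes(cfg)
  expect_equal(sum(Biostrings::width(sim$donor)),
               sum(Biostrings::width(sim$reference)) - 5000L)
})

test_that("emitted variants re-applied to the reference give the donor byte-for-byte", {
  for (seed in c(2, 9)) {
    cfg <- simConfig(scaffoldLengths = rep(30000L, 3),
                     svCounts = c(insertion = 3, deletion = 3,
                                  duplication = 2, inversion = 2, complex = 2),
                     svLengthRanges = list(insertion = c(150L, 300L),
                                           deletion = c(200L, 600L),
                                           duplication = c(300L, 800L),
                                           inversion = c(200L, 900L),
                                           complex = c(200L, 400L)),
                     snpRate = 0.002, minVariantGap = 1200L, seed = seed)
    sim <- simulateParentalGenomes(cfg)
    expect_true(all(table(sim$variants$type) > 0))
    oracle <- oracleApplyVariants(sim$reference, sim$variants, sim$snps)
    expect_identical(as.character(sim$donor), unlist(oracle))
  }
})

test_that("identical configs give bit-identical simulations", {
  cfg <- svTestConfig(5)
  s1 <- simulateParentalGenomes(cfg)
  s2 <- simulateParentalGenomes(cfg)
  expect_identical(as.character(s1$donor), as.character(s2$donor))
  expect_identical(s1$variants, s2$variants)
  p1 <- simulateReadPairs(s1, cfg)
  p2 <- simulateReadPairs(s2, cfg)
  expect_identical(p1, p2)
})

test_that("an impossible variant load raises a capacity error", {
  cfg <- simConfig(scaffoldLengths = 10000L,
                   svCounts = c(deletion = 50),
                   svLengthRanges = list(insertion = c(1L, 1L),
                                         deletion = c(400L, 400L),
                                         duplication = c(1L, 1L),
                                         inversion = c(1L, 1L),
                                         complex = c(1L, 1L)),
                   snpRate = 0, seed = 1)
  expect_error(simulateParentalGenomes(cfg), "capacity|fit")
})

test_that("pairs from a variant-free genome are exactly concordant", {
  cfg <- simConfig(scaffoldLengths = 60000L, svCounts = c(), snpRate = 0,
                   coverage = 10, seed = 4)
  sim <- simulateParentalGenomes(cfg)
  pairs <- simulateReadPairs(sim, cfg)
  ## liftover conservation: reference span == sampled fragment length, FR
  span <- pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2)
  expect_true(all(span == pairs$fragLen))
  expect_true(all(pairs$strand1 == "+" & pairs$strand2 == "-"))
  cls <- classifyPairs(pairs, list(mean = 505, sd = 50, k = 3))
  expect_true(all(cls$signature == "concordant" |
                    abs(cls$insert - 505) > 150))
})

test_that("pairs spanning a deletion gain exactly its length in the reference frame", {
  ref <- Biostrings::DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = ""), "s1"))
  vars <- data.frame(scaffold = "s1", start = 15000L, end = 15400L,
                     type = "deletion", length = 400L, seq = "",
                     stringsAsFactors = FALSE)
  ad <- applyVariants(ref, vars)
  sim <- list(reference = ref, donor = ad$donor, variants = vars,
              segments = ad$segments)
  cfg <- simConfig(scaffoldLengths = 30000L, svCounts = c(), coverage = 30,
                   insertSd = 40, seed = 8)
  pairs <- simulateReadPairs(sim, cfg)
  span <- pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2)
  gain <- span - pairs$fragLen
  ## liftover oracle: every pair whose fragment covers the breakpoint while
  ## both read midpoints sit outside the deleted span gains exactly 400 bp
  spanning <- gain == 400L
  expect_gte(sum(spanning), 6L)
  expect_true(all(gain %in% c(0L, 400L) | !pairs$mapped1 | !pairs$mapped2 |
                    abs(gain) <= 100L))  # straddlers place within a read length
  cls <- classifyPairs(pairs, list(mean = 505, sd = 40, k = 3))
  expect_gte(sum(cls$signature == "del_like"), 6L)
})

test_that("pairs spanning one inversion breakpoint are same-strand", {
  ref <- Biostrings::DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = ""), "s1"))
  vars <- data.frame(scaffold = "s1", start = 12000L, end = 14000L,
                     type = "inversion", length = 2000L, seq = "",
                     stringsAsFactors = FALSE)
  ad <- applyVariants(ref, vars)
  sim <- list(reference = ref, donor = ad$donor, variants = vars,
              segments = ad$segments)
  cfg <- simConfig(scaffoldLengths = 30000L, svCounts = c(), coverage = 30,
                   seed = 13)
  pairs <- simulateReadPairs(sim, cfg)
  cls <- classifyPairs(pairs, list(mean = 505, sd = 50, k = 3))
  ss <- cls[cls$signature == "inv_like", ]
  expect_gte(nrow(ss), 6L)
  expect_true(all(ss$strand1 == ss$strand2))
  ## both breakpoint families appear
  expect_true(any(ss$strand1 == "+") && any(ss$strand1 == "-"))
})

test_that("meiosis reproduces Haldane recombination fractions", {
  truth <- GeneticMap(data.frame(group = c(1L, 1L, 2L),
                                 marker = c("A", "B", "C"),
                                 position = c(0, 10, 0)))
  n <- 50000L
  gt <- simulateMeiosis(truth, n, seed = 99)
  s <- scores(gt)
  rfAB <- mean(s[, "A"] != s[, "B"])
  expRf <- (1 - exp(-0.2)) / 2           # 10 cM, no interference
  se <- sqrt(expRf * (1 - expRf) / n)
  expect_lt(abs(rfAB - expRf), 3 * se)
  ## independent assortment across groups
  rfAC <- mean(s[, "A"] != s[, "C"])
  expect_lt(abs(rfAC - 0.5), 3 * sqrt(0.25 / n))
  ## 1:1 parental allele balance, family-level bound across the markers
  pA <- colMeans(s == "a")
  expect_true(all(abs(pA - 0.5) < 4 * sqrt(0.25 / n)))
})

test_that("meiosis handles empty populations, heterokaryons and missing data", {
  truth <- GeneticMap(data.frame(group = 1L, marker = c("A", "B"),
                                 position = c(0, 5)))
  g0 <- simulateMeiosis(truth, 0)
  expect_equal(dim(g0), c(0L, 2L))
  expect_identical(markerNames(g0), c("A", "B"))
  expect_error(simulateMeiosis(truth, -1), "nProgeny")

  gt <- simulateMeiosis(truth, 2000, heterokaryonRate = 0.2,
                        missingRate = 0.1, seed = 21)
  hets <- gt@metadata$heterokaryons
  expect_gt(length(hets), 300)
  s <- scores(gt)
  expect_true(all(s[hets, ] %in% c("h", "-")))
  expect_lt(abs(mean(s == "-") - 0.1), 0.02)
  ## homokaryon rows never carry h
  hom <- setdiff(rownames(s), hets)
  expect_false(any(s[hom, ] == "h"))
})
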