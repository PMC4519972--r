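test_that("two-point statistics match their closed forms", {
  a <- rep("a", 100)
  r <- twoPoint(a, a)
  expect_equal(r$rf, 0)
  expect_equal(r$lod, 100 * log10(2))
  ## R = n/2: free recombination, zero LOD
  half <- c(rep("a", 50), rep("b", 50))
  r <- twoPoint(rep("a", 100), half)
  expect_equal(r$rf, 0.5)
  expect_equal(r$lod, 0)
  ## 6-strain toy, hand-evaluated
  ci <- c("a", "a", "b", "b", "a", "b")
  cj <- c("a", "b", "b", "b", "a", "a")
  r <- twoPoint(ci, cj)
  expect_equal(r$n, 6L)
  expect_equal(r$R, 2L)
  expect_equal(r$rf, 1 / 3)
  expect_equal(r$lod, 2 * log10(2 / 3) + 4 * log10(4 / 3))
  ## missing and h codes are excluded
  r <- twoPoint(c("a", "h", "b", "-"), c("a", "a", "b", "b"))
  expect_equal(r$n, 2L)
  expect_error(twoPoint(c("-", "-"), c("a", "b")), "no informative")
})

test_that("two-point statistics are symmetric under swap and relabeling", {
  set.seed(91)
  ci <- sample(c("a", "b", "-"), 80, TRUE, prob = c(.45, .45, .1))
  cj <- sample(c("a", "b", "-"), 80, TRUE, prob = c(.45, .45, .1))
  r1 <- twoPoint(ci, cj)
  r2 <- twoPoint(cj, ci)
  expect_equal(r1, r2)
  flip <- function(x) chartr("ab", "ba", x)
  r3 <- twoPoint(flip(ci), cj)
  expect_equal(r3$R, r1$n - r1$R)    # relabeling swaps parental/recombinant
  r4 <- twoPoint(flip(ci), flip(cj))
  expect_equal(r4, r1)
})

test_that("the vectorised two-point table equals the scalar computation", {
  truth <- GeneticMap(data.frame(group = 1L, marker = c("A", "B", "C"),
                                 position = c(0, 7, 25)))
  gt <- simulateMeiosis(truth, 150, missingRate = 0.1, seed = 101)
  tp <- twoPointTable(gt)
  s <- scores(gt)
  for (i in 1:2) for (j in (i + 1):3) {
    r <- twoPoint(s[, i], s[, j])
    expect_equal(unname(tp$n[i, j]), r$n)
    expect_equal(unname(tp$R[i, j]), r$R)
    expect_equal(unname(tp$rf[i, j]), r$rf)
    expect_equal(unname(tp$lod[i, j]), r$lod)
  }
})

test_that("map functions match closed forms and invert exactly", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3))
  expect_equal(kosambi(0.1), 25 * log(1.5))
  expect_equal(haldane(0.25), -50 * log(0.5))
  rs <- seq(0, 0.49, by = 0.007)
  expect_lt(max(abs(kosambiInv(kosambi(rs)) - rs)), 1e-12)
  expect_lt(max(abs(haldaneInv(haldane(rs)) - rs)), 1e-12)
  ## Kosambi compresses relative to Haldane; both linear near 0
  mid <- rs[rs > 0]
  expect_true(all(kosambi(mid) <= haldane(mid)))
  expect_equal(kosambi(1e-9) / (100 * 1e-9), 1, tolerance = 1e-6)
  expect_warning(kosambi(0.5), "infinite")
  expect_equal(suppressWarnings(kosambi(0.5)), Inf)
})

test_that("LOD is zero at free recombination and decreasing in R below n/2", {
  n <- 100
  lods <- vapply(0:50, function(R) {
    rf <- R / n
    if (R == 0) n * log10(2) else
      R * log10(2 * rf) + (n - R) * log10(2 * (1 - rf))
  }, numeric(1))
  expect_true(all(diff(lods) < 0))
  expect_equal(lods[51], 0)
})

test_that("LOD grouping takes connected components and refines monotonically", {
  truth <- GeneticMap(data.frame(group = rep(1:3, each = 4),
                                 marker = sprintf("M%02d", 1:12),
                                 position = rep(c(0, 6, 12, 18), 3)))
  gt <- simulateMeiosis(truth, 192, seed = 111)
  tp <- twoPointTable(gt)
  grp <- groupMarkers(tp, lodThreshold = 3, maxRf = 0.3)
  got <- lapply(grp$groups, sort)
  want <- split(sprintf("M%02d", 1:12), rep(1:3, each = 4))
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, function(x) paste(sort(x), collapse = ","), ""))
  ## threshold -> Inf: everything unlinked
  grpInf <- groupMarkers(tp, lodThreshold = Inf)
  expect_length(grpInf$groups, 0)
  expect_length(grpInf$unlinked, 12)
  ## raising the threshold only refines the partition
  for (thr in c(3, 8, 15, 25)) {
    g1 <- groupMarkers(tp, lodThreshold = thr)
    g2 <- groupMarkers(tp, lodThreshold = thr + 5)
    for (g in g2$groups) {
      container <- vapply(g1$groups, function(h) all(g %in% h), logical(1))
      expect_true(any(container))
    }
  }
})

test_that("group ordering attains the exhaustive optimum on small groups", {
  set.seed(121)
  for (rep_ in 1:10) {
    k <- sample(4:8, 1)
    truth <- GeneticMap(data.frame(group = 1L,
                                   marker = sprintf("M%02d", 1:k),
                                   position = cumsum(c(0, runif(k - 1, 4, 15)))))
    gt <- simulateMeiosis(truth, 192, seed = 121 + rep_)
    tp <- twoPointTable(gt)
    ord <- orderGroup(markerNames(gt), tp)
    expect_equal(orderObjective(ord, tp$rf),
                 bruteForceSarf(markerNames(gt), tp$rf),
                 tolerance = 1e-12)
  }
})

test_that("two-marker groups are canonical and tiny groups error out", {
  tp <- list(rf = matrix(0.1, 2, 2, dimnames = list(c("B", "A"), c("B", "A"))),
             lod = matrix(10, 2, 2, dimnames = list(c("B", "A"), c("B", "A"))))
  expect_equal(orderGroup(c("B", "A"), tp), c("A", "B"))
  expect_error(orderGroup("A", tp), "at least 2")
})

test_that("a supplied framework order is respected and completed", {
  truth <- GeneticMap(data.frame(group = 1L, marker = sprintf("M%d", 1:6),
                                 position = c(0, 8, 16, 24, 32, 40)))
  gt <- simulateMeiosis(truth, 192, seed = 131)
  tp <- twoPointTable(gt)
  ord <- orderGroup(sprintf("M%d", 1:6), tp,
                    framework = c("M1", "M3", "M5"))
  expect_true(ord[1] %in% c("M1", "M6"))
  pos <- match(sprintf("M%d", 1:6), ord)
  expect_true(all(diff(pos) > 0) || all(diff(pos) < 0))
})

test_that("full map construction recovers simulated structure", {
  set.seed(141)
  nG <- 5
  positions <- lapply(1:nG, function(g) cumsum(c(0, runif(7, 5, 15))))
  truth <- GeneticMap(data.frame(
    group = rep(1:nG, each = 8),
    marker = sprintf("G%dM%d", rep(1:nG, each = 8), rep(1:8, nG)),
    position = unlist(positions)))
  gt <- simulateMeiosis(truth, 192, seed = 151)
  map <- buildMap(gt, lodThreshold = 3, maxRf = 0.3)
  tb <- mapTable(map)
  expect_equal(length(unique(tb$group)), nG)
  ## grouping equals truth
  trueTb <- mapTable(truth)
  for (g in unique(tb$group)) {
    mk <- tb$marker[tb$group == g]
    trueG <- unique(trueTb$group[trueTb$marker %in% mk])
    expect_length(trueG, 1L)
    expect_setequal(mk, trueTb$marker[trueTb$group == trueG])
  }
  ## adjacent rf estimates sit within 3 binomial s.e. of the Haldane truth
  tp <- twoPointTable(gt)
  for (g in unique(trueTb$group)) {
    sub <- trueTb[trueTb$group == g, ]
    for (i in seq_len(nrow(sub) - 1)) {
      rTrue <- haldaneInv(sub$position[i + 1] - sub$position[i])
      rHat <- tp$rf[sub$marker[i], sub$marker[i + 1]]
      n <- tp$n[sub$marker[i], sub$marker[i + 1]]
      expect_lt(abs(rHat - rTrue), 3 * sqrt(rTrue * (1 - rTrue) / n) + 1e-9)
    }
  }
  ## group length is invariant under order reversal
  ms <- mapSummary(map)
  for (g in unique(tb$group)) {
    p <- tb$position[tb$group == g]
    expect_equal(max(p) - min(p), ms$perGroup$lengthCm[ms$perGroup$group == g])
  }
})

test_that("map summary reproduces the published group-table arithmetic", {
  facts <- read.delim(system.file("extdata", "vv_linkage_group_summary.tsv",
                                  package = "svmap"))
  ## rebuild a map skeleton with the printed per-group lengths and counts
  rows <- do.call(rbind, lapply(seq_len(nrow(facts)), function(i) {
    k <- facts$n_markers[i]
    data.frame(group = facts$group[i],
               marker = sprintf("g%dm%d", facts$group[i], seq_len(k)),
               position = seq(0, facts$length_cm[i], length.out = k))
  }))
  ms <- mapSummary(GeneticMap(rows))
  expect_equal(ms$totalLengthCm, 411.601)
  expect_equal(ms$totalMarkers, 102L)
  expect_equal(ms$meanSpacingCm, 4.035)
  expect_equal(ms$perGroup$avgSpacing[ms$perGroup$group == 1], 4.22)
  expect_equal(ms$perGroup$avgSpacing[ms$perGroup$group == 7], 0.54)
})
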