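test_that("genes are classified core/accessory/unobserved by cohort presence", {
  ref <- makeRef(3L)
  m <- rbind(rep(TRUE, 10),                  # all 10: core
             c(rep(TRUE, 3), rep(FALSE, 7)), # 3 of 10: accessory
             rep(FALSE, 10))                 # none: unobserved
  lab <- classifyGenes(makePM(m, ref))
  expect_identical(as.character(lab), c("core", "accessory", "unobserved"))
  expect_identical(as.integer(attr(lab, "summary")), c(1L, 1L, 1L))
})

test_that("classification needs at least two unique individuals", {
  ref <- makeRef(2L)
  expect_error(classifyGenes(makePM(matrix(TRUE, 2, 1), ref)), "at least 2")
  pm <- makePM(matrix(TRUE, 2, 2), ref)
  SummarizedExperiment::colData(pm)$individual_id <- c("a", "a")
  expect_error(classifyGenes(pm), "one sample per individual")
})

test_that("classification is invariant to individual ordering", {
  ref <- makeRef(50L)
  set.seed(8)
  m <- matrix(runif(50 * 6) > 0.3, 50, 6)
  lab1 <- classifyGenes(makePM(m, ref))
  lab2 <- classifyGenes(makePM(m[, sample(6)], ref))
  expect_identical(as.character(lab1), as.character(lab2))
})

test_that("subsample fractions match exhaustive enumeration on a tiny cohort", {
  # g1 present in all three, g2 only in individual 1; universe = {g1, g2};
  # every 2-subset misses g2 in at least one member -> fraction 1/2
  ref <- makeRef(2L)
  m <- rbind(c(TRUE, TRUE, TRUE),
             c(TRUE, FALSE, FALSE))
  tab <- subsampleFractions(makePM(m, ref), sizes = 2L)
  expect_equal(tab$n_combinations, 3)
  expect_true(all(abs(tab$fractions[[1]] - 0.5) < 1e-12))
  expect_equal(tab$mean_fraction, 0.5)
})

test_that("all combinations are enumerated when no cap is set", {
  ref <- makeRef(30L)
  set.seed(3)
  m <- matrix(runif(30 * 10) > 0.2, 30, 10)
  tab <- subsampleFractions(makePM(m, ref), sizes = 2L)
  expect_equal(tab$n_combinations, 45)   # C(10, 2)
})

test_that("capped subsampling draws distinct combinations and stays seeded", {
  ref <- makeRef(40L)
  set.seed(4)
  m <- matrix(runif(40 * 12) > 0.25, 40, 12)
  pm <- makePM(m, ref)
  t1 <- subsampleFractions(pm, sizes = 6L, maxCombinations = 50L, seed = 9)
  t2 <- subsampleFractions(pm, sizes = 6L, maxCombinations = 50L, seed = 9)
  expect_equal(t1$n_combinations, 50)
  expect_identical(t1$fractions[[1]], t2$fractions[[1]])
})

test_that("identical individuals give zero fractions at every size", {
  ref <- makeRef(20L)
  m <- matrix(TRUE, 20, 5)
  m[1:3, ] <- FALSE   # absent everywhere: outside the universe
  tab <- subsampleFractions(makePM(m, ref))
  expect_true(all(tab$mean_fraction == 0))
})

test_that("mean fraction is monotone and recovers the cohort fraction at k=n", {
  ref <- makeRef(80L)
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(runif(80 * 8) > runif(1, 0.1, 0.5), 80, 8)
    if (sum(rowSums(m) > 0) == 0) next
    tab <- subsampleFractions(makePM(m, ref))
    expect_true(all(diff(tab$mean_fraction) >= -1e-12))
    expect_equal(tab$mean_fraction[tab$size == 8],
                 observedAccessoryFraction(m))
  }
})

test_that("exhaustive subsample means are permutation invariant", {
  ref <- makeRef(60L)
  set.seed(12)
  m <- matrix(runif(60 * 6) > 0.3, 60, 6)
  t1 <- subsampleFractions(makePM(m, ref))
  t2 <- subsampleFractions(makePM(m[, c(4, 2, 6, 1, 3, 5)], ref))
  expect_equal(t1$mean_fraction, t2$mean_fraction)
})

test_that("the exponential fit recovers a noiseless saturating curve", {
  k <- 2:10
  tab <- data.frame(size = k, mean_fraction = 0.30 - 0.30 * exp(-k / 2),
                    median_fraction = NA_real_)
  fit <- fitAccessoryModel(tab, "exponential")
  expect_lt(abs(asymptote(fit) - 0.30), 1e-3)
  expect_lt(fit@rss, 1e-8)
})

test_that("a constant table degenerates to an asymptote at the constant", {
  tab <- data.frame(size = 2:8, mean_fraction = 0.17,
                    median_fraction = 0.17)
  fit <- fitAccessoryModel(tab, "exponential")
  expect_equal(asymptote(fit), 0.17)
  fitn <- fitAccessoryModel(tab, "negative_exponential")
  expect_equal(asymptote(fitn), 0.17)
})

test_that("saturating data keep the asymptote above the last observed mean", {
  k <- 2:10
  y <- 0.4 * (1 - exp(-0.35 * k))
  tab <- data.frame(size = k, mean_fraction = y, median_fraction = y)
  for (mod in c("exponential", "negative_exponential")) {
    fit <- fitAccessoryModel(tab, mod)
    expect_gte(asymptote(fit), max(y) - 1e-6)
  }
})

test_that("median-based fitting is available alongside the default mean", {
  k <- 2:10
  tab <- data.frame(size = k,
                    mean_fraction = 0.30 - 0.30 * exp(-k / 2),
                    median_fraction = 0.25 - 0.25 * exp(-k / 2))
  fit <- fitAccessoryModel(tab, "exponential", stat = "median")
  expect_lt(abs(asymptote(fit) - 0.25), 1e-3)
})

test_that("accessory percentage conversion and model-family guards", {
  k <- 2:10
  tab <- data.frame(size = k, mean_fraction = 0.3228 - 0.3 * exp(-k / 2),
                    median_fraction = NA_real_)
  fit <- fitAccessoryModel(tab, "exponential")
  expect_equal(estimateAccessoryPercent(fit), 100 * asymptote(fit))
  expect_lt(abs(estimateAccessoryPercent(fit) - 32.28), 0.5)

  zero <- data.frame(size = 2:6, mean_fraction = 0, median_fraction = 0)
  expect_equal(estimateAccessoryPercent(
    fitAccessoryModel(zero, "exponential")), 0)

  grow <- data.frame(size = k, mean_fraction = 0.05 * k^0.4,
                     median_fraction = NA_real_)
  pl <- fitAccessoryModel(grow, "power_law")
  expect_warning(v <- estimateAccessoryPercent(pl), "horizon")
  expect_equal(v, 100 * pl@horizonValue)

  sp <- fitAccessoryModel(grow, "spline")
  expect_error(estimateAccessoryPercent(sp), "spline")
  expect_equal(predict(sp, k), grow$mean_fraction, tolerance = 1e-10)
})

test_that("model deviation is a mean absolute gap in percentage points", {
  k <- 2:10
  y <- 0.30 - 0.30 * exp(-k / 2)
  tab <- data.frame(size = k, mean_fraction = y, median_fraction = NA_real_)
  fit <- fitAccessoryModel(tab, "exponential")
  kk <- 2:15
  exact <- data.frame(size = kk, mean_fraction = 0.30 - 0.30 * exp(-kk / 2),
                      median_fraction = NA_real_)
  expect_lt(modelDeviation(fit, exact), 0.01)
  shifted <- exact
  shifted$mean_fraction <- shifted$mean_fraction + 0.05
  expect_equal(modelDeviation(fit, shifted), 5, tolerance = 0.01)
  expect_error(modelDeviation(fit, exact[0, ]), "no sizes")
})

test_that("exponential beats power law on a saturating truth", {
  k <- 2:10
  y <- 0.35 * (1 - exp(-0.4 * k))
  tab <- data.frame(size = k, mean_fraction = y, median_fraction = y)
  fe <- fitAccessoryModel(tab, "exponential")
  fp <- fitAccessoryModel(tab, "power_law")
  kk <- 2:25
  expected <- data.frame(size = kk,
                         mean_fraction = 0.35 * (1 - exp(-0.4 * kk)),
                         median_fraction = NA_real_)
  expect_lt(modelDeviation(fe, expected), modelDeviation(fp, expected))
})
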