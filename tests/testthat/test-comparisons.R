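test_that("the symmetric-difference distance evaluates the stated formula", {
  # A = {g1,g2,g3}, B = {g2,g3,g4}: 2 genes in exactly one, 4 in the union
  a <- c(TRUE, TRUE, TRUE, FALSE)
  b <- c(FALSE, TRUE, TRUE, TRUE)
  pd <- pairwiseDifference(a, b)
  expect_equal(pd$n_union, 4L)
  expect_equal(pd$n_symmetric_difference, 2L)
  expect_equal(pd$value, 0.5)
  expect_equal(pairwiseDifference(a, a)$value, 0)
  expect_equal(pairwiseDifference(c(TRUE, FALSE), c(FALSE, TRUE))$value, 1)
  expect_error(pairwiseDifference(a, b[1:3]), "length")
  expect_error(pairwiseDifference(c(FALSE, FALSE), c(FALSE, FALSE)), "union")
})

test_that("the gene content distance satisfies the metric axioms", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(5:40, 1)
    x <- runif(n) > 0.4; y <- runif(n) > 0.4; z <- runif(n) > 0.4
    if (!any(x) || !any(y) || !any(z)) next
    dxy <- pairwiseDifference(x, y)$value
    dyx <- pairwiseDifference(y, x)$value
    dxz <- pairwiseDifference(x, z)$value
    dyz <- pairwiseDifference(y, z)$value
    expect_identical(dxy, dyx)
    expect_equal(pairwiseDifference(x, x)$value, 0)
    expect_lte(dxz, dxy + dyz + 1e-12)
    expect_gte(dxy, 0); expect_lte(dxy, 1)
  }
})

test_that("replicate pairs are labeled by individual, time point and lane", {
  ref <- makeRef(30L)
  set.seed(5)
  m <- matrix(runif(30 * 7) > 0.2, 30, 7)
  colnames(m) <- c("i1_t1_l1", "i1_t1_l2", "i1_t1_l3", "i1_t1_l4",
                   "i1_t2_l1", "i2_t1_l1", "i3_t1_l1")
  info <- data.frame(
    sample_id = colnames(m),
    individual_id = c("i1", "i1", "i1", "i1", "i1", "i2", "i3"),
    time_point = c(1L, 1L, 1L, 1L, 2L, 1L, 1L),
    lane = c(1L, 2L, 3L, 4L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  rd <- replicateDifferences(m, info)
  expect_equal(sum(rd$comparison_class == "technical_replicate"), 6L) # C(4,2)
  expect_equal(sum(rd$comparison_class == "biological_replicate"), 4L)
  expect_equal(sum(rd$comparison_class == "inter_individual"), 11L)
  # two time points for one individual alone give exactly one biological pair
  rd2 <- replicateDifferences(m[, c(1, 5)], info)
  expect_equal(rd2$comparison_class, "biological_replicate")
  # 10 individuals give C(10,2) inter-individual pairs
  m10 <- matrix(TRUE, 5, 10,
                dimnames = list(NULL, sprintf("j%02d_t1", 1:10)))
  info10 <- data.frame(sample_id = colnames(m10),
                       individual_id = sprintf("j%02d", 1:10),
                       time_point = 1L, lane = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(replicateDifferences(m10, info10)), 45L)
})

test_that("the reference-conditioned distance ignores non-reference genes", {
  refSet <- paste0("g", 1:5)
  A <- c("g1", "g2", "g3")
  B <- c("g1", "g2", "g4")
  rc <- referenceConditionedDifference(A, B, refSet)
  expect_equal(rc$value, 0.5)   # {g3,g4} over {g1,g2,g3,g4}
  expect_equal(referenceConditionedDifference(A, A, refSet)$value, 0)
  # a gene outside the reference changes nothing
  rc2 <- referenceConditionedDifference(c(A, "g6"), B, refSet)
  expect_equal(rc2$value, rc$value)
  expect_error(referenceConditionedDifference("g9", "g8", refSet),
               "denominator")
})

test_that("conditioning on the full universe reduces to the pairwise metric", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    ids <- paste0("g", seq_len(n))
    x <- runif(n) > 0.4; y <- runif(n) > 0.4
    if (!any(x | y)) next
    d1 <- pairwiseDifference(x, y)$value
    d2 <- referenceConditionedDifference(ids[x], ids[y], ids)$value
    expect_equal(d1, d2)
  }
})

test_that("rank-sum comparison is exact for small untied samples", {
  res <- compareDistanceDistributions(c(1, 2, 3), c(10, 11, 12))
  expect_true(res$exact)
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)   # 2 / C(6,3) labelings as extreme

  same <- compareDistanceDistributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  expect_error(compareDistanceDistributions(numeric(0), 1), "non-empty")
})

test_that("a clear shift is detected at moderate sample size", {
  set.seed(2024)
  hits <- 0L
  for (s in 1:20) {
    x <- rnorm(50, 1); y <- rnorm(50, 0)
    if (compareDistanceDistributions(x, y)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # build labels and one category realizing the table [[8,2],[2,8]]
  genes <- paste0("g", 1:20)
  lab <- factor(rep(c("accessory", "core"), each = 10),
                levels = c("core", "accessory", "unobserved"))
  names(lab) <- genes
  cmap <- data.frame(gene_id = c(genes[1:8], genes[11:12]),
                     category = "CAT1", stringsAsFactors = FALSE)
  res <- fisherEnrichment(lab, cmap)
  expect_equal(res$accessory_in, 8L)
  expect_equal(res$core_in, 2L)
  expect_equal(res$p_value, bruteFisherP(8, 2, 2, 8), tolerance = 1e-10)
  expect_equal(res$p_value, 0.023, tolerance = 1e-3)
  expect_equal(res$q_value, res$p_value)   # single category: q = p

  # balanced category: odds ratio 1, p = 1
  cmap2 <- data.frame(gene_id = c(genes[1:5], genes[11:15]),
                      category = "CAT2", stringsAsFactors = FALSE)
  res2 <- fisherEnrichment(lab, cmap2)
  expect_equal(res2$p_value, 1)
  expect_equal(res2$odds_ratio, 1, tolerance = 1e-6)
})

test_that("unobserved genes are excluded from enrichment tables", {
  genes <- paste0("g", 1:15)
  lab <- factor(c(rep("accessory", 5), rep("core", 5), rep("unobserved", 5)),
                levels = c("core", "accessory", "unobserved"))
  names(lab) <- genes
  cmap <- data.frame(gene_id = genes, category = "ALL",
                     stringsAsFactors = FALSE)
  res <- fisherEnrichment(lab, cmap)
  expect_equal(res$accessory_in + res$accessory_out +
               res$core_in + res$core_out, 10L)
})

test_that("BH-adjusted q values dominate p and stay monotone", {
  set.seed(88)
  genes <- paste0("g", 1:200)
  lab <- factor(sample(c("core", "accessory"), 200, replace = TRUE),
                levels = c("core", "accessory", "unobserved"))
  names(lab) <- genes
  cmap <- data.frame(gene_id = rep(genes, 2),
                     category = sample(paste0("C", 1:12), 400, replace = TRUE),
                     stringsAsFactors = FALSE)
  res <- fisherEnrichment(lab, cmap)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
  expect_true(all(res$q_value <= 1))
})

test_that("the doubling two-sided option is a valid alternative", {
  genes <- paste0("g", 1:20)
  lab <- factor(rep(c("accessory", "core"), each = 10),
                levels = c("core", "accessory", "unobserved"))
  names(lab) <- genes
  cmap <- data.frame(gene_id = c(genes[1:8], genes[11:12]),
                     category = "CAT1", stringsAsFactors = FALSE)
  resD <- fisherEnrichment(lab, cmap, twoSided = "doubling")
  expect_true(resD$p_value >= 0 && resD$p_value <= 1)
  # doubling can only be >= the one-sided tail
  expect_gte(resD$p_value, stats::phyper(7, 10, 10, 10, lower.tail = FALSE))
})

test_that("abundance independence diagnostics flag degenerate inputs", {
  res <- abundanceIndependenceCheck(rep(0.3, 5), 1:5, 5:1)
  expect_true(all(is.na(res$estimate)))
  expect_equal(unique(res$note), "constant input")

  af <- seq(0.1, 0.5, length.out = 5)
  res2 <- abundanceIndependenceCheck(af, 2 * af + 1, rev(af))
  expect_equal(abs(res2$estimate), c(1, 1), tolerance = 1e-10)

  expect_error(abundanceIndependenceCheck(c(0.1, 0.2), 1:2, 1:2), "3 samples")
})

test_that("independent draws rarely show strong correlation", {
  set.seed(404)
  ok <- 0L
  for (s in 1:100) {
    af <- runif(20); cov <- runif(20, 20, 80); ab <- runif(20)
    r <- abundanceIndependenceCheck(af, cov, ab)
    if (all(abs(r$estimate) < 0.5)) ok <- ok + 1L
  }
  expect_gte(ok, 90L)
})
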