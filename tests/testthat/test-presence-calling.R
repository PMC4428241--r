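test_that("the gene-length coverage boundary is inclusive", {
  ref <- makeRef(3L)   # three 100 bp genes on one contig
  prof <- makeProfile(ref, c(0.40, 0, 0.399))
  calls <- callGenePresence(prof, ref, lengthCutoff = 0.40)
  expect_identical(unname(calls), c(TRUE, FALSE, FALSE))
})

test_that("profiles with unknown or missing genes are rejected by name", {
  ref <- makeRef(3L)
  prof <- makeProfile(ref, 0.9)
  prof@coverage$gene_id[2L] <- "rogue_gene"
  expect_error(callGenePresence(prof, ref), "rogue_gene")
  prof2 <- makeProfile(ref, 0.9)
  prof2@coverage <- prof2@coverage[-2L, ]
  expect_error(callGenePresence(prof2, ref), "missing")
})

test_that("presence calls are monotone in the cutoff and idempotent", {
  ref <- makeRef(c(20L, 20L))
  set.seed(42)
  for (rep in 1:5) {
    prof <- makeProfile(ref, runif(40))
    cutoffs <- seq(0, 1, by = 0.1)
    counts <- vapply(cutoffs, function(ct)
      sum(callGenePresence(prof, ref, ct)), numeric(1))
    expect_true(all(diff(counts) <= 0))
    expect_identical(callGenePresence(prof, ref, 0.4),
                     callGenePresence(prof, ref, 0.4))
  }
})

test_that("sample filters implement breadth, marker and depth criteria", {
  ref <- makeRef(10L, markers = c(2L, 7L))
  ok <- makeProfile(ref, 0.9, breadth = 0.8, genomeDepth = 35)
  d <- filterSampleSpecies(ok, ref)
  expect_true(d$pass)
  expect_equal(d$reasons, "")

  lowBreadth <- makeProfile(ref, 0.9, breadth = 0.39, genomeDepth = 100)
  d <- filterSampleSpecies(lowBreadth, ref)
  expect_false(d$pass)
  expect_false(d$breadth_pass)
  expect_true(d$markers_pass && d$depth_pass)

  lowDepth <- makeProfile(ref, 0.9, breadth = 0.8, genomeDepth = 29.9)
  d <- filterSampleSpecies(lowDepth, ref)
  expect_false(d$pass)
  expect_false(d$depth_pass)

  lostMarker <- makeProfile(ref, 0.9, breadth = 0.8, genomeDepth = 35)
  lostMarker@coverage$covered_bp[7L] <- 10L   # marker below 40% of length
  d <- filterSampleSpecies(lostMarker, ref)
  expect_false(d$pass)
  expect_false(d$markers_pass)
  expect_match(d$reasons, "marker")

  # boundary values pass ("at least" is inclusive)
  edge <- makeProfile(ref, 0.9, breadth = 0.40, genomeDepth = 30)
  expect_true(filterSampleSpecies(edge, ref)$pass)
})

test_that("breadth and depth fall back to gene-length-weighted recomputation", {
  ref <- makeRef(4L)
  prof <- makeProfile(ref, c(1, 1, 0, 0), depth = c(40, 40, 0, 0))
  expect_equal(genomeBreadth(prof), 0.5)
  expect_equal(genomeMeanDepth(prof), 20)
})

test_that("cohort selection enforces the minimum and is deterministic", {
  mkDecisions <- function(inds, pass = TRUE) {
    data.frame(sample_id = paste0(inds, "_t1"), species_id = "tst",
               individual_id = inds, breadth = 0.9, depth = 50,
               breadth_pass = pass, markers_pass = pass, depth_pass = pass,
               pass = pass, reasons = "", stringsAsFactors = FALSE)
  }
  mkInfo <- function(inds) {
    data.frame(sample_id = paste0(inds, "_t1"), individual_id = inds,
               time_point = 1L, lane = 1L, stringsAsFactors = FALSE)
  }
  nine <- sprintf("i%02d", 1:9)
  expect_message(res <- selectCohort(mkDecisions(nine), mkInfo(nine), k = 10),
                 "excluded")
  expect_equal(nrow(res), 0L)
  expect_match(attr(res, "reason"), "9 of the required 10")

  sixteen <- sprintf("i%02d", 1:16)
  r1 <- selectCohort(mkDecisions(sixteen), mkInfo(sixteen), k = 10, seed = 4)
  r2 <- selectCohort(mkDecisions(sixteen), mkInfo(sixteen), k = 10, seed = 4)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 10L)

  ten <- sprintf("i%02d", 1:10)
  r3 <- selectCohort(mkDecisions(ten), mkInfo(ten), k = 10, seed = 1)
  r4 <- selectCohort(mkDecisions(ten), mkInfo(ten), k = 10, seed = 999)
  expect_identical(sort(r3$individual_id), ten)
  expect_identical(r3, r4)
})

test_that("the primary sample per individual is the earliest time point", {
  dec <- data.frame(sample_id = c("a_t2", "a_t1", "b_t1"),
                    species_id = "tst", individual_id = c("a", "a", "b"),
                    breadth = 0.9, depth = 50, breadth_pass = TRUE,
                    markers_pass = TRUE, depth_pass = TRUE, pass = TRUE,
                    reasons = "", stringsAsFactors = FALSE)
  info <- data.frame(sample_id = c("a_t2", "a_t1", "b_t1"),
                     individual_id = c("a", "a", "b"),
                     time_point = c(2L, 1L, 1L), lane = 1L,
                     stringsAsFactors = FALSE)
  res <- selectCohort(dec, info, k = 2)
  expect_equal(res$sample_id[res$individual_id == "a"], "a_t1")
})

test_that("cutoff calibration scores replicate variability across the grid", {
  ref <- makeRef(10L)
  # identical replicates: zero difference everywhere, smallest cutoff wins
  a <- makeProfile(ref, 0.9, sampleId = "r1")
  b <- makeProfile(ref, 0.9, sampleId = "r2")
  cal <- calibrateLengthCutoff(list(list(a, b)), ref)
  expect_equal(cal$table$mean_difference, rep(0, 11))
  expect_equal(cal$cutoff, 0.0)

  # three genes straddle the 0.5 cutoff (0.45 vs 0.52): enumerating calls at
  # every grid cutoff puts a nonzero difference only there, so the minimum is
  # attained away from the straddled cutoff and tie-breaks to 0.0
  cfA <- c(rep(0.95, 7), rep(0.45, 3))
  cfB <- c(rep(0.95, 7), rep(0.52, 3))
  a2 <- makeProfile(ref, cfA, sampleId = "r1")
  b2 <- makeProfile(ref, cfB, sampleId = "r2")
  expected <- vapply(seq(0, 1, by = 0.1), function(ct) {
    pa <- cfA >= ct; pb <- cfB >= ct
    if (!any(pa | pb)) 0 else sum(xor(pa, pb)) / sum(pa | pb)
  }, numeric(1))
  cal2 <- calibrateLengthCutoff(list(list(a2, b2)), ref)
  expect_equal(cal2$table$mean_difference, expected)
  expect_gt(cal2$table$mean_difference[cal2$table$cutoff == 0.5], 0)
  expect_equal(cal2$cutoff, 0.0)

  # one gene flipping between cutoffs 0.4 and 0.5 gives a single step
  cfC <- c(rep(0.95, 9), 0.45)
  cfD <- c(rep(0.95, 9), 0.95)
  cal3 <- calibrateLengthCutoff(list(list(
    makeProfile(ref, cfC, sampleId = "r1"),
    makeProfile(ref, cfD, sampleId = "r2"))), ref)
  curve <- cal3$table$mean_difference
  expect_equal(curve[1:5], rep(0, 5))                   # cutoffs 0 .. 0.4
  expect_equal(curve[6:10], rep(0.1, 5))                # cutoffs 0.5 .. 0.9
  expect_equal(length(unique(curve[curve > 0])), 1L)    # one step height
})

test_that("calibration without replicate pairs errors", {
  ref <- makeRef(5L)
  expect_error(calibrateLengthCutoff(list(), ref), "replicate")
})

test_that("presence matrices keep genome order and sample metadata", {
  ref <- makeRef(c(3L, 3L))
  profs <- list(makeProfile(ref, c(1, 1, 0, 1, 1, 1), sampleId = "s1"),
                makeProfile(ref, c(1, 0, 0, 1, 1, 1), sampleId = "s2"))
  pm <- buildPresenceMatrix(profs, ref)
  expect_s4_class(pm, "PresenceMatrix")
  expect_identical(rownames(presence(pm)), geneIds(ref))
  expect_identical(colnames(presence(pm)), c("s1", "s2"))
  expect_identical(unname(presence(pm)[, "s2"]),
                   c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
})
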