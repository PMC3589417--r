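test_that("average RSD is taken over multi-peptide proteins only", {
  q <- data.frame(rsd = c(0.10, 0.14), n_leu_peptides = c(3L, 2L))
  expect_equal(averageRsd(q), 0.12)
  # single-peptide proteins carry no variability information
  q2 <- data.frame(rsd = c(0, 0.12), n_leu_peptides = c(1L, 3L))
  expect_equal(averageRsd(q2), 0.12)
  expect_error(averageRsd(data.frame(rsd = 0, n_leu_peptides = 1L)),
               class = "noQualifyingProtein")
})

test_that("cutoff derivation reproduces the 12% -> 36% -> 1.40 chain", {
  d <- deriveCutoff(0.12)
  expect_equal(d@rawThresholdPct, 36)
  expect_equal(cutoffRatio(d), 1.40)
  expect_equal(avgRsd(d), 0.12)
  d0 <- deriveCutoff(0)
  expect_equal(cutoffRatio(d0), 1.0)
  # ceiling leaves a value already on a 0.1 boundary unchanged
  expect_equal(cutoffRatio(deriveCutoff(0.10)), 1.30)
  # exact mode skips rounding
  expect_equal(cutoffRatio(deriveCutoff(0.115, rounding = "none")), 1.345)
})

test_that("rounding is never downward and the cutoff is monotone in avg RSD", {
  set.seed(77)
  rsds <- sort(runif(30, 0, 0.5))
  cuts <- vapply(rsds, function(r) cutoffRatio(deriveCutoff(r)), numeric(1))
  expect_true(all(diff(cuts) >= 0))
  for (i in seq_along(rsds))
    expect_gte(cuts[i], 1 + 3 * rsds[i] - 1e-12)
})

test_that("classification partitions the quantified set against cutoff, bead list and bait", {
  q <- data.frame(accession = c("B", "P1", "P2", "P3", "STICKY"),
                  normalized_ratio = c(1, 1.45, 1.39, 3.2, 3.2))
  cls <- classifyInteractors(q, deriveCutoff(0.12), bead_list = "STICKY",
                             bait_accession = "B")
  expect_identical(as.character(cls$calls$call),
                   c("bait", "induced_interactor", "non_induced",
                     "induced_interactor", "bead_excluded"))
  # the boundary is inclusive
  q2 <- data.frame(accession = "P", normalized_ratio = 1.40)
  expect_identical(as.character(
    classifyInteractors(q2, 1.40, character(), "B")$calls$call),
    "induced_interactor")
  # counts per call partition the input
  expect_equal(sum(cls$summary[c("bait", "induced_interactor",
                                 "bead_excluded", "non_induced")]), nrow(q))
  expect_error(classifyInteractors(
    data.frame(accession = "P", normalized_ratio = NA_real_), 1.4,
    character(), "B"), class = "invalidArgument")
})

test_that("classification recovers ground truth on a mid-size noisy experiment", {
  cfg <- syntheticConfig(seed = 19, n_induced = 10L, n_constitutive = 20L,
                         n_nonspecific = 20L, n_bead = 5L, n_keratin = 1L,
                         induced_range = c(1.8, 4.0))
  run <- runPipeline(defaultPipelineConfig(seed = 19),
                     experiment = generateExperiment(cfg))
  truth <- truthTable(run@experiment)
  calls <- interactorCalls(run)
  m <- merge(calls, truth, by = "accession")
  induced <- m$true_class == "induced"
  expect_gt(mean(m$call[induced] == "induced_interactor"), 0.8)
  expect_true(all(m$call[m$true_class == "bead"] != "induced_interactor"))
})
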