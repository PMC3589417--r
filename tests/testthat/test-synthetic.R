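test_that("tryptic digestion applies the K/R-not-before-P rule", {
  expect_identical(digestProtein("AAAA", 0)$peptide, "AAAA")
  expect_identical(digestProtein("GLKAKRPC", 0)$peptide, c("GLK", "AK", "RPC"))
  expect_setequal(digestProtein("GLKAK", 1)$peptide, c("GLK", "AK", "GLKAK"))
  expect_error(digestProtein("GLX", 0), class = "invalidArgument")
})

test_that("digestion matches the brute-force substring oracle on random sequences", {
  set.seed(101)
  for (k in 1:40) {
    s <- randomSeq(sample(5:60, 1))
    m <- sample(0:2, 1)
    expect_identical(sort(digestProtein(s, m)$peptide), bruteDigest(s, m),
                     info = sprintf("seq=%s missed=%d", s, m))
  }
})

test_that("zero-missed peptides concatenate back to the input sequence", {
  set.seed(202)
  for (k in 1:20) {
    s <- randomSeq(sample(10:80, 1))
    dig <- digestProtein(s, 0)
    expect_identical(paste(dig$peptide[order(dig$start)], collapse = ""), s)
  }
})

test_that("leucine counting is exact", {
  expect_identical(countLeucines(c("GLK", "AAAA", "LLGLR")), c(1L, 0L, 3L))
})

test_that("simulated XIC pairs honour the label offset and the noise contract", {
  set.seed(5)
  p <- simulateXicPair("GLK", 2, true_ratio = 2.0, noise_rsd = 0)
  expect_equal(p$area[1], 2 * p$area[2])
  expect_equal(p$mz[2] - p$mz[1], mzOffset(1, 2))
  p1 <- simulateXicPair("LLGLR", 1, true_ratio = 1.0, noise_rsd = 0)
  expect_equal(p1$area[1], p1$area[2])
  expect_equal(p1$mz[2] - p1$mz[1], mzOffset(3, 1))
  expect_error(simulateXicPair("AAAK", 2, 1.0, 0.1), class = "noPair")
})

test_that("generator output is byte-identical under a fixed seed", {
  e1 <- generateExperiment(smallConfig(seed = 7))
  e2 <- generateExperiment(smallConfig(seed = 7))
  expect_identical(psmTable(e1), psmTable(e2))
  expect_identical(featureTable(e1), featureTable(e2))
  expect_identical(truthTable(e1), truthTable(e2))
  expect_identical(as.character(proteome(e1)), as.character(proteome(e2)))
  e3 <- generateExperiment(smallConfig(seed = 8))
  expect_false(identical(featureTable(e1), featureTable(e3)))
})

test_that("zero-noise generation reproduces true enrichments in every peptide pair", {
  cfg <- smallConfig(seed = 3, peptide_noise_rsd = 0)
  expt <- generateExperiment(cfg)
  truth <- truthTable(expt)
  feats <- featureTable(expt)
  for (pid in unique(feats$pair_id)) {
    pr <- feats[feats$pair_id == pid, ]
    acc <- sub("_p[0-9]+$", "", pid)
    expect_equal(pr$area[pr$isotope == "light"] / pr$area[pr$isotope == "heavy"],
                 truth$true_enrichment[truth$accession == acc],
                 tolerance = 1e-12)
  }
})

test_that("generated experiments satisfy the container invariants", {
  expt <- generateExperiment(smallConfig(seed = 9))
  expect_true(validObject(expt))
  psms <- psmTable(expt)
  tgt <- psms[!psms$is_decoy, ]
  expect_true(all(tgt$accession %in% names(proteome(expt))))
  expect_true(all(grepl("^REV_", psms$accession[psms$is_decoy])))
  # every feature traces to a generated pair, two features per pair
  expect_true(all(table(featureTable(expt)$pair_id) == 2L))
  # proteins have >= 2 quantifiable leucine peptides by construction
  feats <- featureTable(expt)
  acc <- sub("_p[0-9]+$", "", feats$pair_id)
  n_pep <- tapply(feats$peptide, acc, function(p) length(unique(p)))
  expect_true(all(n_pep >= 2))
  expect_true(startsWith(baitAccession(expt), "BAIT"))
})

test_that("an all-zero class configuration is refused", {
  cfg <- syntheticConfig(seed = 1, n_bait = 0, n_induced = 0,
                         n_constitutive = 0, n_nonspecific = 0,
                         n_bead = 0, n_keratin = 0)
  expect_error(generateExperiment(cfg), class = "emptyDataset")
})
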