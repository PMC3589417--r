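test_that("isotope pairing matches at the label offset within tolerance", {
  f <- data.frame(feature_id = c("a", "b"), peptide = "GLK", charge = 1L,
                  mz = c(500.000, 503.0188), rt_apex = c(30, 30.02),
                  area = c(150, 100))
  p <- pairFeatures(f)
  expect_equal(nrow(p$pairs), 1L)
  expect_identical(p$pairs$light_id, "a")
  expect_identical(p$pairs$heavy_id, "b")
  # outside the 0.01 Da tolerance: no pair
  f$mz[2] <- 503.040
  p2 <- pairFeatures(f)
  expect_equal(nrow(p2$pairs), 0L)
  expect_equal(nrow(p2$singletons), 2L)
})

test_that("ambiguous heavy candidates resolve to nearest m/z then nearest RT", {
  f <- data.frame(feature_id = c("L", "H1", "H2"), peptide = "GLK", charge = 1L,
                  mz = c(500.000, 503.0188, 503.0250),
                  rt_apex = c(30, 30.1, 30.0), area = c(1, 1, 1))
  p <- pairFeatures(f)$pairs
  expect_equal(nrow(p), 1L)
  expect_identical(p$heavy_id, "H1")
  # equal m/z error: RT decides
  f2 <- data.frame(feature_id = c("L", "H1", "H2"), peptide = "GLK", charge = 1L,
                   mz = c(500.000, 503.0188, 503.0188),
                   rt_apex = c(30, 30.3, 30.05), area = c(1, 1, 1))
  expect_identical(pairFeatures(f2)$pairs$heavy_id, "H2")
})

test_that("pairing respects the co-elution window and charge scaling of tolerance", {
  f <- data.frame(feature_id = c("a", "b"), peptide = "GLK", charge = 1L,
                  mz = c(500.000, 503.0188), rt_apex = c(30, 31.2),
                  area = c(1, 1))
  expect_equal(nrow(pairFeatures(f, rt_window = 0.5)$pairs), 0L)
  # at 2+ the 0.01 Da tolerance becomes 0.005 in m/z space
  f2 <- data.frame(feature_id = c("a", "b"), peptide = "GLK", charge = 2L,
                   mz = c(500.000, 500.000 + 3.0188 / 2 + 0.006),
                   rt_apex = c(30, 30), area = c(1, 1))
  expect_equal(nrow(pairFeatures(f2)$pairs), 0L)
  f2$mz[2] <- 500.000 + 3.0188 / 2 + 0.004
  expect_equal(nrow(pairFeatures(f2)$pairs), 1L)
})

test_that("pairing recovers every generated pair on synthetic data", {
  expt <- generateExperiment(smallConfig(seed = 21))
  feats <- featureTable(expt)
  p <- pairFeatures(feats)
  # evaluate recall over species whose (peptide, charge) is unambiguous
  sp <- paste(feats$peptide, feats$charge)
  unambig <- names(which(table(sp) == 2L))
  expected <- unique(feats$pair_id[sp %in% unambig])
  got <- feats$pair_id[match(p$pairs$light_id, feats$feature_id)]
  got_h <- feats$pair_id[match(p$pairs$heavy_id, feats$feature_id)]
  ok <- p$pairs[got == got_h, ]
  expect_true(all(expected %in% feats$pair_id[match(ok$light_id, feats$feature_id)]))
  # and orientation is right: light area / heavy area near the true ratio
  truth <- truthTable(expt)
  acc <- sub("_p[0-9]+$", "", got)
  ratio <- p$pairs$light_area / p$pairs$heavy_area
  tr <- truth$true_enrichment[match(acc, truth$accession)]
  expect_true(all(abs(log(ratio / tr)) < 1))
})

test_that("peptide ratios are light over heavy and require both partners", {
  p <- data.frame(peptide = c("GLK", "GLLK"), charge = 1L, n_leu = c(1L, 2L),
                  light_area = c(150, 97), heavy_area = c(100, 100))
  expect_equal(peptideRatios(p)$ratio_lh, c(1.5, 0.97))
  p$heavy_area[1] <- 0
  expect_error(peptideRatios(p), class = "missingPartner")
})

test_that("mean-dialect aggregation gives mean, sample SD, RSD and the manual flag", {
  a <- aggregateProtein(c(1.2, 1.4, 1.0), dialect = "mean")
  expect_equal(a$ratio_mean, 1.2)
  expect_equal(a$sd, 0.2)
  expect_equal(a$rsd, 0.2 / 1.2)
  expect_false(a$manual_check)
  expect_true(aggregateProtein(c(1, 2, 3))$manual_check)  # rsd 0.816 > 0.20
  s <- aggregateProtein(1.5)
  expect_equal(c(s$ratio, s$sd, s$rsd), c(1.5, 0, 0))
  expect_error(aggregateProtein(numeric(0)), class = "invalidArgument")
})

test_that("median-dialect aggregation collapses to unique peptides with a log-normal CV", {
  a <- aggregateProtein(c(2, 2, 2), dialect = "median")
  expect_equal(a$ratio, 2)
  expect_equal(a$cv_lognormal, 0)
  # two charge species of one peptide collapse to their median first
  b <- aggregateProtein(c(1.0, 2.0, 4.0), peptides = c("AGLK", "AGLK", "VLLR"),
                        dialect = "median")
  expect_equal(b$ratio_median, median(c(1.5, 4.0)))
  expect_equal(b$n_leu_peptides, 2L)
  expect_equal(b$cv_lognormal, sqrt(exp(sd(log(c(1.5, 4)))^2) - 1))
})

test_that("log-normal CV is non-negative and zero only for identical ratios", {
  set.seed(9)
  for (k in 1:20) {
    r <- exp(rnorm(sample(2:8, 1), 0, 0.3))
    a <- aggregateProtein(r, dialect = "median")
    expect_gte(a$cv_lognormal, 0)
    if (length(unique(r)) > 1L) expect_gt(a$cv_lognormal, 0)
  }
  expect_equal(aggregateProtein(rep(1.7, 5))$cv_lognormal, 0)
})

test_that("bait normalization rescales every ratio and fixes the bait at 1", {
  q <- data.frame(accession = c("BAIT", "P1"), ratio = c(0.97, 1.36))
  n <- normalizeToBait(q, "BAIT")
  expect_equal(n$normalized_ratio, c(1, 1.36 / 0.97))
  expect_identical(n$normalized_ratio[1], 1)
  # bait at exactly 1 makes normalization the identity
  q2 <- data.frame(accession = c("BAIT", "P1"), ratio = c(1.0, 1.36))
  expect_equal(normalizeToBait(q2, "BAIT")$normalized_ratio, c(1, 1.36))
  expect_error(normalizeToBait(q, "ABSENT"), class = "missingBait")
})

test_that("protein quantitation maps pair ratios through accepted unique peptides", {
  expt <- generateExperiment(smallConfig(seed = 31, peptide_noise_rsd = 0))
  flt <- filterPsms(psmTable(expt))
  prot <- inferProteins(flt$accepted)
  prs <- pairFeatures(featureTable(expt))
  q <- quantifyProteins(prs$pairs, flt$accepted, proteins = prot$accession)
  truth <- truthTable(expt)
  tr <- truth$true_enrichment[match(q$accession, truth$accession)]
  expect_equal(q$ratio, tr, tolerance = 1e-12)
  qm <- quantifyProteins(prs$pairs, flt$accepted, proteins = prot$accession,
                         dialect = "median")
  expect_equal(qm$ratio, tr, tolerance = 1e-12)
  expect_true(all(q$sd < 1e-12))
})
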