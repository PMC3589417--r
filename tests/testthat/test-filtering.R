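test_that("Xcorr thresholds are charge-dependent with clamping above 3+", {
  expect_equal(xcorrThreshold(1), 1.9)
  expect_equal(xcorrThreshold(2), 2.6)
  expect_equal(xcorrThreshold(3), 3.6)
  expect_equal(xcorrThreshold(5), 3.6)
  expect_error(xcorrThreshold(0), class = "invalidArgument")
})

test_that("PSM acceptance applies all four rules with the documented boundaries", {
  expect_equal(filterPsms(makePsm())$report$n_accepted, 1L)
  # Xcorr boundary is inclusive
  expect_equal(filterPsms(makePsm(xcorr = 2.6))$report$n_accepted, 1L)
  # single-rule toggling: each rule alone rejects
  expect_equal(filterPsms(makePsm(delta_cn = 0.05))$report$n_accepted, 0L)
  expect_equal(filterPsms(makePsm(delta_cn = 0.1))$report$n_accepted, 0L)  # strict >
  expect_equal(filterPsms(makePsm(probability = 0.001))$report$n_accepted, 0L)  # strict <
  expect_equal(filterPsms(makePsm(xcorr = 2.59))$report$n_accepted, 0L)
  expect_equal(filterPsms(makePsm(is_keratin = TRUE))$report$n_accepted, 0L)
  expect_equal(filterPsms(makePsm(accession = "Keratin_like"))$report$n_accepted, 0L)
  # decoys passing the score rules are retained but flagged
  r <- filterPsms(rbind(makePsm(), makePsm(accession = "REV_P1", is_decoy = TRUE)))
  expect_equal(r$report$n_accepted_decoy, 1L)
  expect_equal(r$report$n_accepted_target, 1L)
})

test_that("tightening any threshold never increases the accepted count", {
  set.seed(33)
  for (k in 1:15) {
    psms <- randomPsmTable(200)
    base <- filterPsms(psms)$report$n_accepted
    expect_lte(filterPsms(psms, delta_cn_min = 0.2)$report$n_accepted, base)
    expect_lte(filterPsms(psms, probability_max = 1e-4)$report$n_accepted, base)
    expect_lte(filterPsms(psms, delta_cn_min = 0.3,
                          probability_max = 1e-5)$report$n_accepted, base)
  }
})

test_that("filtering is idempotent", {
  set.seed(44)
  psms <- randomPsmTable(300)
  once <- filterPsms(psms)$accepted
  twice <- filterPsms(once)
  expect_identical(twice$accepted, once)
  expect_equal(twice$report$n_accepted, nrow(once))
})

test_that("target-decoy FDR estimation handles the boundary cases", {
  expect_equal(estimateFdr(data.frame(is_decoy = rep(c(TRUE, FALSE), c(2, 198)))),
               2 / 198)
  expect_equal(estimateFdr(data.frame(is_decoy = rep(FALSE, 100))), 0)
  expect_equal(estimateFdr(data.frame(is_decoy = logical(0))), 0)
  expect_error(estimateFdr(data.frame(is_decoy = TRUE)), class = "undefinedFdr")
  # doubled-decoy variant
  expect_equal(estimateFdr(data.frame(is_decoy = rep(c(TRUE, FALSE), c(2, 198))),
                           doubled = TRUE), 4 / 200)
})

test_that("protein inference requires two unique peptides and groups shared sets", {
  psms <- rbind(makePsm(peptide = "GLK"), makePsm(peptide = "AVLR"),
                makePsm(peptide = "GLK", accession = "P2"),
                makePsm(peptide = "GLK", accession = "P2"),
                makePsm(peptide = "GLK", accession = "REV_P9", is_decoy = TRUE),
                makePsm(peptide = "AVLR", accession = "REV_P9", is_decoy = TRUE))
  inf <- inferProteins(psms)
  expect_identical(inf$accession, "P1")  # P2 has one unique sequence; decoys never count
  # two proteins sharing every peptide end up in one ambiguity group
  shared <- rbind(makePsm(peptide = "GLK", accession = "A"),
                  makePsm(peptide = "AVLR", accession = "A"),
                  makePsm(peptide = "GLK", accession = "B"),
                  makePsm(peptide = "AVLR", accession = "B"))
  inf2 <- inferProteins(shared)
  expect_setequal(inf2$accession, c("A", "B"))
  expect_equal(length(unique(inf2$group)), 1L)
  expect_error(inferProteins(psms, min_unique_peptides = 0),
               class = "invalidArgument")
})
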