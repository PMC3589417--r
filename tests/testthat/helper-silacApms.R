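# shared fixtures and independent oracles

# Brute-force digestion oracle: tests every substring against the cleavage
# rule directly (cut after K/R unless followed by P), independent of the
# segment-joining implementation in digestProtein().
bruteDigest <- function(sequence, max_missed) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  is_cut <- vapply(seq_len(n), function(p)
    p < n && res[p] %in% c("K", "R") && res[p + 1L] != "P", logical(1))
  out <- character()
  for (i in seq_len(n)) {
    if (!(i == 1L || is_cut[i - 1L])) next
    for (j in i:n) {
      if (!(j == n || is_cut[j])) next
      internal <- if (j > i) sum(is_cut[i:(j - 1L)]) else 0L
      if (internal <= max_missed)
        out <- c(out, paste(res[i:j], collapse = ""))
    }
  }
  sort(out)
}

# random amino-acid sequence over the 20 standard residues, K/R/P/L-rich
# enough to exercise the cleavage rule
randomSeq <- function(len) {
  paste(sample(c("A", "G", "S", "V", "L", "K", "R", "P", "E", "D"),
               len, replace = TRUE,
               prob = c(1, 1, 1, 1, 2, 2, 2, 1.5, 1, 1)), collapse = "")
}

makePsm <- function(peptide = "GLK", charge = 2L, xcorr = 2.7,
                    delta_cn = 0.15, probability = 1e-4, accession = "P1",
                    is_decoy = FALSE, is_keratin = FALSE) {
  data.frame(psm_id = "p", peptide = peptide, charge = charge, xcorr = xcorr,
             delta_cn = delta_cn, probability = probability,
             accession = accession, is_decoy = is_decoy,
             is_keratin = is_keratin)
}

randomPsmTable <- function(n) {
  data.frame(psm_id = sprintf("p%d", seq_len(n)),
             peptide = replicate(n, randomSeq(8)),
             charge = sample(1:4, n, replace = TRUE),
             xcorr = runif(n, 0.5, 5),
             delta_cn = runif(n, 0, 0.4),
             probability = 10^runif(n, -6, 0),
             accession = sample(c("P1", "P2", "KERATIN_9", "REV_P1"), n, TRUE),
             is_decoy = runif(n) < 0.2,
             is_keratin = FALSE)
}

smallConfig <- function(seed = 11, ...) {
  syntheticConfig(seed = seed, n_induced = 4L, n_constitutive = 4L,
                  n_nonspecific = 4L, n_bead = 2L, n_keratin = 1L, ...)
}
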