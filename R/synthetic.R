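## Synthetic dual-tagging AP-MS experiment generator.
## Emulates the statistical structure the downstream analysis assumes:
## a bait near L/H = 1, induced interactors enriched beyond the cutoff,
## constitutive/nonspecific binders near 1, sticky bead-proteome
## contaminants with large ratios, log-normal peptide-level ratio noise,
## charge-dependent identification scores and reversed-sequence decoys.

## residue sampling weights: roughly natural frequencies, with L/K/R
## guaranteed common enough that tryptic leucine peptides are plentiful
.RESIDUE_FREQ <- c(
  A = 0.075, R = 0.052, N = 0.043, D = 0.052, C = 0.018, E = 0.063,
  Q = 0.041, G = 0.071, H = 0.022, I = 0.053, L = 0.100, K = 0.060,
  M = 0.022, F = 0.039, P = 0.045, S = 0.071, T = 0.056, W = 0.012,
  Y = 0.032, V = 0.063)

.CATEGORIES <- c("gene transcriptional regulation", "signal transduction",
                 "DNA/RNA binding and splicing", "protein degradation",
                 "protein transport", "cytoskeleton/cell motility",
                 "cell cycle", "apoptosis", "nucleoside metabolic process",
                 "protein translation")
.CATEGORY_W <- c(14, 14, 20, 12, 8, 8, 6, 6, 6, 6) / 100

#' Configuration for the synthetic experiment generator
#'
#' Defines the study conditions a generated experiment emulates: how many
#' proteins of each interaction class, the bait's true L/H (default 0.97,
#' the near-1:1 mixing control), the enrichment ranges for induced
#' interactors and bead-proteome contaminants, the log-normal peptide-level
#' ratio noise (default RSD 0.12), tryptic digestion with up to 2 missed
#' cleavages, the charge distribution, and the score distributions that
#' separate correct identifications from decoy/false matches.
#'
#' @param seed Integer random seed; identical seeds give identical datasets.
#' @param n_bait,n_induced,n_constitutive,n_nonspecific,n_bead,n_keratin
#'   Protein counts per class (keratins are nonspecific contaminants whose
#'   PSMs carry the keratin flag).
#' @param bait_enrichment True L/H of the bait (default 0.97).
#' @param induced_range,bead_range Ranges the true enrichment of induced /
#'   bead proteins is drawn from (uniform).
#' @param peptide_noise_rsd Relative SD of peptide-level L/H ratios
#'   (log-normal noise; default 0.12).
#' @param peptides_per_protein Integer range: number of quantifiable
#'   leucine-containing peptides sampled per protein.
#' @param seq_length Integer range of protein sequence lengths.
#' @param max_missed_cleavages Missed cleavages allowed in digestion.
#' @param decoy_fraction Number of incorrect PSMs drawn as a fraction of
#'   correct PSMs; split evenly between reversed-accession decoys and false
#'   target matches.
#' @param charge_probs Probabilities for charges 1+, 2+, 3+.
#' @param rt_range Retention-time window in minutes features are placed in.
#' @param rt_jitter_sd SD (minutes) of the heavy partner's co-elution offset.
#' @param base_area_meanlog,base_area_sdlog Log-normal parameters of the
#'   heavy-feature integrated area.
#' @param score_distributions Two lists (\code{correct}, \code{incorrect})
#'   parameterising the Xcorr offset from the charge threshold, the deltaCn
#'   normal, and the log10 probability-score uniform range.
#'
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @examples
#' cfg <- syntheticConfig(seed = 7, n_induced = 5)
#' @export
syntheticConfig <- function(seed = 1L,
                            n_bait = 1L,
                            n_induced = 30L,
                            n_constitutive = 60L,
                            n_nonspecific = 92L,
                            n_bead = 15L,
                            n_keratin = 2L,
                            bait_enrichment = 0.97,
                            induced_range = c(1.5, 4.0),
                            bead_range = c(2.0, 8.0),
                            peptide_noise_rsd = 0.12,
                            peptides_per_protein = c(3L, 10L),
                            seq_length = c(180L, 420L),
                            max_missed_cleavages = 2L,
                            decoy_fraction = 0.3,
                            charge_probs = c(0.1, 0.6, 0.3),
                            rt_range = c(10, 110),
                            rt_jitter_sd = 0.05,
                            base_area_meanlog = log(1e6),
                            base_area_sdlog = 0.5,
                            score_distributions = list(
                              correct = list(xcorr_shift = 1.5, xcorr_sd = 0.5,
                                             delta_cn_mean = 0.25, delta_cn_sd = 0.07,
                                             log10_prob_range = c(-6, -3.3)),
                              incorrect = list(xcorr_shift = -0.7, xcorr_sd = 0.5,
                                               delta_cn_mean = 0.08, delta_cn_sd = 0.05,
                                               log10_prob_range = c(-4, 0)))) {
  for (nm in c("n_bait", "n_induced", "n_constitutive", "n_nonspecific",
               "n_bead", "n_keratin"))
    .assertCount(get(nm), nm)
  .assertScalar(peptide_noise_rsd, "peptide_noise_rsd", lower = 0)
  .assertScalar(bait_enrichment, "bait_enrichment", lower = 0, strict = TRUE)
  .assertScalar(decoy_fraction, "decoy_fraction", lower = 0)
  .assertCount(max_missed_cleavages, "max_missed_cleavages")
  if (length(charge_probs) != 3L || any(charge_probs < 0) || sum(charge_probs) <= 0)
    .apmsStop("invalidArgument", "'charge_probs' must be 3 non-negative weights")
  structure(list(seed = as.integer(seed), n_bait = as.integer(n_bait),
                 n_induced = as.integer(n_induced),
                 n_constitutive = as.integer(n_constitutive),
                 n_nonspecific = as.integer(n_nonspecific),
                 n_bead = as.integer(n_bead), n_keratin = as.integer(n_keratin),
                 bait_enrichment = bait_enrichment,
                 induced_range = induced_range, bead_range = bead_range,
                 peptide_noise_rsd = peptide_noise_rsd,
                 peptides_per_protein = as.integer(peptides_per_protein),
                 seq_length = as.integer(seq_length),
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 decoy_fraction = decoy_fraction,
                 charge_probs = charge_probs / sum(charge_probs),
                 rt_range = rt_range, rt_jitter_sd = rt_jitter_sd,
                 base_area_meanlog = base_area_meanlog,
                 base_area_sdlog = base_area_sdlog,
                 score_distributions = score_distributions),
            class = "SyntheticConfig")
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine or arginine except when the next residue is
#' proline, and enumerates all peptides with up to \code{max_missed}
#' internal missed cleavage sites. The zero-missed peptides concatenate, in
#' order, back to the input sequence.
#'
#' @param sequence Amino-acid string over the 20 standard residues.
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @return \code{data.frame} with columns \code{peptide}, \code{start},
#'   \code{end}, \code{missed}.
#' @examples
#' digestProtein("GLKAKRPC", max_missed = 0)$peptide  # "GLK" "AK" "RPC"
#' @export
digestProtein <- function(sequence, max_missed = 2L) {
  res <- .checkSequence(sequence)
  .assertCount(max_missed, "max_missed")
  n <- length(res)
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n & res[pmin(cut + 1L, n)] != "P"]
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  nseg <- length(starts)
  out <- vector("list", max_missed + 1L)
  for (m in 0:max_missed) {
    i <- seq_len(max(0L, nseg - m))
    if (!length(i)) break
    out[[m + 1L]] <- data.frame(
      start = starts[i], end = ends[i + m], missed = m)
  }
  dig <- do.call(rbind, out)
  dig$peptide <- vapply(seq_len(nrow(dig)), function(k)
    paste(res[dig$start[k]:dig$end[k]], collapse = ""), character(1))
  dig[order(dig$missed, dig$start), c("peptide", "start", "end", "missed")]
}

#' Count leucine residues in a peptide
#'
#' Leucine is the labeled residue: only leucine-containing peptides form
#' light/heavy isotope pairs and contribute L/H ratios.
#'
#' @param peptide Amino-acid string (vectorised).
#' @return Integer count(s) of L residues.
#' @examples
#' countLeucines(c("GLK", "AAAA", "LLGLR"))  # 1 0 3
#' @export
countLeucines <- function(peptide) {
  vapply(peptide, function(p) {
    .checkSequence(p)
    nchar(p) - nchar(gsub("L", "", p, fixed = TRUE))
  }, integer(1), USE.NAMES = FALSE)
}

#' Simulate one light/heavy XIC feature pair
#'
#' Draws the paired extracted-ion-chromatogram features of a
#' leucine-containing peptide: the heavy feature sits at the light m/z plus
#' the label offset \code{mzOffset(n_leu, charge)}, and the area ratio
#' light/heavy is log-normally distributed around \code{true_ratio} with
#' relative SD \code{noise_rsd} (mean-unbiased parameterisation; with zero
#' noise the ratio is exact). Uses the current RNG stream.
#'
#' @param peptide Leucine-containing peptide sequence.
#' @param charge Charge state.
#' @param true_ratio True L/H ratio (> 0).
#' @param noise_rsd Relative SD of the ratio (>= 0).
#' @param base_area Heavy-feature integrated area (> 0).
#' @param rt Light-feature retention apex in minutes (drawn uniformly in
#'   10..110 when NULL).
#' @param rt_jitter_sd SD of the heavy partner's retention offset, minutes.
#' @param masses A \code{\link{modificationMasses}} list.
#' @return Two-row \code{data.frame} (light then heavy) with columns
#'   \code{isotope}, \code{peptide}, \code{charge}, \code{mz},
#'   \code{rt_apex}, \code{area}; the realised L/H ratio is in
#'   \code{attr(, "ratio_lh")}.
#' @examples
#' set.seed(1)
#' simulateXicPair("GLK", 2, true_ratio = 2, noise_rsd = 0)
#' @export
simulateXicPair <- function(peptide, charge, true_ratio, noise_rsd,
                            base_area = 1e6, rt = NULL, rt_jitter_sd = 0.05,
                            masses = modificationMasses()) {
  n_leu <- countLeucines(peptide)
  if (n_leu < 1L)
    .apmsStop("noPair", "peptide has no leucine: no isotope pair exists")
  .assertScalar(true_ratio, "true_ratio", lower = 0, strict = TRUE)
  .assertScalar(noise_rsd, "noise_rsd", lower = 0)
  .assertScalar(base_area, "base_area", lower = 0, strict = TRUE)
  s <- sqrt(log1p(noise_rsd^2))
  ratio <- if (s > 0) true_ratio * exp(stats::rnorm(1, -s^2 / 2, s)) else true_ratio
  if (is.null(rt)) rt <- stats::runif(1, 10, 110)
  light_mz <- .peptideMz(peptide, charge)
  out <- data.frame(
    isotope = c("light", "heavy"),
    peptide = peptide, charge = as.integer(charge),
    mz = c(light_mz, light_mz + mzOffset(n_leu, charge, masses)),
    rt_apex = c(rt, rt + stats::rnorm(1, 0, rt_jitter_sd)),
    area = c(ratio * base_area, base_area))
  attr(out, "ratio_lh") <- ratio
  out
}

## random protein sequence with >=2 distinct quantifiable (leucine-bearing,
## length 6-30) fully-tryptic peptides; resamples until satisfied
.randomProtein <- function(len) {
  for (i in 1:100) {
    seqc <- paste(sample(names(.RESIDUE_FREQ), len, replace = TRUE,
                         prob = .RESIDUE_FREQ), collapse = "")
    qp <- .quantifiablePeptides(seqc)
    if (length(qp) >= 2L) return(seqc)
  }
  .apmsStop("generatorFailure", "could not generate a quantifiable sequence")
}

.quantifiablePeptides <- function(sequence) {
  dig <- digestProtein(sequence, max_missed = 0L)
  pep <- unique(dig$peptide)
  pep <- pep[nchar(pep) >= 6 & nchar(pep) <= 30]
  pep[countLeucines(pep) >= 1L]
}

.drawScores <- function(charges, par) {
  n <- length(charges)
  data.frame(
    xcorr = xcorrThreshold(charges) + stats::rnorm(n, par$xcorr_shift, par$xcorr_sd),
    delta_cn = pmax(0, stats::rnorm(n, par$delta_cn_mean, par$delta_cn_sd)),
    probability = 10^stats::runif(n, par$log10_prob_range[1], par$log10_prob_range[2]))
}

#' Generate a complete synthetic dual-tagging AP-MS experiment
#'
#' Produces a \code{\linkS4class{SilacExperiment}} with known ground truth:
#' random tryptic-digestible protein sequences per interaction class, one
#' correct PSM per observed peptide species with charge-dependent scores,
#' reversed-accession decoy PSMs and false target matches at the configured
#' fraction, and one light/heavy XIC feature pair per leucine-containing
#' peptide species with log-normal ratio noise. Output is deterministic
#' given the config seed.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @return A \code{\linkS4class{SilacExperiment}}. The feature table carries
#'   ground-truth helper columns \code{pair_id} and \code{isotope} (ignored
#'   by the pairing algorithm); the PSM table carries \code{is_true_match}.
#'   The truth table includes a \code{category} column used as the default
#'   functional annotation.
#' @examples
#' expt <- generateExperiment(syntheticConfig(seed = 1, n_induced = 3,
#'   n_constitutive = 3, n_nonspecific = 3, n_bead = 1, n_keratin = 0))
#' expt
#' @export
generateExperiment <- function(config = syntheticConfig()) {
  if (!inherits(config, "SyntheticConfig"))
    .apmsStop("invalidArgument", "'config' must come from syntheticConfig()")
  n_total <- config$n_bait + config$n_induced + config$n_constitutive +
    config$n_nonspecific + config$n_bead + config$n_keratin
  if (n_total == 0L)
    .apmsStop("emptyDataset", "all protein class counts are zero")
  set.seed(config$seed)

  cls <- c(rep("bait", config$n_bait), rep("induced", config$n_induced),
           rep("constitutive", config$n_constitutive),
           rep("nonspecific", config$n_nonspecific),
           rep("bead", config$n_bead), rep("nonspecific", config$n_keratin))
  is_ker <- c(rep(FALSE, n_total - config$n_keratin), rep(TRUE, config$n_keratin))
  acc <- character(n_total)
  idx <- stats::ave(seq_len(n_total), paste(cls, is_ker), FUN = seq_along)
  acc[cls == "bait" & !is_ker] <- sprintf("BAIT_%04d", idx[cls == "bait" & !is_ker])
  acc[cls == "induced"] <- sprintf("IND_%04d", idx[cls == "induced"])
  acc[cls == "constitutive"] <- sprintf("CON_%04d", idx[cls == "constitutive"])
  acc[cls == "nonspecific" & !is_ker] <-
    sprintf("NSP_%04d", idx[cls == "nonspecific" & !is_ker])
  acc[cls == "bead"] <- sprintf("BEAD_%04d", idx[cls == "bead"])
  acc[is_ker] <- sprintf("KERATIN_%04d", idx[is_ker])

  enr <- numeric(n_total)
  enr[cls == "bait"] <- config$bait_enrichment
  enr[cls %in% c("constitutive", "nonspecific")] <- 1.0
  enr[cls == "induced"] <- stats::runif(sum(cls == "induced"),
                                        config$induced_range[1], config$induced_range[2])
  enr[cls == "bead"] <- stats::runif(sum(cls == "bead"),
                                     config$bead_range[1], config$bead_range[2])

  lens <- sample(config$seq_length[1]:config$seq_length[2], n_total, replace = TRUE)
  seqs <- vapply(lens, .randomProtein, character(1))
  names(seqs) <- acc

  category <- sample(.CATEGORIES, n_total, replace = TRUE, prob = .CATEGORY_W)
  truth <- data.frame(accession = acc, true_class = cls,
                      true_enrichment = enr, category = category,
                      stringsAsFactors = FALSE)

  psm_list <- vector("list", n_total)
  feat_list <- vector("list", n_total)
  rng <- config$peptides_per_protein
  for (i in seq_len(n_total)) {
    qp <- .quantifiablePeptides(seqs[i])
    npep <- min(length(qp), sample(rng[1]:rng[2], 1L))
    pep <- sample(qp, npep)
    charges <- sample(1:3, npep, replace = TRUE, prob = config$charge_probs)
    feats <- vector("list", npep)
    for (j in seq_len(npep)) {
      pr <- simulateXicPair(pep[j], charges[j], enr[i],
                            config$peptide_noise_rsd,
                            base_area = stats::rlnorm(1, config$base_area_meanlog,
                                                      config$base_area_sdlog),
                            rt = stats::runif(1, config$rt_range[1], config$rt_range[2]),
                            rt_jitter_sd = config$rt_jitter_sd)
      pr$pair_id <- sprintf("%s_p%02d", acc[i], j)
      feats[[j]] <- pr
    }
    feat_list[[i]] <- do.call(rbind, feats)
    sc <- .drawScores(charges, config$score_distributions$correct)
    psm_list[[i]] <- data.frame(
      peptide = pep, charge = charges, xcorr = sc$xcorr,
      delta_cn = sc$delta_cn, probability = sc$probability,
      accession = acc[i], is_decoy = FALSE, is_keratin = is_ker[i],
      is_true_match = TRUE, stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, psm_list)
  features <- do.call(rbind, feat_list)

  ## incorrect matches: half reversed-accession decoys, half false target hits
  n_correct <- nrow(psms)
  n_inc <- round(config$decoy_fraction * n_correct)
  if (n_inc > 0) {
    n_dec <- ceiling(n_inc / 2)
    inc_pep <- vapply(sample(8:15, n_inc, replace = TRUE), function(l)
      paste(sample(names(.RESIDUE_FREQ), l, replace = TRUE,
                   prob = .RESIDUE_FREQ), collapse = ""), character(1))
    inc_charge <- sample(1:3, n_inc, replace = TRUE, prob = config$charge_probs)
    sc_inc <- .drawScores(inc_charge, config$score_distributions$incorrect)
    inc <- data.frame(
      peptide = inc_pep, charge = inc_charge, xcorr = sc_inc$xcorr,
      delta_cn = sc_inc$delta_cn, probability = sc_inc$probability,
      accession = c(paste0("REV_", sample(acc, n_dec, replace = TRUE)),
                    sample(acc, n_inc - n_dec, replace = TRUE)),
      is_decoy = rep(c(TRUE, FALSE), c(n_dec, n_inc - n_dec)),
      is_keratin = FALSE, is_true_match = FALSE, stringsAsFactors = FALSE)
    psms <- rbind(psms, inc)
  }
  psms$psm_id <- sprintf("psm%06d", seq_len(nrow(psms)))
  psms <- psms[, c("psm_id", "peptide", "charge", "xcorr", "delta_cn",
                   "probability", "accession", "is_decoy", "is_keratin",
                   "is_true_match")]
  features$feature_id <- sprintf("f%06d", seq_len(nrow(features)))
  features <- features[, c("feature_id", "peptide", "charge", "mz", "rt_apex",
                           "area", "pair_id", "isotope")]
  rownames(psms) <- rownames(features) <- rownames(truth) <- NULL

  methods::new("SilacExperiment",
               proteome = Biostrings::AAStringSet(seqs),
               truth = truth, psms = psms, features = features,
               config = unclass(config))
}

#' Accession of the bait protein in a synthetic experiment
#' @param expt A \code{\linkS4class{SilacExperiment}} with ground truth.
#' @return The bait accession (first, if several).
#' @export
baitAccession <- function(expt) {
  tr <- truthTable(expt)
  b <- tr$accession[tr$true_class == "bait"]
  if (!length(b)) .apmsStop("missingBait", "experiment has no bait in its truth table")
  b[1L]
}
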