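## Enrichment-cutoff derivation and interactor classification.
## The cutoff is not a free parameter: it is derived from the measured
## peptide-ratio variability as a multiple (default 3) of the average RSD
## over proteins quantified with at least two leucine-containing peptides,
## then rounded conservatively upward (an average RSD of 12% gives
## 3 x 12% = 36%, i.e. a cutoff of L/H >= 1.40).

#' Average relative standard deviation over multi-peptide proteins
#'
#' Unweighted mean of the per-protein RSD, restricted to proteins
#' quantified with at least \code{min_peptides} distinct leucine-containing
#' peptides; single-peptide proteins carry no variability information and
#' are excluded.
#'
#' @param quants Quantitation \code{data.frame} with columns \code{rsd} and
#'   \code{n_leu_peptides}.
#' @param min_peptides Minimum distinct leucine-containing peptides
#'   (default 2).
#' @return Average RSD as a fraction.
#' @examples
#' averageRsd(data.frame(rsd = c(0.10, 0.14), n_leu_peptides = c(3, 2)))
#' @export
averageRsd <- function(quants, min_peptides = 2L) {
  q <- quants[quants$n_leu_peptides >= min_peptides, , drop = FALSE]
  if (!nrow(q))
    .apmsStop("noQualifyingProtein",
              "no protein with >= 2 leucine-containing peptides")
  mean(q$rsd)
}

#' Derive the L/H enrichment cutoff from ratio variability
#'
#' The raw threshold is \code{multiplier x avg_rsd} expressed in percent;
#' the cutoff ratio is \code{1 + multiplier x avg_rsd}, rounded upward to
#' the next 0.1 (\code{rounding = "ceil0.1"}, the default conservative
#' rule) or kept exact (\code{"none"}). Rounding never moves the cutoff
#' downward.
#'
#' @param avg_rsd Average RSD as a fraction (from \code{\link{averageRsd}}).
#' @param multiplier Dimensionless multiplier (default 3).
#' @param rounding \code{"ceil0.1"} or \code{"none"}.
#' @return A \code{\linkS4class{CutoffDerivation}}.
#' @examples
#' deriveCutoff(0.12)  # 36% -> L/H >= 1.40
#' @export
deriveCutoff <- function(avg_rsd, multiplier = 3, rounding = c("ceil0.1", "none")) {
  rounding <- match.arg(rounding)
  .assertScalar(avg_rsd, "avg_rsd", lower = 0)
  .assertScalar(multiplier, "multiplier", lower = 0)
  exact <- 1 + multiplier * avg_rsd
  cutoff <- switch(rounding,
                   ceil0.1 = ceiling(round(exact * 10, 9)) / 10,
                   none = exact)
  methods::new("CutoffDerivation", avgRsd = avg_rsd, multiplier = multiplier,
               rawThresholdPct = 100 * multiplier * avg_rsd,
               cutoffRatio = cutoff, rounding = rounding)
}

.CALLS <- c("bait", "induced_interactor", "bead_excluded", "non_induced")

#' Classify quantified proteins against the enrichment cutoff
#'
#' Partitions the quantified, bait-normalized set: the bait itself; proteins
#' at or above the cutoff that sit on the bead-proteome reference list
#' (matrix-binding contaminants, excluded); remaining proteins at or above
#' the cutoff (induced interactors); everything else (non-induced:
#' constitutive binders, nonspecific associations or disassociations,
#' indistinguishable from a single ratio). The boundary is inclusive
#' (normalized L/H >= cutoff).
#'
#' @param quants Quantitation \code{data.frame} with
#'   \code{normalized_ratio} filled (see \code{\link{normalizeToBait}}).
#' @param cutoff A \code{\linkS4class{CutoffDerivation}} or a numeric
#'   cutoff ratio.
#' @param bead_list Character vector of bead-proteome accessions.
#' @param bait_accession Accession of the bait.
#' @return \code{list(calls, summary)}: \code{calls} has one row per
#'   protein (\code{accession}, \code{normalized_ratio}, \code{call});
#'   \code{summary} is a named integer vector of counts per call plus
#'   \code{n_above_cutoff}.
#' @examples
#' q <- data.frame(accession = c("B", "P1", "P2"),
#'   normalized_ratio = c(1, 1.45, 1.39))
#' classifyInteractors(q, 1.40, character(), "B")$calls$call
#' @export
classifyInteractors <- function(quants, cutoff, bead_list = character(),
                                bait_accession) {
  cut <- if (methods::is(cutoff, "CutoffDerivation")) cutoff@cutoffRatio else cutoff
  .assertScalar(cut, "cutoff", lower = 0, strict = TRUE)
  if (any(is.na(quants$normalized_ratio)))
    .apmsStop("invalidArgument", "quants must be normalized to the bait first")
  above <- quants$normalized_ratio >= cut
  call <- ifelse(quants$accession == bait_accession, "bait",
          ifelse(above & quants$accession %in% bead_list, "bead_excluded",
          ifelse(above, "induced_interactor", "non_induced")))
  calls <- data.frame(accession = quants$accession,
                      normalized_ratio = quants$normalized_ratio,
                      call = factor(call, levels = .CALLS))
  summary <- c(table(calls$call),
               n_above_cutoff = sum(above))
  list(calls = calls, summary = summary)
}
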