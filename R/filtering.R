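## PSM acceptance rules, target-decoy FDR, protein inference.
## Acceptance follows the original search-engine filter set: a
## charge-dependent Xcorr floor, deltaCn strictly above 0.1, probability
## score strictly below 0.001, and exclusion of keratin contaminants.

.XCORR_BY_CHARGE <- c(1.9, 2.6, 3.6)

#' Charge-dependent Xcorr acceptance threshold
#'
#' 1.9 for 1+, 2.6 for 2+ and 3.6 for 3+ precursors; charges above 3+ are
#' clamped to the 3+ threshold (the usual Sequest-filter convention).
#'
#' @param charge Precursor charge (vectorised, integers >= 1).
#' @return Minimum acceptable Xcorr.
#' @examples
#' xcorrThreshold(1:4)  # 1.9 2.6 3.6 3.6
#' @export
xcorrThreshold <- function(charge) {
  if (!length(charge) || any(is.na(charge)) || any(charge < 1) ||
      any(charge != floor(charge)))
    .apmsStop("invalidArgument", "'charge' must be integer(s) >= 1")
  .XCORR_BY_CHARGE[pmin(as.integer(charge), 3L)]
}

#' Filter peptide-spectrum matches
#'
#' A PSM is accepted iff \code{xcorr >= xcorrThreshold(charge)},
#' \code{delta_cn > 0.1}, \code{probability < 0.001}, and it is not a
#' keratin contaminant (flag or accession keyword). Decoy PSMs passing the
#' score filters are retained, flagged, for FDR estimation but never enter
#' the quantifiable set.
#'
#' @param psms \code{data.frame} with at least columns \code{peptide},
#'   \code{charge}, \code{xcorr}, \code{delta_cn}, \code{probability},
#'   \code{accession}, \code{is_decoy}; \code{is_keratin} is derived from
#'   the accession keyword when absent.
#' @param delta_cn_min Strict lower bound for deltaCn (default 0.1).
#' @param probability_max Strict upper bound for the probability score
#'   (default 0.001).
#' @param keratin_keywords Case-insensitive substrings of the accession
#'   marking keratin contaminants (default \code{"keratin"}).
#' @return \code{list(accepted = data.frame, report = list)}. The report
#'   holds \code{n_input}, \code{n_accepted}, \code{n_accepted_target},
#'   \code{n_accepted_decoy}, per-rule rejection counts and
#'   \code{fdr_estimate}.
#' @examples
#' psms <- data.frame(psm_id = "p1", peptide = "GLK", charge = 2,
#'   xcorr = 2.7, delta_cn = 0.15, probability = 1e-4,
#'   accession = "P1", is_decoy = FALSE, is_keratin = FALSE)
#' filterPsms(psms)$report$n_accepted
#' @export
filterPsms <- function(psms, delta_cn_min = 0.1, probability_max = 0.001,
                       keratin_keywords = "keratin") {
  if (!nrow(psms)) {
    rep0 <- list(n_input = 0L, n_accepted = 0L, n_accepted_target = 0L,
                 n_accepted_decoy = 0L,
                 rejected = c(xcorr = 0L, delta_cn = 0L, probability = 0L,
                              keratin = 0L),
                 fdr_estimate = 0)
    return(list(accepted = psms, report = rep0))
  }
  ker <- if ("is_keratin" %in% names(psms)) psms$is_keratin else FALSE
  for (kw in keratin_keywords)
    ker <- ker | grepl(kw, psms$accession, ignore.case = TRUE)
  pass_x <- psms$xcorr >= xcorrThreshold(psms$charge)
  pass_d <- psms$delta_cn > delta_cn_min
  pass_p <- psms$probability < probability_max
  keep <- pass_x & pass_d & pass_p & !ker
  accepted <- psms[keep, , drop = FALSE]
  rownames(accepted) <- NULL
  fdr <- estimateFdr(accepted)
  report <- list(
    n_input = nrow(psms), n_accepted = nrow(accepted),
    n_accepted_target = sum(!accepted$is_decoy),
    n_accepted_decoy = sum(accepted$is_decoy),
    rejected = c(xcorr = sum(!pass_x), delta_cn = sum(!pass_d),
                 probability = sum(!pass_p), keratin = sum(ker)),
    fdr_estimate = fdr)
  list(accepted = accepted, report = report)
}

#' Target-decoy false discovery rate among accepted PSMs
#'
#' The simple target-decoy estimator \code{n_decoy / n_target}; the doubled
#' variant \code{2 * n_decoy / (n_target + n_decoy)} is available via
#' \code{doubled = TRUE}. Zero when the input is empty or has no decoys.
#'
#' @param accepted \code{data.frame} of accepted PSMs with an
#'   \code{is_decoy} column.
#' @param doubled Use the doubled-decoy estimator.
#' @return FDR estimate as a fraction.
#' @examples
#' estimateFdr(data.frame(is_decoy = rep(c(TRUE, FALSE), c(2, 198))))
#' @export
estimateFdr <- function(accepted, doubled = FALSE) {
  n_dec <- sum(accepted$is_decoy)
  n_tgt <- sum(!accepted$is_decoy)
  if (n_tgt == 0L) {
    if (n_dec == 0L) return(0)
    .apmsStop("undefinedFdr", "decoys accepted but no targets: FDR undefined")
  }
  if (doubled) 2 * n_dec / (n_tgt + n_dec) else n_dec / n_tgt
}

#' Infer reported proteins from accepted PSMs
#'
#' A protein is reported iff it is matched by at least
#' \code{min_unique_peptides} distinct peptide sequences among accepted
#' non-decoy PSMs. Proteins sharing an identical peptide set are reported
#' together as one ambiguity group.
#'
#' @param accepted Accepted PSM \code{data.frame} (from
#'   \code{\link{filterPsms}}).
#' @param min_unique_peptides Minimum distinct peptide sequences (default 2).
#' @return \code{data.frame} with columns \code{accession},
#'   \code{n_unique_peptides}, \code{group}; one row per reported protein,
#'   ordered by accession.
#' @examples
#' psms <- data.frame(peptide = c("GLK", "AVLR", "GLK"), charge = 2,
#'   accession = c("P1", "P1", "P2"), is_decoy = FALSE)
#' inferProteins(psms)
#' @export
inferProteins <- function(accepted, min_unique_peptides = 2L) {
  if (min_unique_peptides < 1L)
    .apmsStop("invalidArgument", "'min_unique_peptides' must be >= 1")
  tgt <- accepted[!accepted$is_decoy, , drop = FALSE]
  if (!nrow(tgt))
    return(data.frame(accession = character(), n_unique_peptides = integer(),
                      group = integer()))
  pepsets <- lapply(split(tgt$peptide, tgt$accession),
                    function(p) sort(unique(p)))
  n_unique <- lengths(pepsets)
  keep <- n_unique >= min_unique_peptides
  pepsets <- pepsets[keep]
  if (!length(pepsets))
    return(data.frame(accession = character(), n_unique_peptides = integer(),
                      group = integer()))
  key <- vapply(pepsets, paste, character(1), collapse = "|")
  data.frame(accession = names(pepsets),
             n_unique_peptides = unname(n_unique[keep]),
             group = as.integer(factor(key, levels = unique(key))),
             row.names = NULL)
}
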