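## Isotope-pair matching and protein-level ratio aggregation.
## Light/heavy partners are matched within each (peptide, charge) species at
## the leucine-d3 m/z offset, peptide L/H ratios come from XIC areas, and
## protein ratios are aggregated in either of two dialects: mean of all
## leucine-containing peptide ratios with a sample SD (the original search
## pipeline), or median over unique peptides with a log-normal CV (the
## re-processing pipeline).

#' Match light/heavy XIC features into isotope pairs
#'
#' Within each (peptide, charge) species, a feature is matched to the
#' candidate partner sitting at the expected m/z offset
#' \code{mzOffset(n_leu, charge)} within \code{tolerance / charge}, and
#' co-eluting within \code{rt_window} minutes. Ambiguities are resolved
#' greedily by nearest m/z error, then nearest retention difference; each
#' feature joins at most one pair. Features of leucine-free peptides and
#' unmatched features are reported as singletons.
#'
#' @param features XIC feature \code{data.frame} with columns
#'   \code{feature_id}, \code{peptide}, \code{charge}, \code{mz},
#'   \code{rt_apex}, \code{area}.
#' @param tolerance Pair-matching mass tolerance in Da (applied as
#'   \code{tolerance / charge} in m/z space).
#' @param rt_window Maximum retention-apex separation in minutes.
#' @param masses A \code{\link{modificationMasses}} list.
#' @return \code{list(pairs, singletons)}: \code{pairs} has one row per
#'   matched pair (\code{peptide}, \code{charge}, \code{n_leu}, light/heavy
#'   ids, m/z, retention apexes and areas, and the m/z matching error);
#'   \code{singletons} is the subset of \code{features} left unmatched.
#' @examples
#' f <- data.frame(feature_id = c("a", "b"), peptide = "GLK", charge = 1,
#'   mz = c(500, 503.0188), rt_apex = c(30, 30.02), area = c(150, 100))
#' pairFeatures(f)$pairs
#' @export
pairFeatures <- function(features, tolerance = modificationMasses()$pair_tolerance_da,
                         rt_window = 0.5, masses = modificationMasses()) {
  .assertScalar(tolerance, "tolerance", lower = 0, strict = TRUE)
  .assertScalar(rt_window, "rt_window", lower = 0)
  empty_pairs <- data.frame(
    peptide = character(), charge = integer(), n_leu = integer(),
    light_id = character(), heavy_id = character(),
    light_mz = numeric(), heavy_mz = numeric(), mz_error = numeric(),
    light_rt = numeric(), heavy_rt = numeric(),
    light_area = numeric(), heavy_area = numeric())
  if (!nrow(features))
    return(list(pairs = empty_pairs, singletons = features))
  paired <- logical(nrow(features))
  pair_rows <- list()
  groups <- split(seq_len(nrow(features)),
                  paste(features$peptide, features$charge, sep = "/"))
  for (idx in groups) {
    pep <- features$peptide[idx[1L]]
    z <- features$charge[idx[1L]]
    n_leu <- countLeucines(pep)
    if (n_leu < 1L || length(idx) < 2L) next
    off <- mzOffset(n_leu, z, masses)
    cand <- expand.grid(i = idx, j = idx)
    cand <- cand[cand$i != cand$j, , drop = FALSE]
    cand$mz_error <- features$mz[cand$j] - features$mz[cand$i] - off
    cand$rt_diff <- abs(features$rt_apex[cand$j] - features$rt_apex[cand$i])
    cand <- cand[abs(cand$mz_error) <= tolerance / z &
                   cand$rt_diff <= rt_window, , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(abs(cand$mz_error), cand$rt_diff), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (paired[i] || paired[j]) next
      paired[i] <- paired[j] <- TRUE
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        peptide = pep, charge = as.integer(z), n_leu = n_leu,
        light_id = features$feature_id[i], heavy_id = features$feature_id[j],
        light_mz = features$mz[i], heavy_mz = features$mz[j],
        mz_error = cand$mz_error[k],
        light_rt = features$rt_apex[i], heavy_rt = features$rt_apex[j],
        light_area = features$area[i], heavy_area = features$area[j])
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else empty_pairs
  rownames(pairs) <- NULL
  list(pairs = pairs, singletons = features[!paired, , drop = FALSE])
}

#' Peptide L/H ratios from isotope pairs
#'
#' The light-to-heavy ratio of each pair is the ratio of the integrated XIC
#' areas. Pairs with a missing or non-positive partner area cannot yield a
#' ratio and raise a missing-partner condition.
#'
#' @param pairs Pair \code{data.frame} from \code{\link{pairFeatures}}.
#' @return \code{data.frame} with columns \code{peptide}, \code{charge},
#'   \code{n_leu}, \code{ratio_lh}.
#' @examples
#' p <- data.frame(peptide = "GLK", charge = 1, n_leu = 1,
#'   light_area = 150, heavy_area = 100)
#' peptideRatios(p)$ratio_lh  # 1.5
#' @export
peptideRatios <- function(pairs) {
  if (!nrow(pairs))
    return(data.frame(peptide = character(), charge = integer(),
                      n_leu = integer(), ratio_lh = numeric()))
  if (any(is.na(pairs$heavy_area) | pairs$heavy_area <= 0 |
            is.na(pairs$light_area) | pairs$light_area <= 0))
    .apmsStop("missingPartner",
              "pair with absent or non-positive partner area: no ratio defined")
  data.frame(peptide = pairs$peptide, charge = as.integer(pairs$charge),
             n_leu = pairs$n_leu, ratio_lh = pairs$light_area / pairs$heavy_area)
}

#' Aggregate peptide ratios to one protein ratio
#'
#' Two dialects: \code{"mean"} averages all leucine-containing peptide-
#' species ratios and reports the sample (n-1) SD and RSD (= SD/mean),
#' flagging proteins with RSD above 20\% for manual inspection;
#' \code{"median"} first collapses charge species to one ratio per unique
#' peptide sequence (median), reports the median of those, and expresses
#' variability as the coefficient of variation for log-normal data,
#' \code{sqrt(exp(s^2) - 1)} with \code{s} the sample SD of natural-log
#' ratios. Both dialects are always computed; \code{dialect} selects which
#' fills the active \code{ratio} column.
#'
#' @param ratios Numeric vector of peptide-species L/H ratios (> 0).
#' @param peptides Optional character vector, parallel to \code{ratios},
#'   with the peptide sequence of each species (required to collapse to
#'   unique peptides; when missing every ratio counts as its own peptide).
#' @param dialect \code{"mean"} or \code{"median"}.
#' @param manual_check_rsd RSD above which the protein is flagged for
#'   manual validation (default 0.20).
#' @return One-row \code{data.frame}: \code{n_species},
#'   \code{n_leu_peptides}, \code{ratio_mean}, \code{sd}, \code{rsd},
#'   \code{ratio_median}, \code{cv_lognormal}, \code{manual_check},
#'   \code{ratio}.
#' @examples
#' aggregateProtein(c(1.2, 1.4, 1.0))  # mean 1.2, sd 0.2, rsd 0.167
#' @export
aggregateProtein <- function(ratios, peptides = NULL,
                             dialect = c("mean", "median"),
                             manual_check_rsd = 0.20) {
  dialect <- match.arg(dialect)
  if (!length(ratios))
    .apmsStop("invalidArgument", "no peptide ratios to aggregate")
  if (any(!is.finite(ratios) | ratios <= 0))
    .apmsStop("invalidArgument", "peptide ratios must be positive and finite")
  if (is.null(peptides)) peptides <- as.character(seq_along(ratios))
  ratio_mean <- mean(ratios)
  sd_ <- if (length(ratios) > 1L) stats::sd(ratios) else 0
  rsd <- if (ratio_mean > 0) sd_ / ratio_mean else 0
  per_pep <- vapply(split(ratios, peptides), stats::median, numeric(1))
  ratio_median <- stats::median(per_pep)
  s_log <- if (length(per_pep) > 1L) stats::sd(log(per_pep)) else 0
  cv_lognormal <- sqrt(exp(s_log^2) - 1)
  data.frame(n_species = length(ratios), n_leu_peptides = length(per_pep),
             ratio_mean = ratio_mean, sd = sd_, rsd = rsd,
             ratio_median = ratio_median, cv_lognormal = cv_lognormal,
             manual_check = rsd > manual_check_rsd,
             ratio = if (dialect == "mean") ratio_mean else ratio_median)
}

#' Protein-level quantitation over an accepted PSM set
#'
#' Maps isotope-pair ratios to proteins through the accepted non-decoy
#' PSMs and aggregates per protein with \code{\link{aggregateProtein}}.
#' Peptides matched to more than one protein are dropped from quantitation
#' when \code{unique_only} (only unique peptides carry a protein ratio);
#' they still counted for identification upstream.
#'
#' @param pairs Pair \code{data.frame} from \code{\link{pairFeatures}}.
#' @param accepted Accepted PSM \code{data.frame} (maps peptide to
#'   accession).
#' @param proteins Optional character vector restricting quantitation to
#'   these accessions (typically the identified set from
#'   \code{\link{inferProteins}}).
#' @param dialect Active aggregation dialect, \code{"mean"} or
#'   \code{"median"}.
#' @param unique_only Drop peptides shared between accessions.
#' @param manual_check_rsd Passed to \code{\link{aggregateProtein}}.
#' @return \code{data.frame}, one row per quantified protein: accession,
#'   the \code{\link{aggregateProtein}} columns, and a \code{normalized_ratio}
#'   column (NA until \code{\link{normalizeToBait}}).
#' @export
quantifyProteins <- function(pairs, accepted, proteins = NULL,
                             dialect = c("mean", "median"),
                             unique_only = TRUE, manual_check_rsd = 0.20) {
  dialect <- match.arg(dialect)
  pq <- peptideRatios(pairs)
  tgt <- accepted[!accepted$is_decoy, c("peptide", "accession"), drop = FALSE]
  map <- unique(tgt)
  if (unique_only) {
    shared <- names(which(table(map$peptide) > 1L))
    map <- map[!map$peptide %in% shared, , drop = FALSE]
  }
  if (!is.null(proteins)) map <- map[map$accession %in% proteins, , drop = FALSE]
  merged <- merge(pq, map, by = "peptide")
  if (!nrow(merged))
    return(cbind(data.frame(accession = character()),
                 aggregateProtein(1)[0, ], normalized_ratio = numeric()))
  out <- do.call(rbind, lapply(split(merged, merged$accession), function(g)
    cbind(data.frame(accession = g$accession[1L]),
          aggregateProtein(g$ratio_lh, peptides = g$peptide,
                           dialect = dialect,
                           manual_check_rsd = manual_check_rsd))))
  out <- out[order(out$accession), , drop = FALSE]
  out$normalized_ratio <- NA_real_
  rownames(out) <- NULL
  out
}

#' Normalize protein ratios to the bait
#'
#' Divides every protein's active ratio by the bait's, so the bait sits at
#' exactly 1 and every other ratio reads as fold enrichment relative to the
#' amount of bait pulled down in each channel. This corrects residual
#' deviation of the 1:1 immunoprecipitate mixing (a bait at L/H = 0.97
#' indicates near-accurate mixing).
#'
#' @param quants Quantitation \code{data.frame} from
#'   \code{\link{quantifyProteins}}.
#' @param bait_accession Accession of the bait protein.
#' @return \code{quants} with \code{normalized_ratio} filled in.
#' @examples
#' q <- data.frame(accession = c("BAIT", "P1"), ratio = c(0.97, 1.36))
#' normalizeToBait(q, "BAIT")$normalized_ratio  # 1.0000 1.4021
#' @export
normalizeToBait <- function(quants, bait_accession) {
  i <- match(bait_accession, quants$accession)
  if (is.na(i) || !is.finite(quants$ratio[i]) || quants$ratio[i] <= 0)
    .apmsStop("missingBait",
              "bait absent from the quantified set (or has non-positive ratio)")
  quants$normalized_ratio <- quants$ratio / quants$ratio[i]
  quants$normalized_ratio[i] <- 1
  quants
}
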