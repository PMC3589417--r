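#' @import methods
NULL

.PSM_COLS <- c("psm_id", "peptide", "charge", "xcorr", "delta_cn",
               "probability", "accession", "is_decoy", "is_keratin")
.FEATURE_COLS <- c("feature_id", "peptide", "charge", "mz", "rt_apex", "area")
.TRUTH_COLS <- c("accession", "true_class", "true_enrichment")
.TRUE_CLASSES <- c("bait", "induced", "constitutive", "bead", "nonspecific")

#' SilacExperiment: a simulated or imported dual-tagging AP-MS experiment
#'
#' Container for one light/heavy labeled affinity-purification experiment:
#' the proteome searched, the peptide-spectrum matches with their
#' identification scores and decoy flags, the XIC feature table holding the
#' paired light/heavy elution signals, and (for synthetic data) the ground
#' truth table mapping each accession to its interaction class and true
#' enrichment.
#'
#' @slot proteome An \code{\link[Biostrings]{AAStringSet}} of protein
#'   sequences, named by accession.
#' @slot truth \code{data.frame} with columns \code{accession},
#'   \code{true_class} (one of bait, induced, constitutive, bead,
#'   nonspecific) and \code{true_enrichment} (true L/H fold). Empty for
#'   imported experiments without ground truth.
#' @slot psms \code{data.frame} of peptide-spectrum matches (see
#'   \code{\link{psmTable}} for the column contract).
#' @slot features \code{data.frame} of XIC features (m/z, charge, retention
#'   apex, integrated area, assigned peptide).
#' @slot config \code{list}; the generator configuration that produced the
#'   object, or an empty list for imported data.
#'
#' @seealso \code{\link{generateExperiment}}, \code{\link{psmTable}},
#'   \code{\link{featureTable}}, \code{\link{truthTable}}
#' @export
setClass("SilacExperiment",
  slots = c(proteome = "AAStringSet",
            truth = "data.frame",
            psms = "data.frame",
            features = "data.frame",
            config = "list"))

setValidity("SilacExperiment", function(object) {
  msgs <- character()
  if (is.null(names(object@proteome)) || anyDuplicated(names(object@proteome)))
    msgs <- c(msgs, "proteome must be named by unique accessions")
  miss <- setdiff(.PSM_COLS, names(object@psms))
  if (length(miss))
    msgs <- c(msgs, paste("psms missing column(s):", paste(miss, collapse = ", ")))
  miss <- setdiff(.FEATURE_COLS, names(object@features))
  if (length(miss))
    msgs <- c(msgs, paste("features missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(object@truth)) {
    miss <- setdiff(.TRUTH_COLS, names(object@truth))
    if (length(miss))
      msgs <- c(msgs, paste("truth missing column(s):", paste(miss, collapse = ", ")))
    else if (!all(object@truth$true_class %in% .TRUE_CLASSES))
      msgs <- c(msgs, "truth$true_class outside the allowed classes")
  }
  if (!length(msgs) && nrow(object@psms)) {
    tgt <- object@psms[!object@psms$is_decoy & object@psms$accession != "", ]
    unknown <- setdiff(tgt$accession, names(object@proteome))
    if (length(unknown))
      msgs <- c(msgs, paste("non-decoy PSM accession(s) not in proteome:",
                            paste(utils::head(unknown, 3), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SilacExperiment-accessors protein sequences searched
#' @export
setGeneric("proteome", function(x) standardGeneric("proteome"))
#' @describeIn SilacExperiment-accessors PSM table
#' @export
setGeneric("psmTable", function(x) standardGeneric("psmTable"))
#' @describeIn SilacExperiment-accessors XIC feature table
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @describeIn SilacExperiment-accessors ground-truth table
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' Accessors for SilacExperiment
#'
#' Read-only accessors for the slots of a \code{\linkS4class{SilacExperiment}}.
#'
#' @param x A \code{SilacExperiment}.
#' @return The corresponding slot: an \code{AAStringSet} for
#'   \code{proteome}, a \code{data.frame} otherwise.
#' @name SilacExperiment-accessors
#' @examples
#' expt <- generateExperiment(syntheticConfig(seed = 1, n_induced = 2,
#'   n_constitutive = 2, n_nonspecific = 2, n_bead = 1, n_keratin = 0))
#' head(psmTable(expt))
NULL

#' @rdname SilacExperiment-accessors
#' @export
setMethod("proteome", "SilacExperiment", function(x) x@proteome)
#' @rdname SilacExperiment-accessors
#' @export
setMethod("psmTable", "SilacExperiment", function(x) x@psms)
#' @rdname SilacExperiment-accessors
#' @export
setMethod("featureTable", "SilacExperiment", function(x) x@features)
#' @rdname SilacExperiment-accessors
#' @export
setMethod("truthTable", "SilacExperiment", function(x) x@truth)

setMethod("show", "SilacExperiment", function(object) {
  cat("SilacExperiment with", length(object@proteome), "proteins\n")
  if (nrow(object@truth)) {
    tab <- table(factor(object@truth$true_class, levels = .TRUE_CLASSES))
    cat("  truth classes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  cat("  PSMs:", nrow(object@psms),
      sprintf("(%d decoy)", sum(object@psms$is_decoy)), "\n")
  cat("  XIC features:", nrow(object@features), "\n")
})

#' CutoffDerivation: enrichment threshold derived from ratio variability
#'
#' Records how the L/H enrichment cutoff was obtained from the measured
#' peptide-ratio variability: the average relative standard deviation (RSD)
#' over proteins quantified with at least two leucine-containing peptides,
#' the multiplier applied to it, the resulting raw threshold in percent, and
#' the final cutoff ratio after conservative upward rounding.
#'
#' @slot avgRsd Average RSD (fraction) over qualifying proteins.
#' @slot multiplier Dimensionless multiplier (default 3).
#' @slot rawThresholdPct \code{100 * multiplier * avgRsd}.
#' @slot cutoffRatio Final L/H cutoff, never below
#'   \code{1 + rawThresholdPct/100}.
#' @slot rounding Either \code{"ceil0.1"} or \code{"none"}.
#'
#' @seealso \code{\link{deriveCutoff}}
#' @export
setClass("CutoffDerivation",
  slots = c(avgRsd = "numeric", multiplier = "numeric",
            rawThresholdPct = "numeric", cutoffRatio = "numeric",
            rounding = "character"))

setValidity("CutoffDerivation", function(object) {
  msgs <- character()
  if (object@avgRsd < 0) msgs <- c(msgs, "avgRsd must be >= 0")
  if (abs(object@rawThresholdPct - 100 * object@multiplier * object@avgRsd) > 1e-9)
    msgs <- c(msgs, "rawThresholdPct must equal 100 * multiplier * avgRsd")
  if (object@cutoffRatio < 1 + object@rawThresholdPct / 100 - 1e-12)
    msgs <- c(msgs, "cutoffRatio may never round below 1 + rawThresholdPct/100")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CutoffDerivation-accessors final L/H cutoff ratio
#' @export
setGeneric("cutoffRatio", function(x) standardGeneric("cutoffRatio"))
#' @describeIn CutoffDerivation-accessors average RSD the cutoff was built from
#' @export
setGeneric("avgRsd", function(x) standardGeneric("avgRsd"))

#' Accessors for CutoffDerivation
#' @param x A \code{CutoffDerivation}.
#' @return A numeric scalar.
#' @name CutoffDerivation-accessors
NULL

#' @rdname CutoffDerivation-accessors
#' @export
setMethod("cutoffRatio", "CutoffDerivation", function(x) x@cutoffRatio)
#' @rdname CutoffDerivation-accessors
#' @export
setMethod("avgRsd", "CutoffDerivation", function(x) x@avgRsd)

setMethod("show", "CutoffDerivation", function(object) {
  cat(sprintf(
    "CutoffDerivation: avg RSD %.4f x %g = %.1f%% -> L/H >= %.2f (%s rounding)\n",
    object@avgRsd, object@multiplier, object@rawThresholdPct,
    object@cutoffRatio, object@rounding))
})

#' ApmsRun: a complete pipeline run with all stage outputs
#'
#' Returned by \code{\link{runPipeline}}; bundles the experiment analysed,
#' the PSM filter report, the protein-level quantitation, the derived
#' cutoff, the interactor calls, the optional annotation/network summaries,
#' and the consolidated run report with the identification funnel.
#'
#' @slot experiment The \code{\linkS4class{SilacExperiment}} analysed.
#' @slot filterReport \code{list}: PSM filter counts and FDR estimate.
#' @slot quants \code{data.frame} of protein-level quantitation.
#' @slot cutoff A \code{\linkS4class{CutoffDerivation}}.
#' @slot calls \code{data.frame} of per-protein interactor calls.
#' @slot categories \code{data.frame} of functional-category counts.
#' @slot network \code{data.frame} edge list of the interactor network.
#' @slot report \code{list}: the consolidated run report.
#'
#' @export
setClass("ApmsRun",
  slots = c(experiment = "SilacExperiment", filterReport = "list",
            quants = "data.frame", cutoff = "CutoffDerivation",
            calls = "data.frame", categories = "data.frame",
            network = "data.frame", report = "list"))

#' @describeIn ApmsRun-accessors protein-level quantitation table
#' @export
setGeneric("proteinQuants", function(x) standardGeneric("proteinQuants"))
#' @describeIn ApmsRun-accessors per-protein interactor calls
#' @export
setGeneric("interactorCalls", function(x) standardGeneric("interactorCalls"))
#' @describeIn ApmsRun-accessors consolidated run report
#' @export
setGeneric("runReport", function(x) standardGeneric("runReport"))

#' Accessors for ApmsRun
#' @param x An \code{ApmsRun}.
#' @return A \code{data.frame} (quants, calls) or \code{list} (report).
#' @name ApmsRun-accessors
NULL

#' @rdname ApmsRun-accessors
#' @export
setMethod("proteinQuants", "ApmsRun", function(x) x@quants)
#' @rdname ApmsRun-accessors
#' @export
setMethod("interactorCalls", "ApmsRun", function(x) x@calls)
#' @rdname ApmsRun-accessors
#' @export
setMethod("runReport", "ApmsRun", function(x) x@report)
#' @rdname ApmsRun-accessors
#' @export
setMethod("cutoffRatio", "ApmsRun", function(x) x@cutoff@cutoffRatio)

setMethod("show", "ApmsRun", function(object) {
  r <- object@report
  cat("ApmsRun\n")
  cat(sprintf("  identified: %d  quantified: %d  above cutoff: %d\n",
              r$n_identified, r$n_quantified, r$n_above_cutoff))
  cat(sprintf("  bead-excluded: %d  final interactors: %d\n",
              r$n_bead_excluded, r$n_interactors))
  cat(sprintf("  FDR estimate: %.4f  cutoff L/H >= %.2f\n",
              r$fdr_estimate, object@cutoff@cutoffRatio))
})
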