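## End-to-end orchestration: simulate (or import) -> filter -> infer ->
## pair -> quantify -> normalize -> derive cutoff -> classify -> annotate,
## with a consolidated run report reproducing the identification funnel
## (identified >= quantified >= above-cutoff >= final interactors).

#' Default pipeline configuration
#'
#' Nested list of every tunable stage parameter, with defaults mirroring
#' the original search configuration: deltaCn > 0.1, probability < 0.001,
#' keratin exclusion, two unique peptides per protein, 0.01 Da pair
#' tolerance, mean-dialect aggregation, cutoff multiplier 3 with
#' conservative 0.1-ceiling rounding. \code{call$cutoff_ratio} (NULL =
#' derive from the data) fixes the cutoff instead of deriving it.
#'
#' @param seed Integer seed driving the synthetic generator.
#' @return A list of class \code{"PipelineConfig"}.
#' @examples
#' defaultPipelineConfig(seed = 7)$call$multiplier
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    synthetic = list(),  # overrides forwarded to syntheticConfig()
    filter = list(delta_cn_min = 0.1, probability_max = 0.001,
                  keratin_keywords = "keratin", min_unique_peptides = 2L),
    quant = list(dialect = "mean", tolerance_da = 0.01, rt_window_min = 0.5,
                 unique_only = TRUE, manual_check_rsd = 0.20),
    call = list(multiplier = 3, rounding = "ceil0.1", cutoff_ratio = NULL),
    out_dir = NULL), class = "PipelineConfig")
}

.checkConfigKeys <- function(config, template = defaultPipelineConfig()) {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown))
    .apmsStop("invalidConfig",
              paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  for (nm in intersect(names(config), c("filter", "quant", "call"))) {
    unknown <- setdiff(names(config[[nm]]), names(template[[nm]]))
    if (length(unknown))
      .apmsStop("invalidConfig", sprintf("unknown config key(s) under '%s': %s",
                                         nm, paste(unknown, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly; unknown keys are rejected at
#' read time so typos fail loudly instead of being silently ignored.
#'
#' @param path YAML file path.
#' @param config A \code{"PipelineConfig"} list.
#' @return \code{readPipelineConfig}: the validated config list;
#'   \code{writePipelineConfig}: \code{path}, invisibly.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  .checkConfigKeys(raw)
  cfg <- defaultPipelineConfig()
  for (nm in names(raw)) {
    if (nm %in% c("filter", "quant", "call"))
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    else cfg[nm] <- list(raw[[nm]])  # keeps NULL-valued keys
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full interactor-calling pipeline
#'
#' Executes every stage in order on a synthetic experiment (generated from
#' \code{config$seed} and \code{config$synthetic} overrides) or on a
#' supplied \code{\linkS4class{SilacExperiment}}: PSM filtering with decoy
#' FDR, protein inference (>= 2 unique peptides), isotope-pair matching,
#' protein quantitation, bait normalization, cutoff derivation from the
#' average RSD, bead-proteome exclusion and interactor classification, then
#' functional categorization and network construction. Deterministic given
#' config + seed; when \code{config$out_dir} is set, all stage outputs are
#' written there as TSV/FASTA/JSON.
#'
#' @param config A \code{\link{defaultPipelineConfig}}-shaped list.
#' @param experiment Optional \code{SilacExperiment}; when NULL a synthetic
#'   one is generated.
#' @param bait_accession Bait accession; defaults to the truth table's bait.
#' @param bead_list Character vector of bead-proteome accessions; defaults
#'   to the truth table's bead class (the synthetic stand-in for the
#'   user-supplied bead-proteome reference).
#' @param annotation \code{data.frame(accession, category)}; defaults to the
#'   truth table's category column.
#' @param edges Optional evidence edge table (\code{source}, \code{target}).
#' @return An \code{\linkS4class{ApmsRun}}.
#' @examples
#' cfg <- defaultPipelineConfig(seed = 3)
#' cfg$synthetic <- list(n_induced = 5, n_constitutive = 5,
#'   n_nonspecific = 5, n_bead = 2, n_keratin = 0)
#' run <- runPipeline(cfg)
#' runReport(run)$n_interactors
#' @export
runPipeline <- function(config = defaultPipelineConfig(), experiment = NULL,
                        bait_accession = NULL, bead_list = NULL,
                        annotation = NULL, edges = NULL) {
  .checkConfigKeys(config)
  if (is.null(experiment)) {
    syn_cfg <- do.call(syntheticConfig,
                       c(list(seed = config$seed), config$synthetic))
    experiment <- generateExperiment(syn_cfg)
  }
  truth <- truthTable(experiment)
  if (is.null(bait_accession)) bait_accession <- baitAccession(experiment)
  if (is.null(bead_list))
    bead_list <- truth$accession[truth$true_class == "bead"]
  if (is.null(annotation) && "category" %in% names(truth))
    annotation <- truth[, c("accession", "category")]

  ## identification
  flt <- filterPsms(psmTable(experiment),
                    delta_cn_min = config$filter$delta_cn_min,
                    probability_max = config$filter$probability_max,
                    keratin_keywords = config$filter$keratin_keywords)
  identified <- inferProteins(flt$accepted,
                              min_unique_peptides = config$filter$min_unique_peptides)

  ## quantitation
  paired <- pairFeatures(featureTable(experiment),
                         tolerance = config$quant$tolerance_da,
                         rt_window = config$quant$rt_window_min)
  quants <- quantifyProteins(paired$pairs, flt$accepted,
                             proteins = identified$accession,
                             dialect = config$quant$dialect,
                             unique_only = config$quant$unique_only,
                             manual_check_rsd = config$quant$manual_check_rsd)
  bait_ratio <- quants$ratio[match(bait_accession, quants$accession)]
  quants <- normalizeToBait(quants, bait_accession)

  ## cutoff: derived from measured variability, or fixed by config
  avg_rsd <- averageRsd(quants)
  cutoff <- if (is.null(config$call$cutoff_ratio)) {
    deriveCutoff(avg_rsd, multiplier = config$call$multiplier,
                 rounding = config$call$rounding)
  } else {
    methods::new("CutoffDerivation", avgRsd = avg_rsd, multiplier = 0,
                 rawThresholdPct = 0,
                 cutoffRatio = config$call$cutoff_ratio, rounding = "none")
  }
  cls <- classifyInteractors(quants, cutoff, bead_list = bead_list,
                             bait_accession = bait_accession)
  inter <- as.character(cls$calls$accession[cls$calls$call == "induced_interactor"])

  categories <- if (!is.null(annotation))
    categorizeInteractors(inter, annotation) else
    data.frame(category = character(), count = integer(), percentage = numeric())
  graph <- buildNetwork(inter, bait_accession, edges = edges)
  net <- igraph::as_data_frame(graph, what = "edges")
  names(net)[1:2] <- c("source", "target")

  n_above <- unname(cls$summary[["n_above_cutoff"]])
  report <- list(
    seed = config$seed,
    bait_accession = bait_accession,
    n_psms_input = flt$report$n_input,
    n_psms_accepted = flt$report$n_accepted,
    fdr_estimate = flt$report$fdr_estimate,
    n_identified = nrow(identified),
    n_quantified = nrow(quants),
    n_above_cutoff = n_above,
    n_bead_excluded = unname(cls$summary[["bead_excluded"]]),
    n_interactors = length(inter),
    bait_ratio = bait_ratio,
    avg_rsd = avg_rsd,
    cutoff = list(avg_rsd = cutoff@avgRsd, multiplier = cutoff@multiplier,
                  raw_threshold_pct = cutoff@rawThresholdPct,
                  cutoff_ratio = cutoff@cutoffRatio,
                  rounding = cutoff@rounding),
    calls = as.list(cls$summary[.CALLS]))
  ## funnel consistency check; an internal contradiction is a bug
  stopifnot(report$n_identified >= report$n_quantified,
            report$n_quantified >= report$n_above_cutoff,
            report$n_above_cutoff >= report$n_interactors,
            report$n_interactors == report$n_above_cutoff -
              report$n_bead_excluded -
              sum(cls$calls$call == "bait" &
                    cls$calls$normalized_ratio >= cutoff@cutoffRatio))

  run <- methods::new("ApmsRun", experiment = experiment,
                      filterReport = flt$report, quants = quants,
                      cutoff = cutoff, calls = cls$calls,
                      categories = categories, network = net, report = report)
  if (!is.null(config$out_dir)) writePipelineOutputs(run, config$out_dir)
  run
}

#' Write all stage outputs of a pipeline run
#'
#' Plain-text exports: the experiment (FASTA + TSV), accepted PSMs, protein
#' quantitation, interactor calls, category summary, network edge list, and
#' the consolidated JSON run report. Byte-identical across runs with the
#' same config and seed.
#'
#' @param run An \code{\linkS4class{ApmsRun}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writePipelineOutputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeExperiment(run@experiment, dir)
  .writeTsv(run@filterReport |> (\(r) data.frame(
    metric = c("n_input", "n_accepted", "n_accepted_target", "n_accepted_decoy",
               paste0("rejected_", names(r$rejected)), "fdr_estimate"),
    value = c(r$n_input, r$n_accepted, r$n_accepted_target, r$n_accepted_decoy,
              unname(r$rejected), r$fdr_estimate)))(),
    file.path(dir, "filter_report.tsv"))
  .writeTsv(run@quants, file.path(dir, "protein_quants.tsv"))
  .writeTsv(run@calls, file.path(dir, "interactor_calls.tsv"))
  .writeTsv(run@categories, file.path(dir, "category_summary.tsv"))
  .writeTsv(run@network, file.path(dir, "network_edges.tsv"))
  jsonlite::write_json(run@report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
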