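## Plain-text IO: FASTA through Biostrings, TSV tables, JSON reports.
## All outputs are deterministic given identical inputs (no timestamps).

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a SilacExperiment to a directory of plain-text files
#'
#' Writes \code{proteome.fasta}, \code{psms.tsv}, \code{features.tsv} and
#' \code{truth.tsv} (when ground truth is present) into \code{dir}.
#'
#' @param expt A \code{\linkS4class{SilacExperiment}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeExperiment <- function(expt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(proteome(expt), file.path(dir, "proteome.fasta"))
  .writeTsv(psmTable(expt), file.path(dir, "psms.tsv"))
  .writeTsv(featureTable(expt), file.path(dir, "features.tsv"))
  if (nrow(truthTable(expt)))
    .writeTsv(truthTable(expt), file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a SilacExperiment back from a directory
#'
#' Counterpart of \code{\link{writeExperiment}}; \code{truth.tsv} is
#' optional.
#'
#' @param dir Directory holding \code{proteome.fasta}, \code{psms.tsv} and
#'   \code{features.tsv}.
#' @return A \code{\linkS4class{SilacExperiment}}.
#' @export
readExperiment <- function(dir) {
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) .readTsv(truth_path) else
    data.frame(accession = character(), true_class = character(),
               true_enrichment = numeric())
  methods::new("SilacExperiment",
               proteome = Biostrings::readAAStringSet(file.path(dir, "proteome.fasta")),
               truth = truth,
               psms = .readTsv(file.path(dir, "psms.tsv")),
               features = .readTsv(file.path(dir, "features.tsv")),
               config = list())
}

#' Read a PSM table from TSV
#' @param path Path to a tab-separated PSM table (schema of
#'   \code{\link{psmTable}}).
#' @return \code{data.frame}.
#' @export
readPsmTable <- function(path) .readTsv(path)

#' Read an XIC feature table from TSV
#' @param path Path to a tab-separated feature table (schema of
#'   \code{\link{featureTable}}).
#' @return \code{data.frame}.
#' @export
readFeatureTable <- function(path) .readTsv(path)

#' Read a bead-proteome reference list
#' @param path Text file, one accession per line; blank lines and lines
#'   starting with \code{#} are skipped.
#' @return Character vector of accessions.
#' @export
readBeadList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read an annotation table (accession, category) from TSV
#' @param path Path to a two-column tab-separated file with header columns
#'   \code{accession} and \code{category}.
#' @return \code{data.frame}.
#' @export
readAnnotationTable <- function(path) .readTsv(path)

#' Read an interaction edge table from TSV
#' @param path Path to a tab-separated file with columns \code{source},
#'   \code{target} and optionally \code{weight}.
#' @return \code{data.frame}.
#' @export
readEdgeTable <- function(path) .readTsv(path)
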