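#' Fixed modification masses and pair-matching tolerance
#'
#' The physical constants the pipeline shares: the mass shift per
#' leucine-d3 residue that separates a light peptide from its metabolically
#' labeled heavy partner, the variable-modification masses used by the
#' original database search (phospho-S/T/Y and oxidized Met), and the mass
#' tolerance used when matching light/heavy XIC feature pairs. Values are
#' stored as printed in the original search configuration; note that the
#' oxidized-Met value (15.9994) is the average rather than monoisotopic
#' oxygen mass, and is kept verbatim for fidelity.
#'
#' @param leu_d3_shift_da Mass shift in Da per labeled leucine residue.
#' @param phospho_sty_da Phosphorylation mass for Ser/Thr/Tyr, Da.
#' @param met_ox_da Methionine oxidation mass, Da.
#' @param pair_tolerance_da Mass tolerance in Da for light/heavy pair
#'   matching (must be positive and below 1 Da).
#'
#' @return A named list of class \code{"ModificationMasses"}.
#' @examples
#' modificationMasses()$leu_d3_shift_da
#' @export
modificationMasses <- function(leu_d3_shift_da = 3.0188,
                               phospho_sty_da = 79.9663,
                               met_ox_da = 15.9994,
                               pair_tolerance_da = 0.01) {
  for (nm in c("leu_d3_shift_da", "phospho_sty_da", "met_ox_da"))
    .assertScalar(get(nm), nm, lower = 0, strict = TRUE)
  .assertScalar(pair_tolerance_da, "pair_tolerance_da", lower = 0, strict = TRUE)
  if (pair_tolerance_da >= 1)
    .apmsStop("invalidArgument", "'pair_tolerance_da' must be < 1 Da")
  structure(list(leu_d3_shift_da = leu_d3_shift_da,
                 phospho_sty_da = phospho_sty_da,
                 met_ox_da = met_ox_da,
                 pair_tolerance_da = pair_tolerance_da),
            class = "ModificationMasses")
}

#' Neutral mass shift of a leucine-d3 labeled peptide
#'
#' The heavy form of a peptide carries one deuterated leucine per L residue,
#' each adding a fixed mass increment; the total shift is linear in the
#' leucine count.
#'
#' @param n_leu Number of leucine residues (non-negative integer).
#' @param masses A \code{\link{modificationMasses}} list.
#' @return Mass shift in Da.
#' @examples
#' heavyMassShift(1)  # 3.0188
#' heavyMassShift(4)  # 12.0752
#' @export
heavyMassShift <- function(n_leu, masses = modificationMasses()) {
  .assertCount(n_leu, "n_leu")
  n_leu * masses$leu_d3_shift_da
}

#' m/z offset between light and heavy partner features
#'
#' The neutral label shift divided by charge: the spacing at which the heavy
#' XIC feature is expected relative to its light partner in m/z space.
#'
#' @inheritParams heavyMassShift
#' @param charge Precursor charge state (integer, >= 1).
#' @return m/z difference in Th.
#' @examples
#' mzOffset(2, 2)  # 3.0188
#' @export
mzOffset <- function(n_leu, charge, masses = modificationMasses()) {
  if (length(charge) != 1L || is.na(charge) || charge < 1 || charge != floor(charge))
    .apmsStop("invalidArgument", "'charge' must be a single integer >= 1")
  heavyMassShift(n_leu, masses) / charge
}
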