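## internal helpers shared across modules

## signal a classed error so callers can condition on failure mode
.apmsStop <- function(class, msg, call. = sys.call(-1)) {
  stop(structure(
    class = c(class, "silacApms_error", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

.assertCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    .apmsStop("invalidArgument", sprintf("'%s' must be a single non-negative integer", name))
  invisible(as.integer(x))
}

.assertScalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    .apmsStop("invalidArgument", sprintf("'%s' must be a single finite number", name))
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    .apmsStop("invalidArgument", sprintf("'%s' must be %s %s", name,
                                         if (strict) ">" else ">=", lower))
  invisible(x)
}

## 20 standard residues, monoisotopic residue masses (Da)
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

.MASS_WATER  <- 18.010565
.MASS_PROTON <- 1.00727646

.checkSequence <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence) ||
      nchar(sequence) == 0L)
    .apmsStop("invalidArgument", "sequence must be a single non-empty string")
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, names(.RESIDUE_MASS))
  if (length(bad))
    .apmsStop("invalidArgument",
              sprintf("invalid residue(s) in sequence: %s", paste(bad, collapse = ", ")))
  res
}

## monoisotopic [M+zH]z+ m/z of an unlabeled peptide
.peptideMz <- function(peptide, charge) {
  res <- .checkSequence(peptide)
  (sum(.RESIDUE_MASS[res]) + .MASS_WATER + charge * .MASS_PROTON) / charge
}
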