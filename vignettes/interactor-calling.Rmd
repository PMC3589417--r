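---
title: "Calling stimulus-induced interactors from SILAC/AACT AP-MS ratios"
author: "silacApms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling stimulus-induced interactors from SILAC/AACT AP-MS ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacApms)
```

## The measurement model

A dual-tagging AP-MS screen compares two pulldowns of the same tagged bait:
cells stimulated in light medium against unstimulated cells grown in heavy
(leucine-d3) medium. Because the immunoprecipitates are mixed 1:1 *after*
pulldown, every peptide species appears twice in the same LC-MS run — a
light feature and a heavy partner offset by

$$\Delta m/z = \frac{n_\mathrm{Leu} \times 3.0188\ \mathrm{Da}}{z},$$

where $n_\mathrm{Leu}$ counts the leucines and $z$ is the charge. The
light-to-heavy (L/H) ratio of the integrated XIC areas of a pair measures
the stimulus-induced change in how much of that protein co-purified with
the bait. Leucine-d3 adds $3 \times (m(^2\mathrm{H}) - m(^1\mathrm{H})) =
3.01883$ Da per residue; the package stores the constant as printed in the
original search configuration (3.0188), which agrees with the
first-principles value to four decimals. The oxidized-Met modification
mass is likewise kept as printed (15.9994, the *average* oxygen mass
rather than the monoisotopic 15.9949); a test pins both facts down.

Only leucine-containing peptides form pairs, so only they quantify; a
protein needs at least one paired peptide to receive a ratio and at least
two distinct leucine-containing peptides to contribute variability
information.

## Stages and their parameters

**PSM filtering.** A PSM is accepted iff all of: Xcorr at or above the
charge-dependent floor (1.9 / 2.6 / 3.6 for 1+ / 2+ / 3+; higher charges
clamp to the 3+ value, the common Sequest-filter convention), ΔCn strictly
above 0.1, probability score strictly below 0.001, and not keratin.
The boundary conventions are a literal reading of the filter description:
"set to" is a minimum (inclusive for Xcorr), the other two operators are
strict. Keratin exclusion matches a configurable keyword list against the
accession (default `"keratin"`) in addition to any explicit flag, because
no canonical keratin accession list exists. Decoy PSMs passing the score
rules are kept, flagged, purely for FDR estimation: the estimator is the
simple target-decoy ratio $\hat{\mathrm{FDR}} = n_\mathrm{decoy} /
n_\mathrm{target}$ (the doubled variant is available via
`estimateFdr(doubled = TRUE)`).

**Protein inference.** A protein is reported with at least two distinct
accepted peptide sequences; proteins with identical peptide sets are
reported together as one ambiguity group. Shared (non-unique) peptides
count toward identification of every protein carrying them but are dropped
from quantitation (`unique_only = TRUE`), so one peptide never drives two
ratios.

**Pair matching.** Within each (peptide, charge) species, candidate pairs
must sit within `tolerance / z` of the expected offset in m/z space — the
0.01 Da tolerance is specified as a mass, and dividing by charge is the
conservative, charge-consistent reading — and co-elute within an RT window
(default 0.5 min; label-induced retention shifts for d3 are small).
Ambiguities resolve greedily by nearest m/z error, then nearest RT; each
feature joins at most one pair, and one-sided features are reported as
singletons, never imputed.

**Aggregation dialects.** Two aggregation conventions coexist in practice
and both are always computed. The *mean* dialect averages all
leucine-containing peptide-species ratios, reports the sample (n−1) SD —
appropriate at the small peptide counts typical of pulldowns — and the RSD
= SD/mean, flagging proteins with RSD > 20 % for manual signal inspection
(`manual_check`) rather than dropping them. The *median* dialect first
collapses charge species to one ratio per unique peptide sequence (median),
takes the median of those, and expresses variability as the coefficient of
variation under a log-normal ratio model,
$\mathrm{CV} = \sqrt{e^{s^2} - 1}$ with $s$ the sample SD of natural-log
ratios. That formula is the standard log-normal CV; the exact expression
used by the original vendor software is not documented, so we state ours
explicitly. `dialect` selects which fills the active `ratio` column.

**Bait normalization.** All ratios are divided by the bait's, pinning the
bait at exactly 1. A bait ratio near 1 (e.g. 0.97) is itself the quality
control for the 1:1 mixing; normalization removes the residual deviation
from every other protein's fold change.

**Cutoff derivation.** The enrichment threshold is derived from the data:
the unweighted average RSD $\bar r$ over proteins with ≥ 2
leucine-containing peptides (single-peptide proteins have RSD 0 by
construction and are excluded so they cannot dilute the average), times a
multiplier (default 3), gives the raw threshold $3\bar r$; the cutoff
ratio is $1 + 3\bar r$ rounded *up* to the next 0.1. The ceiling
formalizes the conservative step from, e.g., 36 % to a clean L/H ≥ 1.40
and can never lower the threshold; `rounding = "none"` gives the exact
value. RSD is scale-free, so it is computed before bait normalization.
The classification boundary is inclusive (≥ cutoff).

**Classification.** Bait → `bait`; at/above cutoff and on the
bead-proteome reference list → `bead_excluded`; at/above cutoff otherwise
→ `induced_interactor`; everything else → `non_induced`. Constitutive
binders, nonspecific associations and stimulus-induced *dis*sociations are
indistinguishable from a single ratio and are pooled as `non_induced` on
purpose. The bead-proteome list is user-supplied reference data (a
synthetic fixture ships under `inst/extdata/` for examples and tests).

**Summaries.** Functional categories come from a static
accession-to-category table — annotation services are consumed as exported
tables, never queried live, because versioned databases would make runs
irreproducible. One primary category per protein keeps the summary a
partition; percentages are integer-rounded. The network layer builds an
undirected bait-centred graph: the pulldown itself evidences a
bait–interactor link for every call, supplied edge tables add
between-interactor structure, duplicates and self-loops collapse, and
degree ranking (ties broken lexicographically) typically puts the bait on
top.

## What the synthetic generator emulates

`generateExperiment(syntheticConfig(...))` simulates, per protein class:

| class | count (default) | true L/H |
|---|---|---|
| bait | 1 | 0.97 |
| induced | 30 | uniform 1.5–4.0 |
| constitutive | 60 | 1.0 |
| nonspecific | 92 | 1.0 |
| bead | 15 | uniform 2.0–8.0 |
| keratin | 2 | 1.0, PSMs flagged |

Protein sequences are random draws over near-natural residue frequencies,
re-drawn until they yield ≥ 2 distinct quantifiable tryptic peptides
(leucine-containing, length 6–30). Digestion cleaves C-terminal to K/R
except before P — the classic trypsin rule the original search engines
default to. Each protein contributes 3–10 quantifiable peptide species;
each species gets one light/heavy feature pair whose area ratio is
log-normal around the true enrichment with relative SD
`peptide_noise_rsd` (default 0.12, matching the variability a well-behaved
labeling experiment shows). The log-normal is parameterised mean-unbiased
($\mu = \log(\mathrm{true}) - s^2/2$, $s^2 = \log(1 + \mathrm{RSD}^2)$),
which leaves a median-dialect log bias of $-s^2/2 \approx -0.007$ at RSD
0.12 — inside the ±0.01 the tests demand, and zero when noise is zero.
Heavy-feature base areas are log-normal (meanlog $\log 10^6$, sdlog 0.5);
retention apexes are uniform over 10–110 min with a 0.05 min co-elution
jitter. Correct PSMs draw Xcorr above the charge threshold (+1.5 ± 0.5),
ΔCn ~ N(0.25, 0.07) and log10 probability uniform in (−6, −3.3); incorrect
matches (30 % of the correct count, split evenly between reversed-accession
decoys and false target hits) draw from distributions mostly failing the
filters, so the decoy estimate can be compared against the known
false-target rate. All draws sit on one seeded RNG stream: identical
config + seed gives byte-identical output, which the determinism tests
check at the file level.

What it does **not** emulate — and what passing tests therefore do not
show about real data: chromatographic peak shapes and integration error,
m/z-space interferences between co-eluting species, missing heavy partners
(one-sided pairs), ratio compression, retention drift between runs, true
protein ambiguity from homology, and realistic score correlations. The
generator validates the *inference chain*, not the upstream signal
processing.

## Numerical and design choices

- **Cutoff rounding**: `ceiling(round(x * 10, 9)) / 10` — the inner
  rounding absorbs binary-representation noise so a value already on a 0.1
  boundary (e.g. 1.30) is not bumped to 1.40, while the ceiling never
  rounds down.
- **Zero-variability degeneracy**: with zero peptide noise every RSD is 0
  and the derived cutoff collapses to 1.0, where a constitutive binder
  normalized by a 0.97 bait (→ 1.031) would be called induced. For such
  degenerate data `config$call$cutoff_ratio` fixes the cutoff instead of
  deriving it; the noiseless recovery test runs at the canonical 1.40.
- **Ties in pair matching** are broken by m/z error before RT because mass
  accuracy is the stronger constraint on modern instruments.
- **Sample SD throughout** (n−1): peptide counts per protein are small.
- **Problem sizes in the tests**: the property suites run on experiments
  of 15–200 proteins and noise-calibration on 10^4 draws — sizes chosen so
  the full suite stays a desk-scale check while estimates (e.g. average
  RSD ≈ 12 %, cutoff 1.40) stabilise at their configured values.
- **Errors are classed conditions** (`invalidArgument`, `noPair`,
  `missingBait`, `emptyDataset`, `undefinedFdr`, `invalidConfig`,
  `noQualifyingProtein`, `missingPartner`) so pipelines can branch on
  failure mode.

## Limitations

Spectrum-level scoring is simulated, never computed: the package starts
from PSM tables and never re-scores spectra. Phosphosite localization,
raw-file parsing and live annotation queries are out of scope. The
identification funnel counts of any given screen depend on instrument and
sample; what the package guarantees is the *structure* of the analysis —
the funnel ordering identified ≥ quantified ≥ above-cutoff ≥ final, exact
recovery in the noiseless limit, calibrated noise behaviour, FDR control
on synthetic data, and determinism under a fixed seed.

```{r funnel}
run <- runPipeline(defaultPipelineConfig(seed = 1))
runReport(run)[c("n_identified", "n_quantified", "n_above_cutoff",
                 "n_interactors")]
```
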