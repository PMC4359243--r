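---
title: "Methods: high-content siRNA screen analysis with robust z-scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-content siRNA screen analysis with robust z-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscreen)
```

## The analysis problem

A high-content RNAi screen for DNA-damage modulators knocks down each gene
in a library — here, a ubiquitin-system library of 327 E3 ligase and 92
deubiquitinase (DUB) genes, three independent siRNAs per gene — exposes the
cells to a genotoxic drug, and reads out DNA damage as the nuclear
immunofluorescence intensity of phosphorylated H2AX (γH2AX). The analysis
must turn millions of per-nucleus intensity measurements into a ranked list
of candidate genes whose knockdown raises or lowers the damage signal,
while being robust to the dominant nuisance in plate-based screening:
systematic plate-to-plate variation.

hcscreen implements that analysis as a tested pipeline:

1. **Quantification** — identify nuclei in the Hoechst channel, average the
   signal channel over each nucleus, average nuclei per well, and subtract
   the signal of background wells (stained without the primary antibody).
2. **Normalization** — per-plate robust z-scores,
   `z = (value − plate median) / plate MAD`.
3. **Hit calling** — an siRNA is a hit at `|z| ≥ 2`; a gene is a candidate
   when at least two of its siRNAs pass in the same direction; genes are
   ranked by cumulative (summed) z.
4. **Validation statistics** — ΔΔCt relative expression for knockdown
   confirmation, unpaired two-tailed Student's t-tests with the
   `***`/`**`/`*`/`n.s.` asterisk convention, SD/SEM error summaries, and
   box-plot statistics (median, quartiles, 5th/95th percentiles) for
   single-cell distributions.

Because the original screen's raw images are not publicly deposited, the
package pairs the pipeline with a synthetic screen generator that implants
known effects, so every stage can be tested against ground truth.

## The generative model

The generator emulates the statistical structure the analysis assumes, not
the biology of any particular gene. Per-cell signal intensities are
log-normal — fluorescence intensities are positive and right-skewed, and
treatment, knockdown and plate effects act multiplicatively — with additive
effects on the log scale. For a cell in a sample well:

$$\log S = \mu_0 + \tau\,t + e\,\delta_g\,t + \pi_p + u_w + \varepsilon$$

where $t$ is the treatment indicator, $\delta_g$ the gene's implanted
effect, $e$ the siRNA's knockdown efficacy,
$\pi_p \sim N(0, \sigma_\text{plate}^2)$ the plate effect,
$u_w \sim N(0, \sigma_\text{well}^2)$ well noise and
$\varepsilon \sim N(0, \sigma_\text{cell}^2)$ cell noise. Cell counts per
well are Poisson.

Defaults (all tunable via `model_params()` / `screen_config()`):

| parameter | default | meaning |
|---|---|---|
| `mu0` | ln 100 | baseline log-intensity (arbitrary units) |
| `tau` | ln 3 | treatment raises the damage signal ~3-fold |
| `sigma_cell` | 0.5 | cell-to-cell spread of log-intensity |
| `sigma_well` | 0.1 | well-to-well spread |
| `sigma_plate` | 0.15 | plate-effect spread (what z-scoring removes) |
| `lambda_cells` | 500 | mean cells per well |
| `background_level` | 5 | median signal in background wells |
| `efficacy_range` | 0.6–0.95 | per-siRNA fraction of the gene effect realised |
| `positive_delta` | ln 3 | implanted effect of positive-control wells |

The default implanted-effect configuration gives 5% of genes a two-fold
decrease and 5% a two-fold increase (`delta_magnitude = ln 2`) — a
plausible modulator rate for a focused library; the recovery benchmarks
below use the explicit 20-of-100 condition instead. Positive-control wells
carry a strong implanted increase and negative controls are null, since a
screen's control identities are design choices, not measurements.

Every random draw is keyed to `(seed, plate_id, well_id)` through a
31-bit string hash, so any well can be re-simulated in isolation and the
result never depends on evaluation order. With a fixed seed, all outputs
are bit-reproducible; this is what makes the byte-identical-rerun test
meaningful.

### Plate design

Each siRNA index (1–3) occupies its own set of 96-well plates, so sibling
siRNAs against one gene never share a plate — knockdown replication is
confounded with plates by design, which is exactly why normalization must
be per-plate. Within a plate, 80 sample wells fill columns 2–11 and the 16
edge wells of columns 1 and 12 hold 4 negative-control, 4 background and 8
positive-control wells. The real screen's plate map is not published; this
is a round, testable layout, and the background/control placement is
configurable.

### What the generator does not emulate

No siRNA off-target effects, no cell-cycle or apoptosis structure, no
spatial (row/column/edge) gradients within plates, no illumination fields,
no focus failures. Passing recovery tests therefore show that the pipeline
correctly inverts the declared generative model — plate effects,
log-normal noise, partial efficacy — not that it would be immune to every
artefact of real screening data. The deliberate omission of row/column
gradients matches the normalization choice below (no B-score polish).

## Imaging

`segment_nuclei()` thresholds the Hoechst channel (Otsu's method by
default; a fixed threshold is available for controlled tests), labels
connected components (8-connectivity by default), discards components
outside 40–5000 px or touching the image border, and relabels survivors
consecutively in row-major scan order. There is deliberately no watershed
splitting: touching nuclei merge into one component, a documented
limitation tested explicitly. `quantify_nuclei()` takes the arithmetic
mean of signal-channel pixels over each mask; "relative fluorescence
intensity" is left in arbitrary units with no per-image rescaling, because
the only downstream consumer is plate-relative z-scoring, which absorbs
units and offsets.

The synthetic microscope renders nuclei as discs convolved with a Gaussian
point-spread function. Mean-over-mask quantification of a blurred disc
loses edge flux — about $0.8\,\sigma_\text{psf}/r$ of the nucleus' signal
— so the default optical scale (radius ~10 px, `psf_sigma` 0.5 px,
matching ~10 µm nuclei imaged at ~0.5 µm/pixel) keeps that bias under 3%.
The rendering tests use this scale at ~15 cells per 256×256 field, where
the placement sampler guarantees non-overlapping nuclei; count exactness
is claimed only in that regime.

Wells with fewer than 50 nuclei (configurable) are flagged invalid and
excluded from plate statistics: a per-well mean over a handful of cells is
too unstable to normalize against. Background subtraction defaults to
per-plate scope — the plate is the screen's natural statistical unit, and
the published description leaves the scope open — with a `global` option.
Negative corrected values are retained (clamping would bias plate
statistics) and reported via a warning.

## Normalization

The robust z-score is implemented exactly as the printed formula: the MAD
is the plain median of absolute deviations from the median, **unscaled**
by default. The conventional 1.4826 consistency factor is available behind
`mad_scaled = TRUE`, but fidelity to the formula wins over convention;
note that with the unscaled MAD, null z-scores have spread ≈1.48 rather
than 1, so the `|z| ≥ 2` threshold corresponds to ≈1.35 standard
deviations of a Gaussian null.

Decisions the formula's one-line description leaves open, resolved here:

* **Which wells contribute to median/MAD**: valid sample wells only, by
  default. "All samples" most naturally excludes controls and background;
  `include_controls = TRUE` is available since the original choice is
  unstated. Excluded wells still receive a z against the plate statistics,
  flagged `contributing = FALSE`.
* **Even-length medians**: mean of the two central order statistics (the
  universal convention). A consequence verified by test: the plate median
  of contributing z-scores is bit-exactly 0 for odd plate sizes and zero
  to ~1e−15 rounding for even sizes.
* **Degenerate plates**: a zero MAD or fewer than 8 contributing wells is
  a typed error naming the plate, not a silent NaN.
* No winsorizing and no B-score/row-column polish — neither is part of
  the method being reproduced.

## Hit calling

`flag_sirna()` uses inclusive boundaries (`z = 2.0` is a hit). The
candidate rule — at least two passing siRNAs — is applied **per
direction**: a gene scoring +2.2 and −2.2 has two passes but is
biologically incoherent, so passes must agree in sign to count toward a
call, and a gene whose passes split evenly is not called. This is an
interpretation: the method description counts "siRNAs reaching the
threshold" without addressing direction, and the concordant reading is the
conservative one. A called gene's direction is its majority passing sign —
never the opposite, a property tested over random inputs.

Ranking is by cumulative z — by absolute value for the combined list
(increase and decrease candidates share one axis), signed orders for
separate lists — with stable sorting and lexicographic gene-id
tie-breaking so output order is deterministic. Genes with fewer than three
valid z-scores (dropped wells) are scored on what remains, with the
`min_pass` requirement unchanged (conservative) and an `incomplete` flag.

## Validation statistics

* **ΔΔCt**: technical-replicate Cts are averaged per sample;
  ΔCt = target − reference (GAPDH by default); ΔΔCt is taken relative to a
  calibrator sample; RQ = 2^(−ΔΔCt) with amplification efficiency fixed at
  2 (the classic method, no efficiency correction). The calibrator's RQ is
  exactly 1.
* **t-test**: pooled-variance Student's test (the stated method) with
  two-tailed p from the t distribution on n₁+n₂−2 df; Welch's correction
  behind `var_equal = FALSE`. Two constant, equal groups give p = 1 by
  convention. Asterisk labels use strict inequalities, so p = 0.05 exactly
  is `n.s.`.
* **Box-plot summaries**: median, quartiles, and 5th/95th percentiles with
  linear interpolation between order statistics (R's default type-7
  quantile), documented because the convention is otherwise unstated;
  fewer than 20 values triggers a warning since tail percentiles become
  unstable.
* **Error bars**: sample SD (n−1) or SEM = SD/√n.

## Problem sizes used by the test suite

The shipped tests exercise the pipeline at sizes chosen to probe each
property clearly: the z-score oracle comparison uses 1,000 random plates
of 8–96 wells against an independent sort-based median/MAD
implementation; imaging recovery uses 50 noise-free rendered wells at ~15
cells each; end-to-end recovery uses ten screens of 100 genes (20
implanted at |δ| = ln 2, λ = 500 cells/well), pooled, requiring ≥80%
sensitivity with correct direction and ≥95% specificity against the truth
table; determinism re-runs the full 419-gene, 18-plate default screen
twice at well level and compares output files byte for byte.

At the benchmark effect size the observed recovery is essentially complete
(the summed z of three concordant siRNAs at two-fold effects is far from
the calling boundary), and specificity lands near 98% — consistent with a
Gaussian-tail estimate for the unscaled-MAD threshold (per-direction
per-siRNA pass probability ≈0.09, two-of-three concordant ≈2%).

## Known limitations

* Threshold-plus-components segmentation merges touching nuclei and drops
  border-touching ones; dense wells bias counts low.
* The unscaled-MAD z-score makes the effective stringency of `|z| ≥ 2`
  depend on the plate's noise shape; comparisons with screens that use the
  1.4826-scaled convention need `mad_scaled = TRUE`.
* Gene-level calling assumes sibling siRNAs are exchangeable replicates;
  off-target structure, had it been modelled, would break that.
* The t-test and ΔΔCt helpers implement the small-n conventions of
  bench-side validation figures, not a multiple-testing-corrected
  discovery analysis; no FDR control is applied anywhere, matching the
  method being reproduced.
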