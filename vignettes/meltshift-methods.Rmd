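---
title: "Melting-curve analysis in meltshift: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-curve analysis in meltshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the model

A thermal shift assay reads out protein unfolding as a fluorescence ramp:
an environmentally sensitive dye gains quantum yield as it binds the
hydrophobic core exposed during denaturation, so a well's trace shows a
flat pretransition region, a steep sigmoidal unfolding region and, often, a
post-peak decline as aggregates sequester the dye. Ligand binding
stabilizes the fold and moves the transition to higher temperature, so the
screening statistic is the midpoint melting temperature Tm and its shift
ΔTm against DMSO-treated control wells.

`meltshift` fits each well's processed curve to the five-parameter
log-logistic (5PL) sigmoid

$$f(x) = c + \frac{d - c}{\left[1 + \exp\big(b(\ln x - \ln e)\big)\right]^{f}}$$

with slope $b$, lower/upper asymptotes $c$ and $d$, inflection point $e$
(°C) and asymmetry factor $f > 0$. Curve fitting is preferred over the
first-derivative alternative because it is markedly less sensitive to
noise, and the fifth parameter matters: real melts are rarely symmetric
around their inflection, and a 4PL forces the midpoint onto the inflection
point. For an asymmetric sigmoid the half-height midpoint is instead

$$T_m = \frac{e}{\exp\left[-\tfrac{1}{b}\ln\left(2^{1/f}-1\right)\right]},$$

which satisfies $f(T_m) = (c+d)/2$ by construction and collapses to $e$
exactly at $f = 1$. Both identities are asserted numerically in the test
suite over the full parameter space. Under this parameterization a rising
melting curve has $b < 0$; the fit accepts either sign and infers the
direction from the data.

## Well-level quality control

Three rules reject wells whose traces cannot support a sigmoid fit, applied
in order on the window-cropped data:

* **Low signal** — fluorescence range (max − min) strictly below the
  user's signal threshold. These wells (empty, failed dispense, no protein)
  are separated for review and skip the shape checks, since a flat trace
  has no meaningful shape.
* **Inverted shape** — the global maximum occurs at a lower temperature
  than the global minimum, the signature of high initial fluorescence or a
  downward-sloping trace. Ties on the value break to the first occurrence
  in ascending temperature.
* **Discontinuity** — the largest |Δf| between successive readings exceeds
  25× the mean |Δf| of that well (gaps, jumps, spikes). Absolute values are
  used deliberately so a downward spike is as disqualifying as an upward
  one. The multiplier is user-adjustable: noisier data warrant a higher
  value, and the shipped tests document that at the default the rule
  catches spikes of 100× the mean step with zero false positives on clean
  simulated plates. A constant trace (mean step 0) is never flagged here —
  that is the low-signal rule's job.

Boundary semantics are strict: a range exactly equal to the signal
threshold passes, a step ratio exactly 25 passes. The spike test runs on
raw (unsmoothed) readings, since smoothing would dilute exactly the
artifacts it looks for; smoothing happens afterwards, inside the per-well
preprocessing loop.

## Per-well preprocessing

Accepted wells pass through four stages in a fixed order: crop to the
fitting window, 21-point centred simple moving average, 0–1 normalization,
and a trim that keeps only the monotone transition region — first every
reading below the temperature of the global minimum is discarded, then
everything above the global maximum of the remainder. The trim removes the
pretransition dip and the aggregation decline so the optimizer never
chases non-sigmoid structure; restricting the fit to the transition region
is also what keeps a 384-well plate's fits fast.

Choices the data do not dictate, and how they were made:

* **Edge handling for the moving average**: the window shrinks
  symmetrically near the edges (half-width `min(k, i−1, n−i)`), preserving
  series length and endpoint values without inventing padded data.
* **Normalization after smoothing**, so the fit consumes smoothed,
  normalized, trimmed values. Because normalization is a monotone affine
  map, the midpoint Tm is unaffected; only $c$ and $d$ are reported in
  normalized units.
* **Extremum ties** break to the earliest temperature, so flat plateaus
  keep their first point.
* **Minimum surviving points = 8**, three more than the parameter count,
  below which a window or trim error is raised rather than attempting an
  under-determined fit.

One known, quantified limitation: a 21-point average at 0.5 °C spacing is
a 10.5 °C window, and convolving an *asymmetric* sigmoid with it biases
the absolute Tm (≈0.16 °C at $b=-12$, $f=1.4$; ≈0 for symmetric curves).
The bias is common-mode — every well on the plate is smoothed identically —
so ΔTm and hit calls are affected an order of magnitude less, as the test
suite demonstrates. Reducing `smoothing_points` trades this bias against
noise suppression.

## Fitting: initialization, bounds, convergence

The least-squares fit uses Levenberg–Marquardt (`minpack.lm::nlsLM`).
Starting values come from a closed-form heuristic derived from the
symmetric logistic: $c_0, d_0$ from the data range, $e_0$ at the first
half-height crossing, $f_0 = 1$, and
$b_0 = \ln 16 / (\ln t_{20} - \ln t_{80})$ from the first crossings of the
20% and 80% heights (negative for rising melts, as required). The
inflection point is bounded to the fitted temperature span extended by 10%
per side, the asymmetry factor to $[0.05, 20]$; $b, c, d$ are unbounded.
Convergence uses a relative RSS tolerance of $10^{-10}$, a parameter-step
tolerance of $10^{-8}$ and at most 500 iterations; on failure, up to three
restarts perturb $b_0$ (×0.5, ×2) and $f_0$ (0.7, 1.5, 2) on a fixed
schedule — deterministic restarts keep reprocessing bit-reproducible. A
well that still fails yields a non-converged result object rather than an
exception, and non-converged wells are excluded from replicate aggregation
and hit calling. Temperatures enter the model in °C, all positive inside
any realistic fitting window; no Kelvin shift is applied.

Standard errors are asymptotic, from the linearized covariance at the
optimum, and are labelled as such; the residual standard error is
$\sqrt{RSS/(n-5)}$. An independent brute-force check guards the optimizer:
the model is linear in $(c, d)$ given $(b, e, f)$, so a coarse grid over
$(b, e, f)$ with a closed-form solve for $(c, d)$ bounds the attainable
RSS; the test suite verifies on seeded noisy curves that this oracle never
undercuts the optimizer's RSS by more than 1%. Freezing $f = 1$
(`fix_f = 1`) gives the 4PL reduction, and on symmetric data moves Tm by
less than 0.05 °C.

## Hit calling

Converged fits are grouped by compound identifier; the mean and sample
(n−1 denominator — the denominator convention is stated because nothing in
the data forces one) standard deviation of Tm summarize replicates.
Controls are the wells whose compound identifier equals the control token
(default `DMSO`, case-insensitive). The hit threshold is 3 × SD of the
control Tm, and two variants are always reported: the two-sided shift
threshold (3 × SD) and the one-sided absolute level (mean + 3 × SD).
Tagging uses the two-sided rule by default — the report carries |ΔTm|
alongside ΔTm precisely so destabilizers are visible — with
`two_sided = FALSE` switching to the one-sided variant. The boundary is
inclusive. ΔTm is referenced to the control mean of the plate being
processed; cross-plate control pooling is deliberately out of scope, since
plate-to-plate drift is better inspected on the screen-level heatmap than
silently absorbed.

## The simulator and what passing tests mean

`sim_spec()`/`simulate_plate()` generate ground-truth-labelled plates:
each well's trace is `baseline + amplitude · 5PL(t)`, optionally minus a
linear aggregation decline beyond a peak offset, plus i.i.d. Gaussian
noise, written in the instrument export dialect together with SDF and CSV
plate maps and a truth table. Defaults describe a realistic screen: 384
wells, 25→95 °C at 0.5 °C (141 points, a common qPCR melt program),
controls in the first and last columns (32 wells), amplitude 1000 and
noise SD 2 (0.2%) in arbitrary fluorescence units, true control Tm 50 °C,
16 hit compounds at +2 °C, slope −12 and asymmetry 1.3.

Two design points deserve explanation:

* **Exact shifts.** The 5PL midpoint is $e$ times a factor depending only
  on $(b, f)$, so the generator parameterizes wells by target Tm and
  back-solves $e = T_m / k(b,f)$. Configured shifts are therefore exact
  midpoint-Tm shifts, making end-to-end hit recovery exactly checkable.
* **Where Tm variability lives.** Per-well Tm jitter (SD 0.2 °C) is
  applied to control wells, emulating the assay variability one measures
  on DMSO wells; sample wells apply their configured shift exactly by
  default (`tm_sigma_sample = 0`). This separation keeps the ground truth
  of the hit set crisp — a sample-side jitter would occasionally push an
  inactive compound over a 3 × SD threshold by construction, which is a
  statement about the assay, not about the pipeline under test. Sample
  jitter can be enabled to study exactly that.

The simulator reproduces curve anatomy and the three pathology classes
(flat, inverted, spiked wells) but not optical artifacts, well-to-well
crosstalk, meniscus effects, multi-domain melts or mechanistic two-state
thermodynamics. Passing tests therefore certify the pipeline's arithmetic
and its behaviour under the modelled pathologies — not performance on any
particular instrument's quirks, which is what the diagnostic overlay plots
and the adjustable thresholds are for.

Test and validation problem sizes were chosen to exercise the full
geometry at least once while keeping the suite quick: unit tests run on
96-well simulated plates, the QC confusion matrix and the end-to-end hit
recovery on full 384-well plates, parameter recovery on 81-point ramps
with 20 noise seeds, and the grid oracle on 20 seeded curves.

## Reporting

Result files mirror what screening teams pass downstream: an SD file (or
CSV twin) carrying every original plate-map property plus `Tm`, `RSE`,
`dTm`, `abs_dTm`, `hit` and `QC_flags` — flagged wells included, with
empty fit fields — and a five-sheet XLSX workbook (plate heatmap with a
three-color scale, fit results with hits annotated, DMSO mean and SD with
both threshold variants, per-well fit plots, overlay-plot inventory). The
workbook writer is a minimal OOXML component built into the package; it
stores numeric cells at full precision, and the curve sheets reference the
saved PNGs by path rather than embedding images — molecule renderings are
likewise replaced by SMILES text plus compound ID, which survives every
spreadsheet reader. Multi-plate consolidation unites heterogeneous columns
with explicit missing values, records each record's source file, and
writes into a sibling `Consolidated` directory so re-running a
consolidation never ingests its own output.
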