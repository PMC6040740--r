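---
title: "Modelling oxygen consumption rates within and across plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxygen consumption rates within and across plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocrstats)
```

## The within-plate model and its assumptions

A mitochondrial stress test yields, per well, an OCR time series over
four intervals delimited by the oligomycin / FCCP / rotenone injections.
`ocrstats` models the *logarithm* of OCR, because the measurement error
is multiplicative: the spread between replicate wells grows
proportionally with the OCR level, and taking logs makes the variance
approximately level-independent. On the log scale, for one plate,

$$y_{w,t} = \theta_{b(w),\,i(t)} + \beta_w + \varepsilon_{w,t},$$

where $\theta$ is a fixed effect per (biosample, interval) — the
quantity of scientific interest — $\beta_w$ is a per-well offset
absorbing cell-number and calibration differences, and $\varepsilon$ is
homoscedastic noise. The model assumes OCR is roughly constant within an
interval (no within-interval kinetics) and that a well's offset is
common to all its time points. The fit is exact linear least squares
(QR, via `lm.fit`); no iterative optimiser, no regularisation.

**Identifiability.** Adding a constant to $\beta$ over one biosample's
wells while subtracting it from that biosample's four $\theta$ leaves
fitted values unchanged, so one gauge constraint per biosample is
needed. We constrain $\sum_w \beta_w = 0$ *within each biosample*, which
implies the plate-wide mean of $\hat\beta$ is exactly zero and makes the
log OCR well deviation reduce to $d_{w,t} = y_{w,t} - \hat\theta$. A
single plate-wide constraint would not identify the model when several
biosamples share a plate. All reported quantities (fitted values,
metrics, tests) are invariant to this choice; the test suite asserts
equality of fitted values against a reference-well parameterisation.

**Degenerate inputs.** A biosample with a single well is allowed: its
well effect is forced to zero by the gauge and flagged. An empty
(biosample, interval) cell is an error naming the cell, because its
$\theta$ would be inestimable.

## Quality control before fitting

Wells that did not respond to the treatments are removed before any
model fitting using the strict per-well ordering of interval medians
median(Int3) > median(Int1) > median(Int2) > median(Int4); ties count as
violations. The rule is applied to OCR as loaded (instrument background
correction is assumed already applied; blank corner wells are carried in
the data model but never fitted). Manual exclusions (contamination,
detachment) enter as a user-supplied list — no automatic detection is
attempted. Note one interaction worth knowing: a strong positive
plate-interval effect on interval 1 can push a sample with small spare
capacity (Int3 barely above Int1) below the ordering threshold on that
plate, discarding valid wells. The filter is deliberately left strict;
cell lines that genuinely do not respond to the standard treatments
should be analysed with QC disabled (`qc = FALSE`).

## Two-level outlier removal

Outliers occur as whole aberrant wells and as single aberrant points,
and the two need different handling: dropping a well for one bad point
wastes eleven good ones. Both passes alternate fitting with robust
flagging until a fixed point:

* **Well level.** $s_w = \mathrm{mean}_t(d_{w,t}^2)$; flag wells with
  $s_w > \mathrm{median}(s) + 5\,\mathrm{mad}(s)$ (strict), drop, refit.
  Note $d$ retains $\beta_w$, so a well-wide shift is visible in $s_w$.
* **Point level** (after the well pass). Flag points with
  $d^2 > \mathrm{median}(d^2) + 7\,\mathrm{mad}(d^2)$, drop, refit.

Numerical and robustness choices, all configurable:

* `mad` uses the 1.4826 consistency constant, so thresholds read as
  "5 (resp. 7) robust standard deviations above the median".
* Robust statistics pool over the wells/points *of the same biological
  sample* on the plate (`grouping = "biosample"`); per-plate pooling is
  available and is slightly more sensitive when few wells per sample are
  contaminated.
* Strict `>` keeps the zero-mad degenerate case sane (constant vectors
  flag nothing); a numerical guard of `1e-10` on the exceedance prevents
  exact-fit rounding residue from being flagged on noise-free input.
* Safety floors: a biosample is never reduced below 3 wells, and the
  last remaining point of a (biosample, interval) cell is never removed,
  so every interval effect stays estimable. When a floor halts removal a
  warning is raised and the biosample is frozen for further passes.
* Termination is guaranteed: an iteration either removes something
  (strictly shrinking the data) or stops.

## Metrics: ratios, not differences

Because systematic effects are multiplicative, comparisons use
differences of log interval effects, i.e. ratios in natural scale: the
ETC-dependent proportion $1-e^{\theta_{Ei}-\theta_I}$, the
ATPase-dependent proportion, the ETC-dependent proportion of
ATPase-independent OCR, and the maximal-over-initial and
maximal-over-ETC-independent fold changes. The classical natural-scale
measures (basal, ATP-linked, proton leak, spare, maximal,
non-mitochondrial) are recovered from $OCR_i = e^{\hat\theta_i}$ and
satisfy exact dualities with the ratios (e.g. basal$/OCR_1$ = EI
proportion), which the tests assert to 1e-10.

Within-plate well-to-well variability is summarised by the standard
deviation $\sigma_{p,i}$ of log OCR per plate and interval (over all
included observations — the aggregation across time points is a
documented choice), its median $\bar\sigma_i$ across plates, and the
natural-scale approximation $CV \approx e^{\bar\sigma}-1$. The simpler
$e^{\sigma}-1$ form is used rather than the exact lognormal
$\sqrt{e^{\sigma^2}-1}$ deliberately, to match how such CVs are
conventionally reported for these assays; rounding to whole percent
happens only at the reporting layer.

## Plate-interval effects and the control anchor

Treatment concentrations and instrument conditions shift whole
plate-intervals — e.g. a rotenone batch moving interval 4 of one plate
only. Two defences are built in. First, the cross-plate test uses
$\Delta\Delta\theta$: the log-ratio of a sample minus that of the
*plate-matched control*, in which any additive (plate, interval) shift
cancels exactly — this holds with no correction at all and is asserted
to 1e-10. Second, for natural-scale measures (where cancellation is not
available), the model
$y = \theta_{c,i} + \beta_{i,p} + \varepsilon$ is fitted to the control
biosample only and the $\hat\beta_{i,p}$ are supplied as offsets for a
corrected refit (`OCR-PE`). The gauge here is mean zero over plates per
interval (only contrasts between plates are identified; an absolute
shift of one plate changes corrected levels by a constant per interval,
common to every plate and biosample, leaving all contrasts and ratio
metrics untouched). The correction is estimated after outlier removal
and outlier removal is not re-run on corrected data. The control is
excluded from corrected benchmark summaries, since it anchors the
correction.

## Cross-plate testing

For each ratio metric, $\Delta\Delta\theta_{b,p} = \mu_b +
\epsilon_{b,p}$ is fitted jointly over all biosamples — equivalently
$\hat\mu_b$ is the across-plate mean with error variance pooled over the
complete data set, $\hat\sigma^2 = \sum(\Delta\Delta\theta-\hat\mu_b)^2
/ (N-B)$. Pooling borrows strength so that even a sample on a single
plate is testable; the price is an equal-variance assumption across
samples. Each $\mu_b$ gets a t test on $N-B$ degrees of freedom and a
95% interval; `qq_residuals()` provides the normality diagnostic. Raw
p-values are reported by default (Benjamini-Hochberg behind
`p_adjust = "BH"`); the natural-scale effect is $e^{\hat\mu_b}$ with
exponentiated CI endpoints. The closed form is asserted against `lm()`
to 1e-10 in the tests, and calibration is verified by simulation at
20 biosamples x 3 plates over 1000 replicates: the rejection rate at
the 5% level must fall in [0.04, 0.06] and CI coverage in
[0.93, 0.97].

## Baselines

The vendor-style Extreme Differences estimator takes, per well on *raw*
(pre-outlier-removal, QC-filtered) data, the last point of interval 1,
the minima of intervals 2 and 4, and the maximum of interval 3, forms
the natural-scale measures, and averages across wells per plate. Its
within-plate Wilcoxon rank-sum test treats wells as independent
replicates of the biological claim, which they are not — per-plate
conclusions can disagree across plates. Its across-plate paired
signed-rank variant is sound but needs at least five plates: the exact
two-sided signed-rank distribution cannot go below p = 0.125 at n = 4
(0.0625 at n = 5). Exact p-values are used for small n, the tie-corrected
normal approximation otherwise.

## Power analysis

The minimal detectable relative difference at significance level 5% with
$n$ plates is $e^{1.96\,sd(\epsilon)/\sqrt{n}} - 1$, with 1.96 kept as
the conventional normal quantile (an exact-t option exists for small
$n$). `subsample_power_curve()` re-runs the full pipeline on random
subsamples of 4..16 wells per biosample (10 samplings each, without
replacement, seeded) and records the pooled residual sd per metric.

## The simulator: what it emulates and what it does not

`simulate_plates()` generates data from exactly the structure the method
assumes: log OCR = interval effect + well effect (zero-sum per
biosample, sd 0.1) + plate-interval effect (sd 0.15, larger than the
within-plate components, as observed between plates) + Gaussian noise
(sd 0.1), with 12 time points in 4 intervals of 3, a control on every
plate, 4 test biosamples of 12 wells (typical layouts carry 3-7 samples;
12 wells is the recommended minimum), blank corner wells, and the
canonical profile log(100, 40, 150, 20) giving the interval ordering
Int3 > Int1 > Int2 > Int4. Outlier wells (whole-well log shifts of
random sign), outlier points, and non-responder wells (flat at the
interval-1 level) are injected explicitly at configurable rates
(default 0 — the clean generative model), with ground-truth masks
returned for recovery scoring.

Deliberate omissions, and what they mean for the tests: no
within-interval kinetics (interval levels are constant); no positional
(edge) structure by default — the positional diagnostics are exercised
by injecting edge effects explicitly; no heavy-tailed noise (outliers
are explicit injections instead); and no biosample-by-plate interaction
beyond the shared plate-interval effect. The last point matters for
power curves: since the shared plate-interval effect cancels in the
control-matched differences, the simulated residual sd falls toward
zero as wells increase instead of plateauing at a positive between-plate
floor, as it does in real data where samples respond to plate conditions
idiosyncratically. Passing tests therefore demonstrate correctness of
the machinery under the stated model, not robustness to structure the
model excludes.

## Validation problem sizes

The suite validates the solver against an independent pseudoinverse
oracle on 100 random small plates (1e-10), outlier recovery on 50 seeded
single-plate simulations per scenario (well shifts of e^0.5 on 2 of 12
wells; point shifts of e^1.0 on 3% of points), test calibration on 1000
replicates of 20 biosamples x 3 plates, and end-to-end CI coverage on
150 pipeline replicates of a reduced configuration (3 plates, 2 samples
plus control, 4 wells each). These sizes give stable Monte-Carlo
estimates at percent-level tolerances while keeping the default test run
short.

## Known limitations

* The equal-variance assumption of the pooled test can be violated by a
  contaminated sample, inflating the pooled sd and dulling all other
  comparisons; inspect residuals per biosample.
* The QC ordering filter presumes the standard stress-test response and
  will discard lines that genuinely lack spare capacity.
* The plate-interval correction relies entirely on the control line;
  plates without the control receive no offset.
* ECAR (the acidification readout) is not modelled.
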