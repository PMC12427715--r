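---
title: "Methods: storage-quality indexing and VIS-NIR calibration for date fruits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: storage-quality indexing and VIS-NIR calibration for date fruits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical methods implemented in `dateqi`, the
assumptions behind them, the default parameter values and why they were
chosen, and the limits of the synthetic data generator. It is a methods
reference, not a tutorial; the README walks through a complete worked
example.

## 1. The composite quality index Qi

Stored date fruits are scored on fourteen attributes: seven physicochemical
(moisture, water activity, total soluble solids, browning index, total
colour difference, pH, hardness) and seven hedonic sensory scores on a 1-9
scale. Each attribute is min-max normalized over the calibration dataset,

$$\hat X = \frac{X - X_{\min}}{X_{\max} - X_{\min}},$$

and attributes for which *lower* raw values indicate better quality
(browning index, colour difference, water activity) are reversed as
$1 - \hat X$, so that every normalized contribution points the same way.
Qi is the equal-weight mean of the normalized contributions, hence bounded
in [0, 1] with 1 = best observed quality.

Assumptions and consequences:

* **The extrema are dataset statistics.** `build_normalization_spec()`
  freezes $X_{\min}, X_{\max}$ per attribute on the *training* records;
  `compute_qi()` then applies the frozen spec everywhere, clipping
  out-of-range values to [0, 1] rather than extrapolating. This is the
  anti-leakage discipline used throughout the package: every stateful
  transform is fit on training rows only.
* **Equal weights.** No attribute weighting is applied; the index treats
  the fourteen attributes as equally informative. Changing the attribute
  list (`qi_attributes` in `run_config()`) changes the meaning of Qi.
* **Qi is relative.** Because the extrema are dataset statistics, Qi values
  are comparable within one frozen spec, not across specs. This is why
  degradation analysis of the *generator's* latent quality uses
  `qi_col = "qi_latent"` (absolute scale), while `cmd_degradation()` on
  computed Qi characterizes the dataset at hand.

## 2. Colour derivatives

From CIELAB readings the package derives chroma
$\sqrt{a^{*2} + b^{*2}}$, hue angle ($\operatorname{atan2}(b^*, a^*)$
mapped to [0°, 360°)), the browning index

$$BI = \frac{100\,(x - 0.31)}{0.17}, \qquad
  x = \frac{a^* + 1.75\,L^*}{5.645\,L^* + a^* - 3.012\,b^*},$$

and the total colour difference $\Delta E$, the Euclidean distance in
CIELAB coordinates. `delta_e()` has a `strict` flag that reproduces a
published variant in which the $\Delta b^*$ term enters with a negative
sign under the square root; it errors whenever that expression is not a
real number and exists only as an audit aid. The default is the standard
Euclidean form.

## 3. Degradation models: quadratic vs. linear

Per cultivar, cell-mean Qi versus storage month $t$ is modelled as

$$Q_i(t) = a\,t^2 - b\,t + c,$$

the sign convention in which published coefficient tables are printed
(`fit_degradation()` stores `b` so that the printed formula holds; the
underlying `lm()` fit is available as `fit$lm_fit`). Model choice between
degree 1 and 2 uses two criteria:

* **AIC**, in the profile-Gaussian form $n \ln(\mathrm{RSS}/n) + 2k$ with
  $k = \text{degree} + 2$ (polynomial coefficients plus the error
  variance). This form is exact for least-squares fits with Gaussian
  errors up to an additive constant that cancels in comparisons; a perfect
  fit (RSS = 0) makes it undefined and `degradation_aic()` errors rather
  than returning $-\infty$.
* **The nested F-test**, $F = \frac{(\mathrm{RSS}_1 - \mathrm{RSS}_2)}
  {\mathrm{RSS}_2 / (n - 3)}$ with 1 and $n-3$ degrees of freedom,
  identical to `anova(lm_linear, lm_quadratic)` (which the test suite uses
  as the oracle).

Both are computed on the same cell-mean series, so they answer "is the
curvature real at the resolution of the monthly means", not "per fruit".
`shelf_life_at()` inverts the fitted quadratic for the first crossing of a
quality threshold within the observed time range and returns `NA` outside
it — the model is not trusted for extrapolation.

## 4. Spectral preprocessing

The preprocessing chain, in fixed order:

1. **Windowing** to 410-990 nm (the instrument's informative range; on the
   default 3-nm grid this retains 194 points, 411-990 nm).
2. **Absorbance conversion** $A = \log_{10}(100 / R\%)$.
3. **Multiplicative scatter correction (MSC)**: each spectrum is regressed
   on a reference spectrum and corrected as
   $(x - \hat\alpha)/\hat\beta$. The reference is the *training* mean
   spectrum, stored in the fitted pipeline and reused verbatim for new
   data.
4. **Savitzky-Golay second derivative**, default window 13 points
   (39 nm), polynomial order 2. Coefficients are derived from the local
   polynomial least-squares fit via the pseudoinverse; the output is
   trimmed to the valid interior (no edge padding), losing
   $(w-1)/2$ points per edge.

Order matters: MSC before differentiation removes multiplicative scatter
while the baseline is still additive; the second derivative then removes
the remaining additive baseline and slope exactly (it annihilates
polynomials of degree < 2 — a property the tests verify). The default
window width is a bias-variance compromise at 3-nm resolution: wide enough
to suppress white noise amplification (second derivatives amplify high
frequencies), narrow enough not to flatten the ~30-60 nm absorption bands.
`select_sg_window()` can score alternative windows by calibration RMSECV,
but window selection is off by default — the window is treated as a method
constant, not a tunable, to avoid an extra selection layer leaking into
the reported cross-validation error.

## 5. Replicate-aware splitting

`split_dataset()` partitions at the *replicate group* level (all scans of
one fruit-month sample share `replicate_group_id`), so near-duplicate
spectra can never straddle a split boundary. Targets come from
largest-remainder apportionment of the 70/20/10 fractions; groups are
shuffled under the seed and assigned greedily to the subset with the
largest remaining deficit. With singleton groups and divisible counts the
subset sizes are exact (15,000 samples → 10,500/3,000/1,500).

The three subsets have fixed roles:

* **70% calibration** — all model fitting, the Qi normalization spec, the
  MSC reference, input standardization, and the PLSR latent-variable
  search.
* **20% tuning** — early stopping of the neural network (its
  replicate-disjoint validation split), and the error reported in the
  RMSECV column for that model.
* **10% independent prediction** — untouched until final evaluation;
  RMSEP, REP and RER are computed here, matching the definition of RMSEP
  as the error on an independent prediction set.

## 6. PLSR and latent-variable selection

`plsr_fit()` implements single-response NIPALS: predictors and response
are mean-centred (no variance scaling — after the derivative step all
channels share one scale, and autoscaling would inflate noise channels),
components are extracted by iterating the weight-score-loading cycle to
`tol = 1e-10`, and X is deflated by each component. The regression vector
is $B = W (P^\top W)^{-1} q$. At full rank NIPALS PLSR equals OLS, which
the tests exploit as an oracle.

The number of latent variables is chosen by grouped k-fold
cross-validation (`cross_validate_lv()`, default 10 folds): replicate
groups are shuffled and dealt round-robin into folds, every component
count up to `max_components` (default 12) is scored on the held-out folds,
and the count minimizing RMSECV is selected, ties resolving toward fewer
components. A one-standard-error rule (`one_se = TRUE`) picks instead the
smallest count whose RMSECV is within one between-fold standard error of
the minimum; it is the standard parsimony guard when the RMSECV curve has
a flat tail and the plain minimum occasionally spends a component on
noise. The pipeline default is the plain minimum; the rank-recovery
property tests use the one-SE rule because their success criterion is
exact recovery of a known low rank.

## 7. The neural-network regressor

`mlp_fit()` is a small fully connected network written in-package: inputs
standardized with training statistics, one hidden layer of 32 tanh units
by default, a linear output unit, mean-squared-error loss, mini-batch
Adam (learning rate 0.01, batch 64), early stopping on the 20% tuning
split with patience 50 over at most 600 epochs, and restoration of the
best-validation weights. All randomness (initialization, batch order)
derives from the config seed, so training is bit-reproducible.
Predictions are clipped to [0, 1] at predict time because Qi is defined on
that interval. Defaults were sized so that the default desk-scale training
run converges well inside its early-stopping budget; they are training
*budgets*, not tuned hyperparameters.

Two reporting decisions deserve explicit statement:

* **The ANN's "RMSECV" column is the tuning-split error.** Refitting the
  network once per CV fold would multiply training cost by the fold count
  for a quantity the workflow does not consume (the network has no
  discrete complexity parameter being selected). The column is therefore
  the replicate-disjoint 20%-split error — a validation error, not a
  k-fold estimate — and the two models' RMSECV columns are not strictly
  comparable.
* **Model comparison uses the independent 10% split.** Because the CV
  columns measure different things, the PLSR-vs-ANN comparison (and the
  acceptance expectation that the network does not trail the linear model
  on a nonlinear generator) is evaluated on `r_squared_test` / RMSEP,
  where both models face identical, untouched data.

## 8. Microbial release rules

`release_decision()` applies per-analyte thresholds (total viable count:
accept ≤ 5.0, hold ≤ 6.0, reject > 6.0 log CFU/g; yeast: accept ≤ 4.0,
hold ≤ 5.0, reject > 5.0) and combines analytes by worst case. Intervals
are half-open with the acceptance side inclusive: a count exactly at a
limit takes the milder category. `screen_batch()` lifts the rule to lots:
any reject excludes, otherwise any hold flags, otherwise released.

## 9. The synthetic generator: what it emulates and what it cannot

`simulate_storage_study()` emulates the *structure* of a two-cultivar
storage study — the full factorial of moisture groups (Control, A-E),
temperatures (25, 5, −18 °C), packaging types (OCC, CCC, CCSPB, SSPC,
PSSPC), 13 monthly time points, replicate fruits and replicate scans — so
that every pipeline stage is exercisable without instrument data. Its
calibration anchors are measured quantities:

* initial moisture is drawn per cultivar-group from the measured
  means/SDs (`moisture_table()`);
* latent quality follows each cultivar's published quadratic, with the
  time-dependent part scaled by temperature × packaging severity
  multipliers. The multipliers each average to 1 across their full factor
  levels, so cell-mean trajectories over the full design reproduce the
  quadratics — this is what makes the parameter-recovery acceptance
  property meaningful rather than circular;
* microbial log counts interpolate linearly between tabulated month-3 and
  month-12 anchors per (cultivar, group, temperature), with additive
  packaging offsets that vanish for the anchor's reference packaging.

Spectra are built in absorbance space as a baseline plus Gaussian bands
tied to browning index (450/560/680 nm), soluble solids (840 nm) and
moisture (970 nm, the water overtone region). Band amplitude is
$s\,(x + 0.5\,x^2)$ in the normalized attribute $x$ — the quadratic term
is a deliberate nonlinearity so that a nonlinear regressor has signal to
gain over PLSR. Scans get a per-scan baseline slope, multiplicative
scatter and additive reflectance noise, which is exactly the degradation
the MSC + derivative chain is designed to remove.

Limits, stated plainly: band positions, sensitivities and the severity
multipliers are generator conventions, not instrument claims; the
generator cannot reproduce published calibration R² values obtained on
real spectra, and no acceptance property asks it to. Generator defaults
are the study conditions — they are not adjusted to make downstream
checks pass.

## 10. Numerical choices

* NIPALS inner tolerance 1e-10 / 500 iterations: convergence is quadratic
  for single-response PLS, so the cap is never reached in practice.
* SG coefficients via `MASS`-free pseudoinverse of the local Vandermonde
  design (solved with `qr.solve` on $(V^\top V)$): exact for polynomials
  up to the fit order, verified against `signal::sgolayfilt`.
* AIC in profile form (no additive constant): only differences are ever
  used.
* Combined metric rows are rounded *half-up* at table precision (3/2/1
  decimals for RMSEP/REP/RER), matching how printed tables round, not
  banker's rounding (`round_half_up()`).
* Qi and the degradation fits use base `lm()` as the least-squares
  engine; the package's own code confines itself to the algorithms that
  carry method content (NIPALS, SG, MSC, the network).

## 11. Desk scale

The default `desk_design()` (2 cultivars × 3 groups × 2 temperatures × 2
packagings × 5 fruits × 13 months × 3 scans = 4,680 spectra) is a package
choice sized so that a complete simulate → calibrate → evaluate →
degradation run finishes in minutes on one CPU. `run_config(scale =
"full")` switches to the complete factorial. All statistical behaviour
(splitting, leakage discipline, selection rules) is identical at both
scales; only the factor coverage and sample counts change.
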