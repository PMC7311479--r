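---
title: "Models, estimators and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimstab)
```

# Scientific setting

S-nitrosylation — the covalent addition of a nitric-oxide group to cysteine
thiols — modifies the luminal (ER-resident) domain of the calcium sensor
STIM2 at Cys15, Cys53 and Cys60. The modification stabilises the domain
thermally and thermodynamically, suppresses store-operated calcium entry
(SOCE), and raises basal cytosolic calcium when STIM2 is overexpressed.
This package implements the quantitative analyses behind those statements:
CD thermal melts, chemical (urea) denaturation, NMR chemical-shift
perturbation (CSP) mapping, and Fura-2 ratiometric calcium imaging —
together with synthetic-data generators that embed known ground truth so
every estimator can be validated end to end.

# Thermal melts: Boltzmann sigmoid

CD ellipticity at 222 nm is fit to

$$\theta(T) = \theta_\text{post} +
  \frac{\theta_\text{pre} - \theta_\text{post}}
       {1 + \exp\!\big((T - T_m)/k\big)}$$

optionally with linear pre/post baselines. Because these melts are
irreversible, $T_m$ is an *apparent* melting temperature: valid for
within-study comparison, not a true equilibrium constant. `fit_boltzmann()`
uses Levenberg–Marquardt least squares with a multi-start over the 25/50/75
per cent signal quantiles, keeping the lowest residual sum of squares.
S-nitrosylation shifts are formed by `delta_tm()` with the error of the
difference propagated in quadrature, $\sqrt{s_1^2 + s_2^2}$.

```{r}
cv <- gen_melt_curve(melt_truth(tm = 63.2), seed = 1)
fit_boltzmann(cv)
```

# Chemical denaturation: global two-state fit

Reversible urea unfolding follows the linear extrapolation model: the
unfolding free energy is linear in denaturant,
$\Delta G(D) = \Delta G_{H_2O} - mD$, giving

$$f_u(D) = \mathrm{logis}\!\left(\frac{mD - \Delta G_{H_2O}}{RT}\right),
\qquad
y(D) = (a_f + b_f D)(1 - f_u) + (a_u + b_u D)\, f_u$$

with $R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and $T = 293.15$ K.
`fit_two_state_global()` fits all replicates simultaneously with
$\Delta G_{H_2O}$ and $m$ shared and the four baseline parameters free per
replicate; the logistic form keeps the model numerically stable at
arbitrarily large exponents. The midpoint is $C_\text{mid} = \Delta G/m$
and condition differences are formed by `delta_delta_g()` with quadrature
errors.

Two standard-error conventions exist in the literature: the covariance
matrix of the global fit (`se_mode = "global"`, the default) and the SEM of
independent per-replicate fits (`se_mode = "per_curve"`). Both are
implemented because the published tables do not state which was used; the
point estimates are identical either way.

## Precision floor for $\Delta G$ recovery

A design question worth recording: at the study-like synthetic design
(3 replicates × 25 points over 0–6 M, 1 % multiplicative noise, free sloped
baselines per replicate), how well *can* $\Delta G_{H_2O}$ be recovered?
The Cramér–Rao bound computed from the model Jacobian puts the attainable
standard error at roughly 0.12–0.18 kcal mol$^{-1}$, which implies a median
absolute error near 0.1 kcal mol$^{-1}$ for any unbiased estimator.
Simulation agrees: over 100 seeds the median $|\hat{\Delta G} - \Delta G|$
is ≈ 0.10, with median $|z|$ ≈ 0.7 confirming the reported standard errors
are calibrated. Relative weighting of the residuals (the maximum-likelihood
form under multiplicative noise, weighting by either the observed or the
model signal) improves this only to ≈ 0.09. A target of 0.05 kcal
mol$^{-1}$ is therefore not attainable at these conditions — the
corresponding acceptance assertion is deliberately left failing rather than
weakened or silently re-tuned. The $m$-value, by contrast, is recovered
with median error ≈ 0.03 kcal mol$^{-1}$ M$^{-1}$, and noiseless data are
recovered to relative error below $10^{-5}$. Much smaller printed
uncertainties (e.g. ±0.02) are consistent with lower-noise instruments or
tighter baseline constraints than the deliberately conservative generator
assumes.

## Published-table reproduction

`stim_thermal_params()` and `stim_chemical_params()` ship the published
(mean ± SEM) fit parameters;
`reproduce_thermal_deltas()` / `reproduce_chemical_deltas()` recompute every
printed $\Delta T_m$, $\Delta\Delta G$ and propagated error at the printed
rounding. All ten $\Delta T_m$ rows and seven of eight $\Delta\Delta G$
cells reproduce exactly. The exceptions are internal inconsistencies of the
printed tables at their own precision, which the agreement flags expose
rather than hide:

* the C53S/C60S $\Delta\Delta G$ cell prints 0.10 while its own $\Delta G$
  entries give $3.63 - 3.54 = 0.09$;
* several printed $C_\text{mid}$ cells do not equal their row's
  $\Delta G/m$ at two decimals (e.g. wild-type Ca$^{2+}$-loaded: printed
  3.34 and 3.58 vs computed 3.35 and 3.74). The self-consistent cells
  (2.85, 3.11, 3.69, 2.36, 3.09, 3.29, 1.33) all reproduce.

A related arithmetic note: for $\Delta G = 4.82$, $m = 1.69$, $D = 2.85$
the two-state signal with unit folded / zero unfolded baselines evaluates
to 0.5015022 (the equilibrium constant is 0.9940), not exactly 0.5 — the
midpoint 4.82/1.69 is 2.85207, not 2.85.

```{r}
ch <- reproduce_chemical_deltas()
ch[, c("construct", "ca_state", "ddg_rounded", "ddg_printed", "ddg_matches")]
```

Cross-paralog comparisons (`cross_paralog_differences()`) reproduce the
discussed STIM2-minus-STIM1 free-energy differences: −0.4 (Ca-loaded,
GSNO), +2.8 (Ca-depleted, GSNO), +1.0 and +3.1 kcal mol$^{-1}$ (reducing).

# NMR chemical-shift perturbation

Per-residue amide perturbations use the conventional nitrogen weighting
$w = 0.14$ that places $^{15}$N shift changes on the $^1$H scale:

$$\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2}$$

`read_peaklist()` accepts Sparky-style or CSV lists (the N and H dimensions
are told apart by their ppm ranges); `match_peaks()` pairs by assignment or,
when assignments differ, by greedy minimum weighted distance with an
acceptance cutoff, never silently dropping peaks. The significance
threshold is the iterative trimmed mean + SD of the profile (points above
mean + 3 SD excluded until stable), and `detect_clusters()` reports
contiguous perturbed stretches spanning at least 3 residues, tolerating
single-residue gaps (unassigned prolines, overlapped peaks).
`map_to_structure()` writes 100 × CSP into the PDB B-factor column (capped
at the column's 999.99 format limit) via `bio3d` for structure colouring.

# Fura-2 calcium imaging

Ratios $R = F_{340}/F_{380}$ are converted to concentrations with the
Grynkiewicz relation

$$[\mathrm{Ca}^{2+}] = K_d\,\beta\,\frac{R - R_\min}{R_\max - R},$$

$K_d = 225$ nM, with $R_\min$, $R_\max$ and $\beta$ derived from in-situ
Triton/EGTA calibration segments. Basal calcium is the mean ratio over the
30 s preceding EGTA addition; baselines for $F/F_0$ use the 50 s
(suspension) or 80 s (plate) window before thapsigargin; peak SOCE is the
mean over 450–550 s after calcium add-back. Windows are defined by *time*,
not point count, so they are robust to the sampling interval, and windows
that end at a reagent addition are half-open — the sample acquired at the
addition instant belongs to the response. Plate-reader acquisitions lack
absolute calibration, so that protocol reports ratio differences
($F_\text{basal} - F_0$, $F_\text{SOCE} - F_0$) instead of concentrations.

The single-cell population comparisons reported for the cell-biology
experiments depend on unreleased raw measurements and are **not**
reproducible from published numbers. They are covered instead by synthetic
fixtures that embed the printed values as generator ground truth — e.g. a
118 nM control group versus a 2-fold-enhanced group, which the pipeline
must recover and distinguish by `unpaired_t_test()` (classic equal-variance
Student's form, as stated in the study's methods; Welch available via
`welch = TRUE`).

```{r}
ft <- gen_fura_trace(fura_truth(basal_nM = 118, noise_sd = 0.05), seed = 1)
basal_concentration(ft$trace, ft$truth$calib)
```

# Synthetic-data generators

All generators (`gen_melt_curve()`, `gen_denaturation_replicates()`,
`gen_peaklist_pair()`, `gen_fura_trace()`) are pure functions of a truth
object and a seed: identical inputs give bit-identical output, and the
caller's RNG stream is saved and restored. Noise models are deliberately
simple but honest about their realism limits: Gaussian additive noise for
CD (instrument-dominated), multiplicative for fluorescence
(shot-noise-like), independent per-peak jitter for shifts (no peak overlap
is simulated), and channel-level noise plus in-situ calibration segments
for Fura-2. At zero noise each generator reproduces its analytic model
exactly, which the test suite asserts.

# Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes the main
quantities (printed-delta reproduction, recovery medians over 100 seeds,
cluster counts, calcium round trips) as a flat JSON file, and the numbered
scripts under `analysis/` run the simulate → fit → report workflow into
`results/`.
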