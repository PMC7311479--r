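#' Gas constant in kcal mol^-1 K^-1
#' @export
R_KCAL <- 1.987e-3

#' Construct a urea denaturation curve
#'
#' Intrinsic tryptophan/tyrosine fluorescence of samples equilibrated
#' overnight across a 0-6 M urea gradient; reversible unfolding makes these
#' curves amenable to equilibrium two-state analysis by the linear
#' extrapolation method.
#'
#' @param denaturant numeric vector of urea concentrations (M), >= 0 and
#'   strictly increasing, at least 8 points.
#' @param signal fluorescence intensity (arbitrary units), same length.
#' @param replicate_id replicate label.
#' @param protein_id,condition,ca_state metadata as for [melt_curve()].
#' @return An object of class `denaturation_curve` (a data frame).
#' @export
denaturation_curve <- function(denaturant, signal, replicate_id = "rep1",
                               protein_id = "protein",
                               condition = c("DTT", "GSNO"),
                               ca_state = c("loaded", "depleted")) {
  condition <- match.arg(condition)
  ca_state <- match.arg(ca_state)
  if (length(denaturant) != length(signal))
    stop("denaturant and signal must have equal length")
  if (length(denaturant) < 8)
    stop("a denaturation curve needs at least 8 points")
  if (any(denaturant < 0)) stop("denaturant concentrations must be >= 0")
  if (any(diff(denaturant) <= 0))
    stop("denaturant must be strictly increasing within a replicate")
  if (any(!is.finite(signal))) stop("non-finite signal values")
  out <- data.frame(denaturant = denaturant, signal = signal,
                    replicate_id = replicate_id)
  attr(out, "protein_id") <- protein_id
  attr(out, "condition") <- condition
  attr(out, "ca_state") <- ca_state
  class(out) <- c("denaturation_curve", "data.frame")
  out
}

#' Read denaturation replicates from delimited text
#'
#' Expects columns `urea_M`, `fluorescence_au`, `replicate` (CSV or TSV).
#'
#' @param path file path.
#' @inheritParams denaturation_curve
#' @return A list of [denaturation_curve()] objects, one per replicate.
#' @export
read_denaturation_curves <- function(path, protein_id = "protein",
                                     condition = "DTT", ca_state = "loaded") {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("urea_M", "fluorescence_au", "replicate")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$urea_M), ]
    denaturation_curve(d$urea_M, d$fluorescence_au,
                       replicate_id = as.character(d$replicate[1]),
                       protein_id = protein_id, condition = condition,
                       ca_state = ca_state)
  })
}

#' Two-state equilibrium unfolding signal
#'
#' Linear extrapolation method: the unfolding free energy depends linearly on
#' denaturant, dG(D) = dg - m*D, so the unfolding equilibrium constant is
#' K_U = exp(-(dg - m*D)/(R*T)). The observed signal is the population-
#' weighted average of linear folded and unfolded baselines:
#' `[(a_f + b_f*D) + (a_u + b_u*D) * K_U] / (1 + K_U)`.
#' Evaluated through the logistic function so it is stable for arbitrarily
#' large |exponent|.
#'
#' @param D denaturant concentration (M), vectorised.
#' @param dg Gibbs free energy of unfolding in water (kcal/mol).
#' @param m denaturant dependence, m-value (kcal/mol/M), > 0 for fitting.
#' @param baselines numeric `c(a_f, b_f, a_u, b_u)`: folded intercept/slope,
#'   unfolded intercept/slope.
#' @param temperature absolute temperature (K), default 293.15 (20 degC).
#' @param gas_constant kcal/mol/K, default [R_KCAL].
#' @return numeric vector of model signal values.
#' @export
two_state_signal <- function(D, dg, m, baselines = c(1, 0, 0, 0),
                             temperature = 293.15, gas_constant = R_KCAL) {
  if (any(!is.finite(c(D, dg, m, baselines, temperature))))
    stop("non-finite inputs to two_state_signal")
  if (temperature <= 0) stop("temperature must be positive (Kelvin)")
  fu <- stats::plogis(-(dg - m * D) / (gas_constant * temperature))
  folded <- baselines[1] + baselines[2] * D
  unfolded <- baselines[3] + baselines[4] * D
  folded * (1 - fu) + unfolded * fu
}

#' Fraction of molecules unfolded at a denaturant concentration
#'
#' `K_U / (1 + K_U)` under the linear extrapolation model; equals 0.5 at the
#' midpoint D = dg/m and increases monotonically with denaturant.
#'
#' @inheritParams two_state_signal
#' @return numeric vector in \[0, 1\].
#' @export
fraction_unfolded <- function(D, dg, m, temperature = 293.15,
                              gas_constant = R_KCAL) {
  if (temperature <= 0) stop("temperature must be positive (Kelvin)")
  stats::plogis(-(dg - m * D) / (gas_constant * temperature))
}

# Pack/unpack the global-fit parameter vector:
# (dg, m, then per replicate a_f, b_f, a_u, b_u -- or one shared quartet).
ts_resid <- function(p, curves, temperature, shared_baselines) {
  dg <- p[1]; m <- p[2]
  res <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    j <- if (shared_baselines) 3L else 3L + 4L * (i - 1L)
    bl <- p[j:(j + 3L)]
    mod <- two_state_signal(curves[[i]]$denaturant, dg, m, bl, temperature)
    res[[i]] <- curves[[i]]$signal - mod
  }
  unlist(res, use.names = FALSE)
}

#' Global two-state fit of replicate denaturation curves
#'
#' Fits the linear-extrapolation two-state model to all replicates at once
#' with `dg_h2o` and `m_value` shared across replicates and the four linear
#' baseline parameters free per replicate (or shared, see
#' `shared_baselines`). Initialisation is multi-start over a grid of
#' (dg, m) guesses (dg in 1, 3, 5, 8 kcal/mol; m in 1, 2, 3 kcal/mol/M),
#' keeping the lowest residual sum of squares. Standard errors for the
#' shared parameters come, by default, from the covariance matrix of the
#' global fit; `se_mode = "per_curve"` instead refits each replicate
#' independently and reports the SEM of the per-curve estimates.
#'
#' @param replicates a single [denaturation_curve()] or a list of them
#'   (same condition).
#' @param temperature K, default 293.15.
#' @param shared_baselines logical; default FALSE (per-replicate baselines).
#' @param se_mode `"global"` (covariance of the global fit, default) or
#'   `"per_curve"` (SEM over independent single-replicate fits).
#' @return An object of class `two_state_fit` with `dg_h2o`, `m_value`,
#'   `cmid` (= dg/m), `se_dg`, `se_m`, per-replicate `baselines` (matrix),
#'   `residual_ss`, `n_points`, `temperature`, `se_mode`, and a
#'   `post_transition` flag that is FALSE (with a warning) when no replicate
#'   extends past the estimated midpoint.
#' @export
fit_two_state_global <- function(replicates, temperature = 293.15,
                                 shared_baselines = FALSE,
                                 se_mode = c("global", "per_curve")) {
  se_mode <- match.arg(se_mode)
  if (inherits(replicates, "denaturation_curve")) replicates <- list(replicates)
  if (length(replicates) < 1) stop("at least one replicate is required")
  nrep <- length(replicates)
  nbl <- if (shared_baselines) 1L else nrep

  bl0 <- lapply(replicates[seq_len(nbl)], function(cv) {
    k <- max(3L, nrow(cv) %/% 5L)
    c(mean(utils::head(cv$signal, k)), 0, mean(utils::tail(cv$signal, k)), 0)
  })
  bl0 <- unlist(bl0)

  starts <- expand.grid(dg = c(1, 3, 5, 8), m = c(1, 2, 3))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- c(starts$dg[s], starts$m[s], bl0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = ts_resid, curves = replicates,
        temperature = temperature, shared_baselines = shared_baselines,
        lower = c(-Inf, 1e-6, rep(-Inf, length(bl0))),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- fit$deviance
    if (is.null(best) || ss < best$deviance - 1e-12) best <- fit
  }
  if (is.null(best)) stop("global two-state fit failed to converge")

  p <- best$par
  dg <- p[1]; m <- p[2]
  npts <- sum(vapply(replicates, nrow, 0L))
  npar <- length(p)
  sm <- summary(best)
  se <- sm$coefficients[, "Std. Error"]
  se_dg <- se[1]; se_m <- se[2]

  if (se_mode == "per_curve" && nrep > 1) {
    per <- vapply(replicates, function(cv) {
      f <- fit_two_state_global(list(cv), temperature = temperature,
                                shared_baselines = FALSE, se_mode = "global")
      f$dg_h2o
    }, 0)
    se_dg <- stats::sd(per) / sqrt(nrep)
  }

  bl <- matrix(p[-(1:2)], ncol = 4, byrow = TRUE,
               dimnames = list(NULL, c("a_f", "b_f", "a_u", "b_u")))
  max_d <- max(vapply(replicates, function(cv) max(cv$denaturant), 0))
  post_transition <- max_d > dg / m
  if (!post_transition)
    warning("no replicate extends past the estimated midpoint (",
            signif(dg / m, 3), " M); dg_h2o is an extrapolation")

  structure(list(
    dg_h2o = dg, m_value = m, cmid = dg / m,
    se_dg = unname(se_dg), se_m = unname(se_m),
    baselines = bl, shared_baselines = shared_baselines,
    residual_ss = best$deviance, n_points = npts, n_replicates = nrep,
    df_residual = npts - npar,
    temperature = temperature, gas_constant = R_KCAL,
    se_mode = se_mode, post_transition = post_transition,
    protein_id = attr(replicates[[1]], "protein_id"),
    condition = attr(replicates[[1]], "condition"),
    ca_state = attr(replicates[[1]], "ca_state")
  ), class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("Two-state linear-extrapolation global fit (", x$n_replicates,
      " replicate", if (x$n_replicates > 1) "s", ")\n", sep = "")
  cat(sprintf("  dG_H2O = %.3f +/- %.3f kcal/mol  (se: %s)\n",
              x$dg_h2o, x$se_dg, x$se_mode))
  cat(sprintf("  m      = %.3f +/- %.3f kcal/mol/M\n", x$m_value, x$se_m))
  cat(sprintf("  Cmid   = %.3f M;  T = %.2f K;  RSS = %.4g on %d points\n",
              x$cmid, x$temperature, x$residual_ss, x$n_points))
  invisible(x)
}

#' Midpoint of chemical denaturation
#'
#' `Cmid = dG_H2O / m`: the denaturant concentration at which folded and
#' unfolded states are equally populated.
#'
#' @param fit a `two_state_fit`, or a numeric dG_H2O (kcal/mol) combined with `m`.
#' @param m m-value (kcal/mol/M) when `fit` is numeric.
#' @return Cmid in M.
#' @examples
#' cmid(4.82, 1.69)  # 2.85 M
#' @export
cmid <- function(fit, m = NULL) {
  if (inherits(fit, "two_state_fit")) return(fit$dg_h2o / fit$m_value)
  if (is.null(m)) stop("supply an m-value")
  if (any(m <= 0)) stop("m-value must be positive")
  fit / m
}

#' S-nitrosylation-induced change in unfolding free energy
#'
#' `ddG = dG_H2O(modified) - dG_H2O(reference)` with the error propagated in
#' quadrature from the two standard errors.
#'
#' @param reference,modified `two_state_fit` objects or numeric `c(dg, se)`.
#' @param reference_label,modified_label labels for reporting.
#' @return A `stability_delta` with `value` (kcal/mol) and `error`.
#' @examples
#' delta_delta_g(c(6.87, 0.02), c(7.49, 0.06))  # +0.62 +/- 0.063
#' @export
delta_delta_g <- function(reference, modified,
                          reference_label = "reference",
                          modified_label = "modified") {
  r <- extract_est(reference, "dg_h2o")
  m <- extract_est(modified, "dg_h2o")
  stability_delta(r[1], r[2], m[1], m[2], reference_label, modified_label,
                  units = "kcal/mol")
}

#' Define a reagent for absorbance-based concentration estimates
#'
#' @param name reagent label (e.g. "GSNO", "STIM2 15-217 WT").
#' @param extinction_coefficient extinction coefficient, > 0; units determine
#'   the concentration units returned (mM^-1 cm^-1 gives mM, mg/mL^-1 cm^-1
#'   gives mg/mL).
#' @param wavelength nm at which the coefficient applies.
#' @param units free-text units of the coefficient.
#' @return An object of class `reagent_spec`.
#' @export
reagent_spec <- function(name, extinction_coefficient, wavelength,
                         units = "") {
  if (extinction_coefficient <= 0)
    stop("extinction coefficient must be positive")
  structure(list(name = name,
                 extinction_coefficient = extinction_coefficient,
                 wavelength = wavelength, units = units),
            class = "reagent_spec")
}

#' Built-in reagent definitions
#'
#' Extinction coefficients used in the study: GSNO at 335 nm
#' (0.92 mM^-1 cm^-1) and the STIM2 15-217 constructs at 280 nm
#' (mg mL^-1 cm^-1; the Cys-to-Ser substitutions shift the value slightly).
#'
#' @return Named list of [reagent_spec()] objects.
#' @export
stim_reagents <- function() {
  list(
    gsno = reagent_spec("GSNO", 0.92, 335, "mM^-1 cm^-1"),
    stim2_wt = reagent_spec("STIM2 15-217 WT", 1.2944, 280, "mg mL^-1 cm^-1"),
    stim2_single = reagent_spec("STIM2 15-217 single Cys>Ser", 1.2953, 280,
                                "mg mL^-1 cm^-1"),
    stim2_double = reagent_spec("STIM2 15-217 C53S/C60S", 1.2961, 280,
                                "mg mL^-1 cm^-1"),
    stim2_triple = reagent_spec("STIM2 15-217 C15S/C53S/C60S", 1.2970, 280,
                                "mg mL^-1 cm^-1")
  )
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' @param A absorbance, >= 0.
#' @param reagent a [reagent_spec()] or a numeric extinction coefficient.
#' @param path_cm cuvette path length in cm, default 1.
#' @return concentration in the reciprocal units of the coefficient.
#' @export
concentration_from_absorbance <- function(A, reagent, path_cm = 1) {
  if (any(A < 0)) stop("absorbance must be non-negative")
  if (path_cm <= 0) stop("path length must be positive")
  eps <- if (inherits(reagent, "reagent_spec"))
    reagent$extinction_coefficient else reagent
  A / (eps * path_cm)
}
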