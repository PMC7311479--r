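#' Construct a thermal melt curve
#'
#' A far-UV CD thermal melt: ellipticity at 225 nm recorded while the sample
#' is heated at a constant scan rate. The apparent unfolding midpoint (Tm) is
#' read out by Boltzmann sigmoid fitting; because thermal denaturation of the
#' STIM luminal domain is irreversible, Tm values are apparent, not
#' equilibrium, quantities.
#'
#' @param temperature numeric vector of temperatures in degrees C, strictly
#'   increasing, at least 10 points.
#' @param ellipticity numeric vector of ellipticity in mdeg (same length).
#' @param protein_id label for the construct (e.g. "STIM2 15-217 WT").
#' @param condition `"DTT"` (reducing) or `"GSNO"` (S-nitrosylating).
#' @param ca_state `"loaded"` or `"depleted"`.
#' @return An object of class `melt_curve`: a data frame with columns
#'   `temperature` and `ellipticity` plus metadata attributes.
#' @export
melt_curve <- function(temperature, ellipticity, protein_id = "protein",
                       condition = c("DTT", "GSNO"),
                       ca_state = c("loaded", "depleted")) {
  condition <- match.arg(condition)
  ca_state <- match.arg(ca_state)
  if (length(temperature) != length(ellipticity))
    stop("temperature and ellipticity must have equal length")
  if (length(temperature) < 10)
    stop("a melt curve needs at least 10 points")
  if (any(!is.finite(temperature)) || any(!is.finite(ellipticity)))
    stop("non-finite values in melt curve")
  if (any(diff(temperature) <= 0))
    stop("temperature must be strictly increasing")
  out <- data.frame(temperature = temperature, ellipticity = ellipticity)
  attr(out, "protein_id") <- protein_id
  attr(out, "condition") <- condition
  attr(out, "ca_state") <- ca_state
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Read a melt curve from delimited text
#'
#' Expects columns `temperature_C` and `ellipticity_mdeg` (CSV or TSV,
#' autodetected from the first line).
#'
#' @param path file path.
#' @inheritParams melt_curve
#' @return A [melt_curve()].
#' @export
read_melt_curve <- function(path, protein_id = "protein",
                            condition = "DTT", ca_state = "loaded") {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("temperature_C", "ellipticity_mdeg")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  melt_curve(df$temperature_C, df$ellipticity_mdeg,
             protein_id = protein_id, condition = condition,
             ca_state = ca_state)
}

#' Evaluate the Boltzmann sigmoid
#'
#' theta(T) = theta_post + (theta_pre - theta_post) / (1 + exp((T - tm)/slope)).
#' At `T = tm` the value is the midpoint of the two plateaus; as T decreases
#' far below tm the curve approaches `theta_pre` (folded plateau).
#'
#' @param temperature numeric vector, degrees C.
#' @param tm midpoint, degrees C.
#' @param slope transition width parameter, degrees C (> 0).
#' @param theta_pre,theta_post pre- and post-transition plateaus, mdeg.
#' @param pre_slope,post_slope optional linear baseline slopes (mdeg/degC);
#'   zero gives the flat-plateau 4-parameter model.
#' @return numeric vector of model ellipticities (mdeg).
#' @export
boltzmann_signal <- function(temperature, tm, slope, theta_pre, theta_post,
                             pre_slope = 0, post_slope = 0) {
  L <- stats::plogis((temperature - tm) / slope)  # 0 pre, 1 post
  pre <- theta_pre + pre_slope * temperature
  post <- theta_post + post_slope * temperature
  pre + (post - pre) * L
}

#' Fit a Boltzmann sigmoid to a thermal melt
#'
#' Least-squares fit of the 4-parameter Boltzmann model (flat plateaus) or
#' the 6-parameter variant with linear pre/post baselines. Initialisation is
#' multi-start: candidate Tm values at the 25/50/75 percent quantiles of the
#' temperature range (plus any user guess), keeping the fit with the lowest
#' residual sum of squares (ties broken by lowest Tm). The standard error of
#' Tm comes from the parameter covariance of the converged fit.
#'
#' @param curve a [melt_curve()] or a data frame with `temperature` and
#'   `ellipticity` columns.
#' @param init optional named list of starting values
#'   (`tm`, `slope`, `theta_pre`, `theta_post`).
#' @param baseline `"flat"` (default) or `"linear"`.
#' @return An object of class `boltzmann_fit`: list with `tm`, `slope`,
#'   `theta_pre`, `theta_post`, `se_tm`, `residual_ss`, `n_points`,
#'   `tm_in_range` (FALSE flags an extrapolated midpoint), `coefficients`
#'   and `vcov`.
#' @export
fit_boltzmann <- function(curve, init = NULL,
                          baseline = c("flat", "linear")) {
  baseline <- match.arg(baseline)
  temperature <- curve$temperature
  y <- curve$ellipticity
  if (length(temperature) < 10) stop("a melt curve needs at least 10 points")
  if (any(diff(temperature) <= 0)) stop("temperature must be strictly increasing")

  rng <- range(temperature)
  tm_starts <- stats::quantile(rng, c(0.25, 0.5, 0.75), names = FALSE)
  if (!is.null(init$tm)) tm_starts <- c(init$tm, tm_starts)
  slope0 <- if (!is.null(init$slope)) init$slope else diff(rng) / 20
  k <- max(3L, length(y) %/% 10L)
  pre0 <- if (!is.null(init$theta_pre)) init$theta_pre else mean(utils::head(y, k))
  post0 <- if (!is.null(init$theta_post)) init$theta_post else mean(utils::tail(y, k))

  dat <- data.frame(temperature = temperature, y = y)
  form <- if (baseline == "flat") {
    y ~ boltzmann_signal(temperature, tm, slope, theta_pre, theta_post)
  } else {
    y ~ boltzmann_signal(temperature, tm, slope, theta_pre, theta_post,
                         pre_slope, post_slope)
  }

  best <- NULL
  for (tm0 in tm_starts) {
    start <- list(tm = tm0, slope = slope0, theta_pre = pre0,
                  theta_post = post0)
    if (baseline == "linear") start <- c(start, pre_slope = 0, post_slope = 0)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        lower = c(-Inf, 1e-6, rep(-Inf, length(start) - 2L)),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::resid(fit)^2)
    tm_hat <- stats::coef(fit)[["tm"]]
    if (is.null(best) || ss < best$ss - 1e-12 ||
        (abs(ss - best$ss) <= 1e-12 && tm_hat < best$tm)) {
      best <- list(fit = fit, ss = ss, tm = tm_hat)
    }
  }
  if (is.null(best))
    stop("Boltzmann fit failed to converge from any start")

  cf <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  se_tm <- if (!is.null(vc)) sqrt(max(vc["tm", "tm"], 0)) else NA_real_
  tm_in_range <- cf[["tm"]] >= rng[1] && cf[["tm"]] <= rng[2]
  if (!tm_in_range)
    warning("fitted Tm (", signif(cf[["tm"]], 4),
            " degC) lies outside the scanned temperature range")

  structure(list(
    tm = cf[["tm"]],
    slope = cf[["slope"]],
    theta_pre = cf[["theta_pre"]],
    theta_post = cf[["theta_post"]],
    pre_slope = if (baseline == "linear") cf[["pre_slope"]] else 0,
    post_slope = if (baseline == "linear") cf[["post_slope"]] else 0,
    se_tm = se_tm,
    residual_ss = best$ss,
    n_points = length(y),
    tm_in_range = tm_in_range,
    baseline = baseline,
    coefficients = cf,
    vcov = vc,
    protein_id = attr(curve, "protein_id"),
    condition = attr(curve, "condition"),
    ca_state = attr(curve, "ca_state")
  ), class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("Boltzmann thermal-melt fit (", x$baseline, " plateaus)\n", sep = "")
  cat(sprintf("  apparent Tm = %.2f +/- %.2f degC  (slope %.2f degC, n = %d)\n",
              x$tm, x$se_tm, x$slope, x$n_points))
  cat(sprintf("  plateaus: pre %.2f, post %.2f mdeg; RSS = %.4g\n",
              x$theta_pre, x$theta_post, x$residual_ss))
  invisible(x)
}

#' Predict ellipticity from a Boltzmann fit
#'
#' @param object a `boltzmann_fit`.
#' @param temperatures numeric vector of temperatures (degC); defaults not
#'   stored, must be supplied.
#' @param ... unused.
#' @return numeric vector of model ellipticities (mdeg).
#' @export
predict.boltzmann_fit <- function(object, temperatures, ...) {
  boltzmann_signal(temperatures, object$tm, object$slope,
                   object$theta_pre, object$theta_post,
                   object$pre_slope, object$post_slope)
}

#' Difference of two fitted quantities with quadrature error
#'
#' Internal constructor shared by [delta_tm()] and [delta_delta_g()].
#' @noRd
stability_delta <- function(value_ref, se_ref, value_mod, se_mod,
                            reference_label, modified_label, units) {
  if (se_ref < 0 || se_mod < 0) stop("standard errors must be non-negative")
  structure(list(
    value = value_mod - value_ref,
    error = propagate_quadrature(se_ref, se_mod),
    reference = value_ref, reference_se = se_ref,
    modified = value_mod, modified_se = se_mod,
    reference_label = reference_label, modified_label = modified_label,
    units = units
  ), class = "stability_delta")
}

#' @export
print.stability_delta <- function(x, ...) {
  cat(sprintf("%s - %s: %+.4g +/- %.4g %s\n", x$modified_label,
              x$reference_label, x$value, x$error, x$units))
  invisible(x)
}

extract_est <- function(x, field) {
  if (inherits(x, "boltzmann_fit")) return(c(x$tm, x$se_tm))
  if (inherits(x, "two_state_fit")) return(c(x$dg_h2o, x$se_dg))
  if (is.list(x) && !is.null(x[[field]])) {
    se <- if (!is.null(x$se)) x$se else x[[paste0("se_", field)]]
    return(c(x[[field]], se))
  }
  if (is.numeric(x) && length(x) == 2) return(unname(x))
  stop("cannot extract (estimate, se) from input")
}

#' GSNO-vs-DTT shift in apparent Tm
#'
#' Computes `Tm(modified) - Tm(reference)` with the uncertainty propagated in
#' quadrature, `sqrt(se_ref^2 + se_mod^2)`: the convention used to report
#' S-nitrosylation-induced thermal stabilisation.
#'
#' @param reference,modified `boltzmann_fit` objects, or numeric `c(tm, se)`.
#' @param reference_label,modified_label labels for reporting.
#' @return A `stability_delta` with fields `value` (degC) and `error`.
#' @examples
#' delta_tm(c(63.2, 0.1), c(67.3, 0.7))  # +4.1 +/- 0.71 degC
#' @export
delta_tm <- function(reference, modified,
                     reference_label = "reference", modified_label = "modified") {
  r <- extract_est(reference, "tm")
  m <- extract_est(modified, "tm")
  stability_delta(r[1], r[2], m[1], m[2], reference_label, modified_label,
                  units = "degC")
}
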