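# Run code under a fixed RNG seed, restoring the caller's RNG state, so the
# generators are pure functions of (truth, seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is mandatory for stochastic generation")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for a synthetic thermal melt
#'
#' Defaults reproduce the wild-type Ca2+-loaded reducing condition
#' (apparent Tm 63.2 degC) on a 20-90 degC scan with an 8 mdeg transition
#' amplitude and 0.1 mdeg additive noise.
#'
#' @param tm midpoint (degC). @param slope transition width (degC).
#' @param theta_pre,theta_post plateaus (mdeg).
#' @param noise_sd additive Gaussian noise (mdeg).
#' @param t_min,t_max,t_step temperature grid (degC).
#' @return list of class `melt_truth`.
#' @export
melt_truth <- function(tm = 63.2, slope = 2, theta_pre = -10,
                       theta_post = -2, noise_sd = 0.1,
                       t_min = 20, t_max = 90, t_step = 1) {
  stopifnot(noise_sd >= 0, slope > 0, t_max > t_min)
  structure(list(tm = tm, slope = slope, theta_pre = theta_pre,
                 theta_post = theta_post, noise_sd = noise_sd,
                 t_min = t_min, t_max = t_max, t_step = t_step),
            class = "melt_truth")
}

#' Generate a synthetic thermal melt curve
#'
#' Boltzmann signal on the truth's temperature grid plus additive Gaussian
#' noise; deterministic given (truth, seed).
#'
#' @param truth a [melt_truth()].
#' @param seed integer seed.
#' @inheritParams melt_curve
#' @return A [melt_curve()].
#' @export
gen_melt_curve <- function(truth = melt_truth(), seed,
                           protein_id = "synthetic", condition = "DTT",
                           ca_state = "loaded") {
  temperature <- seq(truth$t_min, truth$t_max, by = truth$t_step)
  y <- boltzmann_signal(temperature, truth$tm, truth$slope,
                        truth$theta_pre, truth$theta_post)
  if (truth$noise_sd > 0)
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, truth$noise_sd))
  melt_curve(temperature, y, protein_id = protein_id,
             condition = condition, ca_state = ca_state)
}

#' Ground truth for synthetic urea denaturation replicates
#'
#' Defaults reproduce the wild-type Ca2+-depleted reducing condition
#' (dG_H2O 4.82 kcal/mol, m 1.69 kcal/mol/M): three replicates of 25 points
#' on 0-6 M urea with slightly different linear baselines and 1 percent
#' multiplicative noise — the fractional-error behaviour typical of
#' fluorescence intensity measurements.
#'
#' @param dg,m shared thermodynamic parameters.
#' @param baselines matrix with one row per replicate, columns
#'   `a_f, b_f, a_u, b_u`.
#' @param noise_fraction multiplicative Gaussian noise, as a fraction of the
#'   signal value.
#' @param n_points points per replicate. @param urea_max M.
#' @param temperature K.
#' @return list of class `denat_truth`.
#' @export
denat_truth <- function(dg = 4.82, m = 1.69,
                        baselines = rbind(c(1.00, -0.010, 0.35, 0.012),
                                          c(0.97, -0.012, 0.33, 0.010),
                                          c(1.03, -0.008, 0.37, 0.014)),
                        noise_fraction = 0.01, n_points = 25,
                        urea_max = 6, temperature = 293.15) {
  stopifnot(noise_fraction >= 0, m > 0, n_points >= 8)
  structure(list(dg = dg, m = m, baselines = baselines,
                 noise_fraction = noise_fraction, n_points = n_points,
                 urea_max = urea_max, temperature = temperature),
            class = "denat_truth")
}

#' Generate synthetic denaturation replicates
#'
#' Two-state signal with shared (dg, m) and per-replicate baselines, plus
#' multiplicative Gaussian noise.
#'
#' @param truth a [denat_truth()].
#' @param seed integer seed.
#' @inheritParams denaturation_curve
#' @return list of [denaturation_curve()] objects (one per baseline row).
#' @export
gen_denaturation_replicates <- function(truth = denat_truth(), seed,
                                        protein_id = "synthetic",
                                        condition = "DTT",
                                        ca_state = "depleted") {
  D <- seq(0, truth$urea_max, length.out = truth$n_points)
  nrep <- nrow(truth$baselines)
  with_seed(seed, {
    lapply(seq_len(nrep), function(i) {
      y <- two_state_signal(D, truth$dg, truth$m, truth$baselines[i, ],
                            truth$temperature)
      if (truth$noise_fraction > 0)
        y <- y * (1 + stats::rnorm(length(y), 0, truth$noise_fraction))
      denaturation_curve(D, y, replicate_id = paste0("rep", i),
                         protein_id = protein_id, condition = condition,
                         ca_state = ca_state)
    })
  })
}

#' Ground truth for a synthetic HSQC peak-list pair
#'
#' Defaults emulate the S-nitrosylation CSP pattern of the STIM2 EF-SAM
#' region (native numbering, residues 62-205): two perturbed spans — one on
#' the canonical EF-hand entering helix and one on the non-canonical
#' EF-hand exiting helix / SAM linker — over a small random referencing
#' jitter elsewhere.
#'
#' @param residues integer residue numbers present in both spectra.
#' @param spans list of perturbed spans, each `list(from, to, dh, dn)` (ppm).
#' @param jitter_h,jitter_n Gaussian jitter (ppm) applied to the modified
#'   spectrum everywhere.
#' @param h_range,n_range uniform ranges for the reference shifts (ppm).
#' @param n_add unassigned peaks added to the modified list.
#' @param n_remove assigned peaks removed from the modified list.
#' @return list of class `csp_truth`.
#' @export
csp_truth <- function(residues = 62:205,
                      spans = list(list(from = 68, to = 80, dh = 0.06,
                                        dn = 0.60),
                                   list(from = 112, to = 130, dh = 0.05,
                                        dn = 0.50)),
                      jitter_h = 0.003, jitter_n = 0.03,
                      h_range = c(6.5, 10.5), n_range = c(105, 130),
                      n_add = 0, n_remove = 0) {
  for (sp in spans)
    if (sp$from < min(residues) || sp$to > max(residues))
      stop("perturbed span ", sp$from, "-", sp$to,
           " lies outside the residue range")
  structure(list(residues = residues, spans = spans, jitter_h = jitter_h,
                 jitter_n = jitter_n, h_range = h_range, n_range = n_range,
                 n_add = n_add, n_remove = n_remove),
            class = "csp_truth")
}

#' Generate a reference/modified peak-list pair
#'
#' @param truth a [csp_truth()].
#' @param seed integer seed.
#' @return list with `reference` and `modified` [peaklist()]s and `truth`.
#' @export
gen_peaklist_pair <- function(truth = csp_truth(), seed) {
  with_seed(seed, {
    n <- length(truth$residues)
    h <- stats::runif(n, truth$h_range[1], truth$h_range[2])
    np <- stats::runif(n, truth$n_range[1], truth$n_range[2])
    ref <- peaklist(truth$residues, h, np, spectrum_label = "reference")
    h2 <- h; n2 <- np
    for (sp in truth$spans) {
      sel <- truth$residues >= sp$from & truth$residues <= sp$to
      h2[sel] <- h2[sel] + sp$dh
      n2[sel] <- n2[sel] + sp$dn
    }
    if (truth$jitter_h > 0)
      h2 <- h2 + stats::rnorm(n, 0, truth$jitter_h)
    if (truth$jitter_n > 0)
      n2 <- n2 + stats::rnorm(n, 0, truth$jitter_n)
    res2 <- truth$residues
    if (truth$n_remove > 0) {
      drop <- sample(seq_len(n), truth$n_remove)
      res2 <- res2[-drop]; h2 <- h2[-drop]; n2 <- n2[-drop]
    }
    if (truth$n_add > 0) {
      res2 <- c(res2, rep(NA_integer_, truth$n_add))
      h2 <- c(h2, stats::runif(truth$n_add, truth$h_range[1],
                               truth$h_range[2]))
      n2 <- c(n2, stats::runif(truth$n_add, truth$n_range[1],
                               truth$n_range[2]))
    }
    mod <- peaklist(res2, h2, n2, spectrum_label = "modified")
    list(reference = ref, modified = mod, truth = truth)
  })
}

#' Ground truth for a synthetic Fura-2 trace
#'
#' Defaults emulate the suspension-protocol control experiment: resting
#' cytosolic Ca2+ of 118 nM, EGTA step drop, thapsigargin store-release
#' transient, and a SOCE plateau reaching F/F0 = 2 well before the
#' 450-550 s readout window of a 600-s record, with events at 100 s (EGTA),
#' 180 s (TG) and 400 s (Ca2+ addback).
#'
#' @param basal_nM resting cytosolic Ca2+ (nM).
#' @param egta_drop ratio-unit step drop at EGTA addition.
#' @param tg_amp,tg_tau amplitude (ratio units) and decay constant (s) of
#'   the TG store-release transient.
#' @param soce_ff0 plateau F/F0 reached after Ca2+ addback.
#' @param rise_tau SOCE rise time constant (s).
#' @param events list of event times (s). @param duration record length (s).
#' @param noise_sd additive Gaussian noise on each fluorescence channel (AU).
#' @param f380_sat 380 nm fluorescence of Ca2+-saturated dye (AU).
#' @param calib ground-truth [calibration_params()].
#' @param n_calib samples per calibration segment.
#' @return list of class `fura_truth`.
#' @export
fura_truth <- function(basal_nM = 118, egta_drop = 0.10, tg_amp = 0.30,
                       tg_tau = 40, soce_ff0 = 2.0, rise_tau = 8,
                       events = list(egta_add = 100, tg_add = 180,
                                     ca_addback = 400),
                       duration = 600, noise_sd = 0.3, f380_sat = 100,
                       calib = calibration_params(kd = 225, r_min = 0.3,
                                                  r_max = 6.0, beta = 2.0),
                       n_calib = 30) {
  stopifnot(noise_sd >= 0, basal_nM >= 0,
            events$egta_add < events$tg_add,
            events$tg_add < events$ca_addback,
            events$ca_addback < duration)
  structure(list(basal_nM = basal_nM, egta_drop = egta_drop,
                 tg_amp = tg_amp, tg_tau = tg_tau, soce_ff0 = soce_ff0,
                 rise_tau = rise_tau, events = events, duration = duration,
                 noise_sd = noise_sd, f380_sat = f380_sat, calib = calib,
                 n_calib = n_calib),
            class = "fura_truth")
}

#' Generate a synthetic Fura-2 trace with calibration segments
#'
#' The noiseless ratio is built piecewise: the basal level is obtained by
#' inverting the Grynkiewicz relation at the truth's resting Ca2+; EGTA
#' causes a step drop; TG adds a decaying exponential store-release
#' transient; the Ca2+ addback relaxes exponentially to a plateau scaled so
#' that F/F0 equals the truth's SOCE level. The ratio is decomposed into
#' f340/f380 channels (f380 held at the dye's mixed-state level) and
#' additive Gaussian noise is applied per channel. Triton (saturating) and
#' EGTA (Ca2+-free) calibration segments consistent with the truth's
#' calibration constants, including the beta decomposition of the 380 nm
#' channel, are appended.
#'
#' @param truth a [fura_truth()].
#' @param seed integer seed.
#' @param protocol `"suspension"` or `"plate"`.
#' @return list with `trace` (a [fura_trace()]), `calib_segments` (list of
#'   `triton_ratio`, `egta_ratio`, `f380_triton`, `f380_egta`) and `truth`.
#' @export
gen_fura_trace <- function(truth = fura_truth(), seed,
                           protocol = "suspension") {
  ev <- truth$events
  time <- seq(0, truth$duration, by = 1)
  r_basal <- ratio_for_concentration(truth$basal_nM, truth$calib)
  f0_true <- r_basal - truth$egta_drop
  R <- rep(r_basal, length(time))
  post_egta <- time >= ev$egta_add
  R[post_egta] <- f0_true
  post_tg <- time >= ev$tg_add
  R[post_tg] <- f0_true +
    truth$tg_amp * exp(-(time[post_tg] - ev$tg_add) / truth$tg_tau)
  post_ab <- time >= ev$ca_addback
  r_at_ab <- f0_true +
    truth$tg_amp * exp(-(ev$ca_addback - ev$tg_add) / truth$tg_tau)
  plateau <- truth$soce_ff0 * f0_true
  R[post_ab] <- plateau +
    (r_at_ab - plateau) * exp(-(time[post_ab] - ev$ca_addback) /
                                truth$rise_tau)
  f380_level <- truth$f380_sat * (1 + truth$calib$beta) / 2
  f380 <- rep(f380_level, length(time))
  f340 <- R * f380
  with_seed(seed, {
    if (truth$noise_sd > 0) {
      f340 <- f340 + stats::rnorm(length(time), 0, truth$noise_sd)
      f380 <- f380 + stats::rnorm(length(time), 0, truth$noise_sd)
    }
    cal <- truth$calib
    nseg <- truth$n_calib
    seg_noise <- truth$noise_sd / truth$f380_sat
    segs <- list(
      triton_ratio = cal$r_max + stats::rnorm(nseg, 0, seg_noise),
      egta_ratio = cal$r_min + stats::rnorm(nseg, 0, seg_noise),
      f380_triton = truth$f380_sat + stats::rnorm(nseg, 0, truth$noise_sd),
      f380_egta = cal$beta * truth$f380_sat +
        stats::rnorm(nseg, 0, truth$noise_sd))
    list(trace = fura_trace(time, f340, f380, events = ev,
                            protocol = protocol),
         calib_segments = segs, truth = truth)
  })
}
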