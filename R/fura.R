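#' Construct a Fura-2 ratiometric trace
#'
#' Fluorescence emission at 510 nm recorded at alternating 340/380 nm
#' excitation (nominal 1-s sampling) with an event schedule: EGTA addition
#' (chelates extracellular Ca2+), thapsigargin (TG; passive ER store
#' depletion) and CaCl2 addback (reveals store-operated Ca2+ entry, SOCE).
#' Two acquisition protocols are supported: `"suspension"` (cuvette,
#' HEK293T; absolute calibration available) and `"plate"` (96-well reader,
#' STIM1/2 knockout cells; ratio-difference readouts only).
#'
#' @param time seconds, strictly increasing.
#' @param f340,f380 fluorescence (AU); `f380` must be positive everywhere.
#' @param events named list with `egta_add`, `tg_add`, `ca_addback`
#'   (seconds, in that order, within the record).
#' @param protocol `"suspension"` or `"plate"`.
#' @return An object of class `fura_trace` (a data frame with metadata
#'   attributes).
#' @export
fura_trace <- function(time, f340, f380,
                       events = list(egta_add = 100, tg_add = 180,
                                     ca_addback = 400),
                       protocol = c("suspension", "plate")) {
  protocol <- match.arg(protocol)
  n <- length(time)
  if (length(f340) != n || length(f380) != n)
    stop("time, f340 and f380 must have equal length")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  bad <- which(f380 <= 0)
  if (length(bad))
    stop("f380 must be positive everywhere; first violation at index ",
         bad[1])
  ev <- events
  need <- c("egta_add", "tg_add", "ca_addback")
  if (!all(need %in% names(ev)))
    stop("events must name egta_add, tg_add and ca_addback")
  ev <- ev[need]
  if (!(ev$egta_add < ev$tg_add && ev$tg_add < ev$ca_addback))
    stop("events must be ordered egta_add < tg_add < ca_addback")
  if (ev$egta_add < min(time) || ev$ca_addback > max(time))
    stop("event times must lie within the record")
  out <- data.frame(time = time, f340 = f340, f380 = f380)
  attr(out, "events") <- ev
  attr(out, "protocol") <- protocol
  class(out) <- c("fura_trace", "data.frame")
  out
}

#' Read a Fura-2 trace from CSV
#'
#' Expects columns `time_s`, `f340`, `f380`.
#'
#' @param path file path.
#' @inheritParams fura_trace
#' @return A [fura_trace()].
#' @export
read_fura_trace <- function(path,
                            events = list(egta_add = 100, tg_add = 180,
                                          ca_addback = 400),
                            protocol = "suspension") {
  df <- utils::read.csv(path)
  need <- c("time_s", "f340", "f380")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  fura_trace(df$time_s, df$f340, df$f380, events = events,
             protocol = protocol)
}

#' Ratiometric signal R(t) = F340/F380
#'
#' @param trace a [fura_trace()].
#' @return numeric vector, same length as the trace.
#' @export
compute_ratio <- function(trace) {
  bad <- which(trace$f380 <= 0)
  if (length(bad))
    stop("f380 must be positive everywhere; first violation at index ",
         bad[1])
  trace$f340 / trace$f380
}

window_mean <- function(time, x, from, to, include_right = TRUE) {
  sel <- time >= from & (if (include_right) time <= to else time < to)
  if (!any(sel)) stop("empty time window [", from, ", ", to, "] s")
  mean(x[sel])
}

#' Baseline-normalised ratio trace
#'
#' F0 is the mean ratio over a baseline window ending at TG addition:
#' 50 s for the suspension protocol, 80 s (EGTA present) for the plate
#' protocol. The baseline is defined by time window, not point count, so it
#' is robust to the actual sampling interval. The window is half-open: the
#' sample acquired at the instant of TG addition belongs to the response,
#' not the baseline. Suspension traces are returned
#' as F/F0; plate traces are returned un-normalised with `f0` retained for
#' ratio differencing.
#'
#' @param trace a [fura_trace()].
#' @param baseline_s baseline duration (s); default 50 (suspension) or
#'   80 (plate).
#' @return list with `f_over_f0` (suspension) or `ratio` (plate), plus `f0`
#'   and the `window` used.
#' @export
normalize_f_over_f0 <- function(trace, baseline_s = NULL) {
  protocol <- attr(trace, "protocol")
  ev <- attr(trace, "events")
  if (is.null(baseline_s))
    baseline_s <- if (protocol == "plate") 80 else 50
  from <- ev$tg_add - baseline_s
  if (from < min(trace$time))
    stop("baseline window extends before the start of the record")
  R <- compute_ratio(trace)
  f0 <- window_mean(trace$time, R, from, ev$tg_add, include_right = FALSE)
  if (protocol == "suspension")
    list(f_over_f0 = R / f0, f0 = f0, window = c(from, ev$tg_add))
  else
    list(ratio = R, f0 = f0, window = c(from, ev$tg_add))
}

#' Grynkiewicz calibration constants
#'
#' @param kd Fura-2 Ca2+ dissociation constant (nM), default 225.
#' @param r_min ratio at zero Ca2+ (10 mM EGTA).
#' @param r_max ratio at saturating Ca2+ (Triton-permeabilised).
#' @param beta Sf380/Sb380: ratio of 380 nm fluorescence of free vs bound
#'   dye; defaults to 1 when no 380 nm calibration segments are available.
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(kd = 225, r_min, r_max, beta = 1) {
  if (kd <= 0) stop("kd must be positive")
  if (beta <= 0) stop("beta must be positive")
  if (!(r_max > r_min && r_min > 0))
    stop("require r_max > r_min > 0")
  structure(list(kd = kd, r_min = r_min, r_max = r_max, beta = beta),
            class = "calibration_params")
}

#' Convert a Fura-2 ratio to free Ca2+ concentration
#'
#' Grynkiewicz relation: `[Ca2+] = kd * beta * (R - r_min) / (r_max - R)`
#' (nM). Strictly increasing in R on (r_min, r_max) and divergent as R
#' approaches r_max.
#'
#' @param R ratio value(s).
#' @param calib a [calibration_params()].
#' @return Ca2+ concentration(s) in nM. Ratios below `r_min` are clamped to
#'   0 nM with a warning; ratios at or above `r_max` are an error
#'   (dye saturation).
#' @export
calibrate_concentration <- function(R, calib) {
  if (any(R >= calib$r_max))
    stop("ratio at or above r_max: Fura-2 saturated, concentration undefined")
  if (any(R < calib$r_min)) {
    warning("ratio(s) below r_min clamped to 0 nM")
    R <- pmax(R, calib$r_min)
  }
  calib$kd * calib$beta * (R - calib$r_min) / (calib$r_max - R)
}

# inverse of the Grynkiewicz relation (used by the trace generator)
ratio_for_concentration <- function(ca_nM, calib) {
  kb <- calib$kd * calib$beta
  (ca_nM * calib$r_max + kb * calib$r_min) / (ca_nM + kb)
}

#' Resting cytosolic Ca2+ concentration (suspension protocol)
#'
#' Mean ratio over a half-open window preceding EGTA addition (default
#' 30 s; the sample at the addition instant is excluded), calibrated
#' through the Grynkiewicz relation.
#'
#' @param trace a [fura_trace()].
#' @param calib a [calibration_params()].
#' @param basal_s basal window duration (s) before `egta_add`, default 30.
#' @return basal Ca2+ in nM.
#' @export
basal_concentration <- function(trace, calib, basal_s = 30) {
  ev <- attr(trace, "events")
  from <- ev$egta_add - basal_s
  if (from < min(trace$time))
    stop("basal window extends before the start of the record")
  R <- compute_ratio(trace)
  calibrate_concentration(window_mean(trace$time, R, from, ev$egta_add,
                                      include_right = FALSE),
                          calib)
}

#' Relative basal Ca2+ readout (plate protocol)
#'
#' `F_basal - F0`: the mean ratio over 30 s before EGTA addition minus the
#' mean ratio over the 80-s post-EGTA / pre-TG baseline. Used when absolute
#' calibration is not available (plate-reader acquisitions).
#'
#' @param trace a [fura_trace()] with `protocol = "plate"`.
#' @param basal_s pre-EGTA window (s), default 30.
#' @param baseline_s post-EGTA baseline window (s), default 80.
#' @return ratio difference (dimensionless).
#' @export
relative_basal <- function(trace, basal_s = 30, baseline_s = 80) {
  ev <- attr(trace, "events")
  from_basal <- ev$egta_add - basal_s
  if (from_basal < min(trace$time))
    stop("basal window extends before the start of the record")
  if (ev$tg_add - baseline_s < ev$egta_add)
    stop("baseline window extends before EGTA addition")
  R <- compute_ratio(trace)
  f_basal <- window_mean(trace$time, R, from_basal, ev$egta_add,
                         include_right = FALSE)
  f0 <- window_mean(trace$time, R, ev$tg_add - baseline_s, ev$tg_add,
                    include_right = FALSE)
  f_basal - f0
}

#' Peak store-operated Ca2+ entry
#'
#' Suspension protocol: mean F/F0 over the SOCE window (default 450-550 s
#' after the Ca2+ addback). Plate protocol: `F_SOCE - F0`, the mean ratio
#' over the window minus the pre-TG baseline ratio.
#'
#' @param trace a [fura_trace()].
#' @param window numeric `c(from, to)` in s, default `c(450, 550)`.
#' @return mean F/F0 (suspension) or ratio difference (plate).
#' @export
peak_soce <- function(trace, window = c(450, 550)) {
  ev <- attr(trace, "events")
  if (window[1] < ev$ca_addback)
    stop("SOCE window must start after the Ca2+ addback")
  if (window[2] > max(trace$time))
    stop("SOCE window extends past the end of the record")
  norm <- normalize_f_over_f0(trace)
  if (attr(trace, "protocol") == "suspension")
    window_mean(trace$time, norm$f_over_f0, window[1], window[2])
  else
    window_mean(trace$time, norm$ratio, window[1], window[2]) - norm$f0
}

#' Derive calibration constants from in-situ calibration segments
#'
#' r_max is the mean ratio after Triton X-100 permeabilisation (saturating
#' Ca2+), r_min the mean ratio after 10 mM EGTA (Ca2+-free), and beta the
#' mean 380 nm fluorescence of the Ca2+-free segment over that of the
#' saturated segment. The dissociation constant stays at its literature
#' value (225 nM) — it is a property of the dye, not of the instrument.
#'
#' @param triton_segment ratio values from the Ca2+-saturated segment.
#' @param egta_segment ratio values from the Ca2+-free segment.
#' @param f380_triton,f380_egta optional 380 nm fluorescence from the two
#'   segments; when absent beta defaults to 1 with a warning.
#' @param kd nM, default 225.
#' @return A [calibration_params()].
#' @export
derive_calibration <- function(triton_segment, egta_segment,
                               f380_triton = NULL, f380_egta = NULL,
                               kd = 225) {
  if (!length(triton_segment) || !length(egta_segment))
    stop("both calibration segments must be non-empty")
  r_max <- mean(triton_segment)
  r_min <- mean(egta_segment)
  if (r_max <= r_min)
    stop("calibration error: saturated ratio (", signif(r_max, 4),
         ") not above Ca2+-free ratio (", signif(r_min, 4),
         "); segments swapped?")
  if (is.null(f380_triton) || is.null(f380_egta)) {
    warning("no 380 nm calibration segments supplied; beta set to 1")
    beta <- 1
  } else {
    beta <- mean(f380_egta) / mean(f380_triton)
  }
  calibration_params(kd = kd, r_min = r_min, r_max = r_max, beta = beta)
}
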