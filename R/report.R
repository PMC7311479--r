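#' Quadrature propagation of two standard errors
#'
#' `sqrt(e1^2 + e2^2)`: the standard error of a difference of two
#' independent estimates.
#'
#' @param e1,e2 non-negative standard errors.
#' @return propagated error.
#' @examples
#' propagate_quadrature(0.1, 0.7)  # 0.7071
#' @export
propagate_quadrature <- function(e1, e2) {
  if (any(e1 < 0) || any(e2 < 0))
    stop("standard errors must be non-negative")
  sqrt(e1^2 + e2^2)
}

#' Unpaired two-sample t-test
#'
#' Classic equal-variance Student's t-test by default
#' (df = nA + nB - 2, two-sided); Welch's unequal-variance form via
#' `welch = TRUE`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param welch use the Welch correction (default FALSE).
#' @return list with `t`, `df`, `p`, and the group means.
#' @export
unpaired_t_test <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

read_extdata_tsv <- function(name) {
  path <- system.file("extdata", name, package = "stimstab")
  if (path == "") path <- file.path("inst", "extdata", name)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Reported thermal-stability parameters for STIM luminal domains
#'
#' Apparent Tm values (degC, mean +/- SEM, n = 3) of the STIM2 15-217 and
#' STIM1 23-213 luminal domains under reducing (DTT) and S-nitrosylating
#' (GSNO) conditions, Ca2+ loaded and depleted, as reported by the source
#' study; inputs for the derived-quantity reproduction.
#'
#' @return data frame with one row per construct/Ca2+ state, columns
#'   `tm_dtt`, `se_dtt`, `tm_gsno`, `se_gsno` and the printed
#'   `dtm_printed`, `dtm_se_printed`.
#' @export
stim_thermal_params <- function() read_extdata_tsv("stim_thermal_params.tsv")

#' Reported thermodynamic-stability parameters for STIM luminal domains
#'
#' Two-state global-fit parameters (dG_H2O in kcal/mol, Cmid in M, m-value
#' in kcal/mol/M) for the same constructs and conditions, with the printed
#' ddG column.
#'
#' @return data frame, one row per construct/Ca2+ state.
#' @export
stim_chemical_params <- function() read_extdata_tsv("stim_chemical_params.tsv")

#' Recompute GSNO-induced Tm shifts from reported fit parameters
#'
#' For every construct, applies [delta_tm()] to the reported (Tm, SEM)
#' pairs and rounds to the reporting precision (one decimal for degC).
#'
#' @param params data frame as returned by [stim_thermal_params()].
#' @param digits reporting precision, default 1.
#' @return the input with computed `dtm`, `dtm_se` (full precision),
#'   `dtm_rounded`, `dtm_se_rounded` and agreement flags against the
#'   printed columns.
#' @export
reproduce_thermal_deltas <- function(params = stim_thermal_params(),
                                     digits = 1) {
  d <- lapply(seq_len(nrow(params)), function(i) {
    delta_tm(c(params$tm_dtt[i], params$se_dtt[i]),
             c(params$tm_gsno[i], params$se_gsno[i]))
  })
  params$dtm <- vapply(d, `[[`, 0, "value")
  params$dtm_se <- vapply(d, `[[`, 0, "error")
  params$dtm_rounded <- round(params$dtm, digits)
  params$dtm_se_rounded <- round(params$dtm_se, digits)
  params$dtm_matches <- params$dtm_rounded == params$dtm_printed
  params$dtm_se_matches <- params$dtm_se_rounded == params$dtm_se_printed
  params
}

#' Recompute ddG and Cmid from reported fit parameters
#'
#' Applies [delta_delta_g()] to the reported (dG, SEM) pairs and recomputes
#' `Cmid = dG/m` for both conditions, rounding to the reporting precision
#' (two decimals). Agreement flags against the printed cells are returned;
#' a handful of printed Cmid (and one ddG) cells are internally
#' inconsistent with their own dG and m at the printed precision, and the
#' flags expose exactly which.
#'
#' @param params data frame as returned by [stim_chemical_params()].
#' @param digits reporting precision, default 2.
#' @return the input with computed `ddg`, `ddg_se`, rounded versions,
#'   `cmid_dtt_calc`, `cmid_gsno_calc` and agreement flags.
#' @export
reproduce_chemical_deltas <- function(params = stim_chemical_params(),
                                      digits = 2) {
  d <- lapply(seq_len(nrow(params)), function(i) {
    delta_delta_g(c(params$dg_dtt[i], params$se_dg_dtt[i]),
                  c(params$dg_gsno[i], params$se_dg_gsno[i]))
  })
  params$ddg <- vapply(d, `[[`, 0, "value")
  params$ddg_se <- vapply(d, `[[`, 0, "error")
  params$ddg_rounded <- round(params$ddg, digits)
  params$ddg_se_rounded <- round(params$ddg_se, digits)
  params$ddg_matches <- params$ddg_rounded == params$ddg_printed
  params$ddg_se_matches <- params$ddg_se_rounded == params$ddg_se_printed
  params$cmid_dtt_calc <- round(cmid(params$dg_dtt, params$m_dtt), digits)
  params$cmid_gsno_calc <- round(cmid(params$dg_gsno, params$m_gsno), digits)
  params$cmid_dtt_matches <- params$cmid_dtt_calc == params$cmid_dtt
  params$cmid_gsno_matches <- params$cmid_gsno_calc == params$cmid_gsno
  params
}

#' Cross-paralog stability differences
#'
#' STIM2-minus-STIM1 wild-type dG_H2O differences per Ca2+ state and redox
#' condition, at one-decimal rounding: the comparison that shows the
#' paralogs' stability rank order switching under S-nitrosylation
#' (STIM1 more stable when Ca2+ loaded, STIM2 more stable when depleted).
#'
#' @param params data frame as returned by [stim_chemical_params()].
#' @return data frame with `ca_state`, `condition`, `stim2_dg`, `stim1_dg`,
#'   `difference` (full precision) and `difference_rounded`.
#' @export
cross_paralog_differences <- function(params = stim_chemical_params()) {
  wt <- params[params$construct == "WT", ]
  grid <- expand.grid(ca_state = c("loaded", "depleted"),
                      condition = c("DTT", "GSNO"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cs <- grid$ca_state[i]; cond <- grid$condition[i]
    col <- if (cond == "DTT") "dg_dtt" else "dg_gsno"
    s2 <- wt[wt$paralog == "STIM2" & wt$ca_state == cs, col]
    s1 <- wt[wt$paralog == "STIM1" & wt$ca_state == cs, col]
    data.frame(ca_state = cs, condition = cond, stim2_dg = s2,
               stim1_dg = s1, difference = s2 - s1)
  }))
  out$difference_rounded <- round(out$difference, 1)
  out
}

#' Fit reports for batches of melt and denaturation data
#'
#' Runs [fit_boltzmann()] on each melt curve and [fit_two_state_global()]
#' on each replicate set, then forms GSNO-vs-DTT differences with
#' quadrature errors for the requested pairs. Fit failures are reported per
#' row and do not abort the run; output is deterministic given the inputs.
#'
#' @param melt_groups named list of [melt_curve()] objects (may be NULL).
#' @param denat_groups named list, each element a list of
#'   [denaturation_curve()] replicates (may be NULL).
#' @param pairs data frame with columns `reference` and `modified` naming
#'   entries of the groups to difference (optional).
#' @param out_dir if non-NULL, CSV reports (`thermal_fits.csv`,
#'   `chemical_fits.csv`, `comparisons.csv`) are written there at full
#'   precision.
#' @param ... passed to the fitters.
#' @return list with data frames `thermal`, `chemical`, `comparisons` and
#'   the underlying fit objects.
#' @export
run_stability_report <- function(melt_groups = NULL, denat_groups = NULL,
                                 pairs = NULL, out_dir = NULL, ...) {
  if (is.null(melt_groups) && is.null(denat_groups))
    stop("no input data: supply melt_groups and/or denat_groups")
  if (!is.null(melt_groups) && length(melt_groups) == 0)
    stop("empty melt manifest")
  if (!is.null(denat_groups) && length(denat_groups) == 0)
    stop("empty denaturation manifest")

  safe_fit <- function(f, x, ...) tryCatch(f(x, ...), error = identity)
  thermal <- chemical <- NULL
  melt_fits <- denat_fits <- list()

  if (!is.null(melt_groups)) {
    melt_fits <- lapply(melt_groups, function(cv)
      safe_fit(fit_boltzmann, cv, ...))
    thermal <- do.call(rbind, lapply(names(melt_fits), function(nm) {
      f <- melt_fits[[nm]]
      if (inherits(f, "error"))
        return(data.frame(group = nm, apparent_tm = NA, se_tm = NA,
                          slope = NA, theta_pre = NA, theta_post = NA,
                          rss = NA, n = NA, status = conditionMessage(f)))
      data.frame(group = nm, apparent_tm = f$tm, se_tm = f$se_tm,
                 slope = f$slope, theta_pre = f$theta_pre,
                 theta_post = f$theta_post, rss = f$residual_ss,
                 n = f$n_points, status = "ok")
    }))
  }
  if (!is.null(denat_groups)) {
    denat_fits <- lapply(denat_groups, function(reps)
      safe_fit(fit_two_state_global, reps, ...))
    chemical <- do.call(rbind, lapply(names(denat_fits), function(nm) {
      f <- denat_fits[[nm]]
      if (inherits(f, "error"))
        return(data.frame(group = nm, dg_h2o = NA, se_dg = NA, cmid = NA,
                          m_value = NA, se_m = NA, se_mode = NA, rss = NA,
                          n = NA, status = conditionMessage(f)))
      data.frame(group = nm, dg_h2o = f$dg_h2o, se_dg = f$se_dg,
                 cmid = f$cmid, m_value = f$m_value, se_m = f$se_m,
                 se_mode = f$se_mode, rss = f$residual_ss, n = f$n_points,
                 status = "ok")
    }))
  }

  comparisons <- NULL
  if (!is.null(pairs)) {
    comparisons <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      rn <- pairs$reference[i]; mn <- pairs$modified[i]
      if (rn %in% names(melt_fits) && mn %in% names(melt_fits)) {
        fr <- melt_fits[[rn]]; fm <- melt_fits[[mn]]
        kind <- "delta_tm"; fun <- delta_tm
      } else if (rn %in% names(denat_fits) && mn %in% names(denat_fits)) {
        fr <- denat_fits[[rn]]; fm <- denat_fits[[mn]]
        kind <- "delta_delta_g"; fun <- delta_delta_g
      } else stop("pair (", rn, ", ", mn, ") not found among fitted groups")
      if (inherits(fr, "error") || inherits(fm, "error"))
        return(data.frame(reference = rn, modified = mn, kind = kind,
                          delta = NA, error = NA, status = "fit failed"))
      d <- fun(fr, fm, reference_label = rn, modified_label = mn)
      data.frame(reference = rn, modified = mn, kind = kind,
                 delta = d$value, error = d$error, status = "ok")
    }))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(thermal))
      utils::write.csv(thermal, file.path(out_dir, "thermal_fits.csv"),
                       row.names = FALSE)
    if (!is.null(chemical))
      utils::write.csv(chemical, file.path(out_dir, "chemical_fits.csv"),
                       row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
  }
  list(thermal = thermal, chemical = chemical, comparisons = comparisons,
       melt_fits = melt_fits, denat_fits = denat_fits)
}
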