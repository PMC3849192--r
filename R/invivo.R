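## In vivo translation: vascular correction, unbound ratio conversion,
## free-brain profile prediction, microdialysis correction, fold comparison,
## and efficacy coverage.

#' Concentration-time profile
#'
#' A free-concentration time series: observed free plasma or free brain
#' (microdialysis) or a predicted free brain profile.
#'
#' @param times Strictly increasing sampling times, min.
#' @param values Concentrations, nM (>= 0).
#' @param kind One of `"plasma-free"`, `"brain-free-observed"`,
#'   `"brain-free-predicted"`.
#' @return An object of class `"concentration_profile"`.
#' @examples
#' concentration_profile(c(30, 60, 120), c(900, 2500, 3300))
#' @export
concentration_profile <- function(times, values,
                                  kind = c("plasma-free", "brain-free-observed",
                                           "brain-free-predicted")) {
  kind <- match.arg(kind)
  if (length(times) == 0L) stop_kpuu("empty profile")
  if (length(times) != length(values)) {
    stop_kpuu("`times` and `values` must have equal length")
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop_kpuu("`times` must be finite and strictly increasing")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_kpuu("`values` must be finite and non-negative")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile (%s), %d timepoints, %g-%g min\n",
              x$kind, length(x$times), min(x$times), max(x$times)))
  print(data.frame(time_min = x$times, conc_nM = x$values), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(time_min = x$times, conc_nM = x$values)
}

#' Correct a total brain concentration for residual blood
#'
#' Brain tissue retains residual blood after dissection; its drug content is
#' removed by subtracting `V_vasc` (the vascular space, 13 µL/g measured
#' with \eqn{^{14}}C-sucrose) times the plasma concentration. Negative
#' results are floored at zero with a warning.
#'
#' @param C_br_raw Measured total brain concentration, µM per g (>= 0).
#' @param C_pl Plasma concentration, µM (>= 0).
#' @param V_vasc Residual blood volume, mL/g (default 0.013).
#' @return The corrected brain concentration.
#' @examples
#' correct_vascular(1.0, 10)  # 1.0 - 0.013 * 10 = 0.87
#' @export
correct_vascular <- function(C_br_raw, C_pl, V_vasc = 0.013) {
  check_number(C_br_raw, "C_br_raw", 0)
  check_number(C_pl, "C_pl", 0)
  check_number(V_vasc, "V_vasc", 0)
  out <- C_br_raw - V_vasc * C_pl
  if (out < 0) {
    warning(sprintf(
      "vascular correction gives %.3g < 0; floored at 0 (brain signal may be all residual blood)",
      out), call. = FALSE)
    out <- 0
  }
  out
}

#' In vivo unbound brain/plasma ratio from total concentrations
#'
#' Converts a steady-state total brain/plasma concentration ratio into the
#' unbound ratio using in vitro unbound fractions:
#' \deqn{C_{u,br}/C_{u,pl} = \frac{C_{br}}{C_{pl}} \times
#'       \frac{f_{u,br}}{f_{u,pl}}}
#'
#' @param C_tot_br Total brain concentration (vascular-corrected), µM.
#' @param C_tot_pl Total plasma concentration, µM (> 0).
#' @param fu_br Fraction unbound in brain (> 0).
#' @param fu_pl Fraction unbound in plasma (> 0).
#' @return The dimensionless unbound ratio.
#' @examples
#' kpuu_in_vivo(C_tot_br = 2, C_tot_pl = 1, fu_br = 0.01, fu_pl = 0.05)
#' @export
kpuu_in_vivo <- function(C_tot_br, C_tot_pl, fu_br, fu_pl) {
  check_number(C_tot_br, "C_tot_br", 0)
  check_number(fu_br, "fu_br", 0, strict = TRUE)
  if (!is.numeric(C_tot_pl) || length(C_tot_pl) != 1L || is.na(C_tot_pl) ||
      C_tot_pl <= 0) {
    stop_kpuu("undefined ratio: total plasma concentration must be positive")
  }
  if (!is.numeric(fu_pl) || length(fu_pl) != 1L || is.na(fu_pl) || fu_pl <= 0) {
    stop_kpuu("undefined ratio: fu_pl must be positive")
  }
  (C_tot_br / C_tot_pl) * (fu_br / fu_pl)
}

#' Predict a free brain concentration-time profile
#'
#' Multiplies a free plasma profile by the in vitro unbound brain/plasma
#' ratios: the 1-h ratio for timepoints up to 60 min (distribution phase),
#' the steady-state ratio from 120 min onward (plasma assumed at steady
#' state by 2 h), and a ratio interpolated linearly in time between 60 and
#' 120 min so the predicted profile is continuous.
#'
#' @param plasma A `"concentration_profile"` of free plasma concentrations.
#' @param R_1h In vitro 1-h ratio (>= 0).
#' @param R_ss In vitro steady-state ratio (>= 0).
#' @return A `"concentration_profile"` of kind `"brain-free-predicted"` on
#'   the same timepoints.
#' @examples
#' pl <- concentration_profile(c(30, 90, 180), c(3300, 3300, 3300))
#' predict_free_brain_profile(pl, R_1h = 0.17, R_ss = 0.15)
#' @export
predict_free_brain_profile <- function(plasma, R_1h, R_ss) {
  stopifnot(inherits(plasma, "concentration_profile"))
  check_number(R_1h, "R_1h", 0)
  check_number(R_ss, "R_ss", 0)
  t <- plasma$times
  w <- pmin(pmax((t - 60) / 60, 0), 1)  # 0 up to 60 min, 1 from 120 min
  ratio <- R_1h + (R_ss - R_1h) * w
  concentration_profile(t, ratio * plasma$values, kind = "brain-free-predicted")
}

#' Correct microdialysis concentrations for carrier-flow dilution
#'
#' The dialysate (flow `F_dialysate`) is diluted by an ultrapure-water
#' carrier flow (`F_carrier`) before collection; measured concentrations
#' are multiplied by `(F_dialysate + F_carrier) / F_dialysate`. With the
#' standard flows of 0.15 and 0.80 µL/min the factor is 19/3.
#'
#' @param raw A `"concentration_profile"` of measured concentrations.
#' @param F_dialysate Dialysate flow, µL/min (> 0, default 0.15).
#' @param F_carrier Carrier flow, µL/min (>= 0, default 0.80).
#' @return The corrected profile (same kind and times).
#' @examples
#' p <- concentration_profile(c(30, 60), c(1, 2), kind = "brain-free-observed")
#' correct_microdialysis_dilution(p)
#' @export
correct_microdialysis_dilution <- function(raw, F_dialysate = 0.15,
                                           F_carrier = 0.80) {
  stopifnot(inherits(raw, "concentration_profile"))
  check_number(F_dialysate, "F_dialysate", 0, strict = TRUE)
  check_number(F_carrier, "F_carrier", 0)
  factor <- (F_dialysate + F_carrier) / F_dialysate
  concentration_profile(raw$times, raw$values * factor, kind = raw$kind)
}

#' Per-timepoint fold comparison of two profiles
#'
#' Compares a predicted and an observed profile sampled at identical times:
#' a timepoint is within `k`-fold when `max(pred/obs, obs/pred) <= k`
#' (boundary inclusive), with both values positive. Pairs in which one
#' value is zero are incomparable; they are flagged, excluded from the
#' summary, and warned about.
#'
#' @param pred,obs `"concentration_profile"` objects on identical
#'   timepoints (no resampling is performed).
#' @param k Fold threshold (>= 1, default 3).
#' @return An object of class `"fold_comparison"`: a data frame of
#'   per-timepoint folds and flags plus a summary.
#' @examples
#' a <- concentration_profile(c(30, 60), c(30, 10), "brain-free-predicted")
#' b <- concentration_profile(c(30, 60), c(10, 31), "brain-free-observed")
#' fold_comparison(a, b, k = 3)
#' @export
fold_comparison <- function(pred, obs, k = 3) {
  stopifnot(inherits(pred, "concentration_profile"),
            inherits(obs, "concentration_profile"))
  check_number(k, "k", 1)
  if (length(pred$times) != length(obs$times) ||
      any(abs(pred$times - obs$times) > 1e-9)) {
    stop_kpuu("profiles must be aligned on identical timepoints")
  }
  comparable <- pred$values > 0 & obs$values > 0
  fold <- ifelse(comparable, pmax(pred$values / obs$values,
                                  obs$values / pred$values), NA_real_)
  if (any(!comparable)) {
    warning(sprintf(
      "%d timepoint(s) with a zero concentration are incomparable and excluded",
      sum(!comparable)), call. = FALSE)
  }
  tab <- data.frame(time = pred$times, pred = pred$values, obs = obs$values,
                    fold = fold, comparable = comparable,
                    within = !is.na(fold) & fold <= k)
  structure(list(table = tab, k = k,
                 n = sum(comparable),
                 n_within = sum(tab$within),
                 violations = tab$time[comparable & !tab$within]),
            class = "fold_comparison")
}

#' @export
print.fold_comparison <- function(x, ...) {
  cat(sprintf("Fold comparison (k = %g): %d of %d comparable timepoints within\n",
              x$k, x$n_within, x$n))
  if (length(x$violations)) {
    cat("  violating timepoints (min):", paste(x$violations, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Efficacy coverage of predicted free brain concentrations
#'
#' Predicts the free brain concentration at each dose as the in vitro
#' steady-state ratio times the steady-state free plasma concentration, and
#' relates it to an in vitro potency: `coverage = Cu_br_pred / IC50`. Doses
#' with coverage at or above 1 are flagged as "effect anticipated".
#'
#' @param R_ss In vitro steady-state unbound ratio (>= 0).
#' @param Cu_pl_per_dose Steady-state free plasma concentrations, nM, one
#'   per dose (> 0).
#' @param IC50 In vitro potency, nM (> 0).
#' @param doses Optional dose labels (e.g. µmol/kg), recycled to the
#'   concentrations.
#' @return An object of class `"efficacy_assessment"` wrapping a data frame
#'   with `dose`, `Cu_pl`, `Cu_br_pred`, `coverage`, `effect_anticipated`.
#' @examples
#' efficacy_coverage(R_ss = 0.15, Cu_pl_per_dose = c(40, 400, 3300),
#'                   IC50 = 55, doses = c(30, 100, 300))
#' @export
efficacy_coverage <- function(R_ss, Cu_pl_per_dose, IC50, doses = NULL) {
  check_number(R_ss, "R_ss", 0)
  if (!is.numeric(Cu_pl_per_dose) || length(Cu_pl_per_dose) < 1L ||
      any(!is.finite(Cu_pl_per_dose)) || any(Cu_pl_per_dose <= 0)) {
    stop_kpuu("`Cu_pl_per_dose` must be positive concentrations")
  }
  if (!is.numeric(IC50) || length(IC50) != 1L || is.na(IC50) || IC50 <= 0) {
    stop_kpuu("`IC50` must be positive")
  }
  if (is.null(doses)) doses <- seq_along(Cu_pl_per_dose)
  Cu_br <- R_ss * Cu_pl_per_dose
  coverage <- Cu_br / IC50
  tab <- data.frame(dose = doses, Cu_pl = Cu_pl_per_dose,
                    Cu_br_pred = Cu_br, coverage = coverage,
                    effect_anticipated = coverage >= 1)
  structure(list(table = tab, R_ss = R_ss, IC50 = IC50),
            class = "efficacy_assessment")
}

#' @export
print.efficacy_assessment <- function(x, digits = 3, ...) {
  cat(sprintf("Efficacy coverage: R_ss = %g, IC50 = %g nM\n", x$R_ss, x$IC50))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}
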