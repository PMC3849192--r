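## Transwell transport model: geometry, forward simulation, and the
## single-timepoint steady-state extrapolation fit.

#' Transwell insert geometry
#'
#' Describes the co-culture insert used in the blood-brain-barrier transport
#' assay: a luminal ("blood", donor) compartment above the endothelial
#' monolayer and an abluminal ("brain", receiver) compartment containing
#' glial cells.
#'
#' @param V_lum Luminal (donor) fill volume, µL.
#' @param V_ab Abluminal (receiver) free buffer volume, µL.
#' @param A Insert membrane area, cm². Defaults to 4.7 cm², the area of the
#'   six-well format insert the assay uses.
#'
#' @return An object of class `"transwell_geometry"`.
#' @examples
#' transwell_geometry()
#' @export
transwell_geometry <- function(V_lum = 1500, V_ab = 2500, A = 4.7) {
  check_number(V_lum, "V_lum", 0, strict = TRUE)
  check_number(V_ab, "V_ab", 0, strict = TRUE)
  check_number(A, "A", 0, strict = TRUE)
  structure(list(V_lum = V_lum, V_ab = V_ab, A = A),
            class = "transwell_geometry")
}

#' @export
print.transwell_geometry <- function(x, ...) {
  cat(sprintf("Transwell geometry: V_lum = %g uL, V_ab = %g uL, A = %g cm2\n",
              x$V_lum, x$V_ab, x$A))
  invisible(x)
}

#' Mechanistic transport parameters
#'
#' The quantities governing transfer across the monolayer in the forward
#' model: an influx permeability-surface clearance (luminal to abluminal),
#' an efflux-direction clearance (abluminal to luminal), and the apparent
#' abluminal distribution volume, which exceeds the free buffer volume when
#' glial or nonspecific binding takes up compound. The true open-system
#' steady-state unbound ratio implied by the parameters is
#' `R_ss_true = PS_in / PS_out`.
#'
#' @param PS_in Influx clearance, µL/min (>= 0).
#' @param PS_out Efflux-direction clearance, µL/min (> 0).
#' @param V_app Apparent abluminal distribution volume, µL. Must be at least
#'   the free abluminal volume of the geometry it is used with.
#'
#' @return An object of class `"transport_params"` with an `R_ss_true` field.
#' @examples
#' transport_params(PS_in = 10, PS_out = 20, V_app = 3000)
#' @export
transport_params <- function(PS_in, PS_out, V_app) {
  check_number(PS_in, "PS_in", 0)
  check_number(PS_out, "PS_out", 0, strict = TRUE)
  check_number(V_app, "V_app", 0, strict = TRUE)
  structure(list(PS_in = PS_in, PS_out = PS_out, V_app = V_app,
                 R_ss_true = PS_in / PS_out),
            class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf(
    "Transport parameters: PS_in = %g, PS_out = %g uL/min, V_app = %g uL (R_ss_true = %.4g)\n",
    x$PS_in, x$PS_out, x$V_app, x$R_ss_true))
  invisible(x)
}

#' One transwell measurement
#'
#' Donor and receiver concentrations of one compound in one insert: the
#' donor concentration at the start (nominally 2 µM) and both compartment
#' concentrations at the sampling time (1 h in the standard protocol),
#' optionally with the receiver/donor fraction of the co-dosed
#' \eqn{^{14}}C-sucrose integrity tracer.
#'
#' @param C_d0 Donor concentration at t = 0, µM (> 0).
#' @param C_d_t Donor concentration at time `t`, µM (must not exceed `C_d0`).
#' @param C_r_t Receiver concentration at time `t`, µM (>= 0).
#' @param t Sampling time, min (default 60).
#' @param sucrose_receiver_frac Receiver/donor fraction of the sucrose
#'   tracer at `t`, in `[0, 1)`; `NA` when the tracer was not measured.
#'
#' @return An object of class `"transwell_measurement"`.
#' @examples
#' transwell_measurement(C_d0 = 2, C_d_t = 1.6, C_r_t = 0.2)
#' @export
transwell_measurement <- function(C_d0 = 2, C_d_t, C_r_t, t = 60,
                                  sucrose_receiver_frac = NA_real_) {
  check_number(C_d0, "C_d0", 0, strict = TRUE)
  check_number(C_d_t, "C_d_t", 0)
  check_number(C_r_t, "C_r_t", 0)
  check_number(t, "t", 0, strict = TRUE)
  check_number(sucrose_receiver_frac, "sucrose_receiver_frac", 0, allow_na = TRUE)
  if (C_d_t > C_d0) {
    stop_kpuu("donor concentration cannot increase: C_d_t > C_d0")
  }
  if (!is.na(sucrose_receiver_frac) && sucrose_receiver_frac >= 1) {
    stop_kpuu("`sucrose_receiver_frac` must be in [0, 1)")
  }
  structure(list(C_d0 = C_d0, C_d_t = C_d_t, C_r_t = C_r_t, t = t,
                 sucrose_receiver_frac = sucrose_receiver_frac),
            class = "transwell_measurement")
}

#' @export
print.transwell_measurement <- function(x, ...) {
  cat(sprintf("Transwell measurement at t = %g min:\n", x$t))
  cat(sprintf("  donor    %g -> %g uM\n", x$C_d0, x$C_d_t))
  cat(sprintf("  receiver 0 -> %g uM\n", x$C_r_t))
  if (!is.na(x$sucrose_receiver_frac)) {
    cat(sprintf("  sucrose receiver fraction %g\n", x$sucrose_receiver_frac))
  }
  invisible(x)
}

## Closed-form solution of the two-compartment linear system
##   dC_d/dt = -(PS_in C_d - PS_out C_r)/V_lum
##   dC_r/dt = +(PS_in C_d - PS_out C_r)/V_app
## The system matrix is singular (amount V_lum C_d + V_app C_r is conserved),
## so the solution relaxes toward the equilibrium split with a single rate
## k = PS_in/V_lum + PS_out/V_app.

#' Simulate a transwell transport experiment
#'
#' Exact solution of the two-compartment donor/receiver system with influx
#' clearance `PS_in`, efflux-direction clearance `PS_out` and apparent
#' abluminal volume `V_app`. The receiver starts drug-free and total tracked
#' amount `V_lum * C_d + V_app * C_r` is conserved.
#'
#' @param params A [transport_params()] object.
#' @param geom A [transwell_geometry()] object; `V_app` must be at least
#'   `geom$V_ab`.
#' @param C_d0 Initial donor concentration, µM.
#' @param times Sorted, non-negative sampling times, min.
#'
#' @return A data frame with columns `time`, `C_donor`, `C_receiver` (µM).
#' @examples
#' p <- transport_params(PS_in = 10, PS_out = 20, V_app = 3000)
#' simulate_transwell(p, transwell_geometry(), C_d0 = 2, times = c(0, 30, 60))
#' @export
simulate_transwell <- function(params, geom = transwell_geometry(), C_d0 = 2,
                               times = seq(0, 60, by = 5)) {
  stopifnot(inherits(params, "transport_params"),
            inherits(geom, "transwell_geometry"))
  check_number(C_d0, "C_d0", 0, strict = TRUE)
  if (params$V_app < geom$V_ab) {
    stop_kpuu("V_app must be at least the free abluminal volume V_ab")
  }
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0) ||
      is.unsorted(times)) {
    stop_kpuu("`times` must be sorted, finite and non-negative")
  }
  V_lum <- geom$V_lum
  k <- params$PS_in / V_lum + params$PS_out / params$V_app
  C_d_inf <- V_lum * C_d0 /
    (V_lum + params$V_app * params$PS_in / params$PS_out)
  C_r_inf <- params$R_ss_true * C_d_inf
  decay <- exp(-k * times)
  data.frame(time = times,
             C_donor = C_d_inf + (C_d0 - C_d_inf) * decay,
             C_receiver = C_r_inf * (1 - decay))
}

#' Receiver/donor concentration ratio at the sampling time
#'
#' The non-steady-state in vitro Cu,br/Cu,pl estimate: the abluminal
#' concentration divided by the luminal concentration at 1 h.
#'
#' @param meas A [transwell_measurement()].
#' @return The dimensionless ratio `C_r_t / C_d_t`.
#' @examples
#' ratio_one_hour(transwell_measurement(C_d0 = 2, C_d_t = 1.6, C_r_t = 0.2))
#' @export
ratio_one_hour <- function(meas) {
  stopifnot(inherits(meas, "transwell_measurement"))
  if (meas$C_d_t <= 0) {
    stop_kpuu("degenerate measurement: donor concentration at t is not positive")
  }
  meas$C_r_t / meas$C_d_t
}

## Stable divided difference (exp(-lambda t) - exp(-mu t)) / (mu - lambda),
## including the confluent limit t * exp(-lambda t) as mu -> lambda.
exp_divided_diff <- function(lambda, mu, t) {
  x <- (mu - lambda) * t
  h <- ifelse(abs(x) < 1e-8, 1 - x / 2 + x^2 / 6, -expm1(-x) / x)
  exp(-lambda * t) * t * h
}

#' Fit the steady-state extrapolation model to a transwell measurement
#'
#' Estimates the in vitro steady-state unbound brain/plasma ratio from a
#' single-timepoint transwell experiment. The donor decline is treated as a
#' mono-exponential with rate \eqn{\lambda = \log(C_{d0}/C_{d,t})/t} (influx
#' clearance \eqn{CL_{in} = \lambda V_{lum}}); with the donor forced to that
#' exponential, the receiver compartment is modelled as an open compartment
#' with exit clearance \eqn{CL_{out} = \mu V_{ab}}, and \eqn{\mu} is solved
#' so the receiver solution
#' \deqn{C_r(\tau) = \frac{CL_{in} C_{d0}}{V_{ab}}
#'   \frac{e^{-\lambda\tau} - e^{-\mu\tau}}{\mu - \lambda}}
#' matches the observed receiver concentration at the sampling time. The
#' extrapolated steady-state ratio is the constant-donor plateau
#' \eqn{R_{ss} = CL_{in}/CL_{out}}, mirroring the in vivo constant-rate
#' infusion steady state. The exit clearance lumps true backflux across the
#' monolayer with abluminal (glial/nonspecific) binding uptake, so the
#' extrapolation is an approximation whose stated validity domain is
#' `C_r_t << C_d_t` with appreciable abluminal uptake; see the package
#' vignette for an identifiability analysis.
#'
#' @param meas A [transwell_measurement()] with measurable donor decline
#'   (`0 < C_d_t < C_d0`).
#' @param geom A [transwell_geometry()].
#'
#' @return An object of class `"transwell_fit"` with coefficients
#'   `lambda_donor` and `mu_receiver` (1/min), `CL_in` and `CL_out`
#'   (µL/min), and the ratios `R_1h` and `R_ss`.
#' @seealso [simulate_transwell()] for the forward model, [sucrose_qc()] for
#'   monolayer integrity.
#' @examples
#' m <- transwell_measurement(C_d0 = 2, C_d_t = 1.6, C_r_t = 0.2, t = 60)
#' fit <- transwell_fit(m)
#' coef(fit)
#' summary(fit)
#' @export
transwell_fit <- function(meas, geom = transwell_geometry()) {
  stopifnot(inherits(meas, "transwell_measurement"),
            inherits(geom, "transwell_geometry"))
  if (meas$C_d_t <= 0) {
    stop_kpuu("donor concentration at t must be positive")
  }
  if (meas$C_d_t >= meas$C_d0) {
    stop_kpuu("no measurable donor decline (C_d_t >= C_d0): ",
              "influx clearance is not identifiable")
  }
  t <- meas$t
  lambda <- log(meas$C_d0 / meas$C_d_t) / t
  CL_in <- lambda * geom$V_lum
  R_1h <- meas$C_r_t / meas$C_d_t

  if (meas$C_r_t == 0) {
    warning("receiver concentration is zero: steady-state ratio reported as 0",
            call. = FALSE)
    est <- c(lambda_donor = lambda, mu_receiver = NA_real_,
             CL_in = CL_in, CL_out = NA_real_, R_1h = R_1h, R_ss = 0)
    return(new_transwell_fit(est, meas, geom, residual = 0))
  }

  scale <- CL_in * meas$C_d0 / geom$V_ab
  f <- function(mu) scale * exp_divided_diff(lambda, mu, t) - meas$C_r_t
  lower <- 1e-8
  upper <- 10
  f_lo <- f(lower)
  f_hi <- f(upper)
  if (f_lo < 0) {
    stop_kpuu("steady-state estimation failed: receiver concentration is at ",
              "or above the zero-exit bound implied by the donor decline ",
              "(no receiver exit rate in (1e-8, 10) 1/min fits the data)")
  }
  if (f_hi > 0) {
    stop_kpuu("steady-state estimation failed: receiver exit rate exceeds ",
              "the search bracket (1e-8, 10) 1/min")
  }
  root <- uniroot(f, lower = lower, upper = upper,
                  f.lower = f_lo, f.upper = f_hi, tol = 1e-12)
  mu <- root$root
  residual <- f(mu)
  if (abs(residual) >= 1e-9 * meas$C_d0) {
    stop_kpuu("steady-state estimation did not converge (residual ",
              format(residual), " uM)")
  }
  CL_out <- mu * geom$V_ab
  est <- c(lambda_donor = lambda, mu_receiver = mu,
           CL_in = CL_in, CL_out = CL_out, R_1h = R_1h,
           R_ss = CL_in / CL_out)
  new_transwell_fit(est, meas, geom, residual = residual)
}

new_transwell_fit <- function(coefficients, meas, geom, residual) {
  structure(list(coefficients = coefficients, measurement = meas,
                 geometry = geom, residual = residual),
            class = "transwell_fit")
}

#' @export
print.transwell_fit <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  cat("Transwell steady-state extrapolation fit\n")
  cat(sprintf("  R at %g min (C_r/C_d): %s\n", x$measurement$t,
              format(cf[["R_1h"]], digits = digits)))
  cat(sprintf("  R at steady state:     %s\n",
              format(cf[["R_ss"]], digits = digits)))
  invisible(x)
}

#' @export
coef.transwell_fit <- function(object, ...) object$coefficients

#' @export
residuals.transwell_fit <- function(object, ...) {
  c(receiver = object$residual)
}

#' @rdname transwell_fit
#' @param object,x A `"transwell_fit"` object.
#' @param ... Unused.
#' @export
summary.transwell_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.transwell_fit")
}

#' @export
print.summary.transwell_fit <- function(x, digits = 4, ...) {
  fit <- x$fit
  cf <- fit$coefficients
  m <- fit$measurement
  print(fit$geometry)
  print(m)
  cat("Fitted kinetic constants:\n")
  cat(sprintf("  lambda_donor  %s 1/min   CL_in  %s uL/min\n",
              format(cf[["lambda_donor"]], digits = digits),
              format(cf[["CL_in"]], digits = digits)))
  cat(sprintf("  mu_receiver   %s 1/min   CL_out %s uL/min\n",
              format(cf[["mu_receiver"]], digits = digits),
              format(cf[["CL_out"]], digits = digits)))
  cat("Unbound brain/plasma ratio estimates:\n")
  cat(sprintf("  R_1h = %s, R_ss = %s\n",
              format(cf[["R_1h"]], digits = digits),
              format(cf[["R_ss"]], digits = digits)))
  invisible(x)
}

#' Predicted concentration curves from a transwell fit
#'
#' Evaluates the fitted forced-exponential donor curve and the open-receiver
#' solution at the requested times.
#'
#' @param object A `"transwell_fit"`.
#' @param times Times, min.
#' @param ... Unused.
#' @return A data frame with columns `time`, `C_donor`, `C_receiver`.
#' @export
predict.transwell_fit <- function(object, times = seq(0, 120, by = 5), ...) {
  cf <- object$coefficients
  m <- object$measurement
  lambda <- cf[["lambda_donor"]]
  C_d <- m$C_d0 * exp(-lambda * times)
  if (is.na(cf[["mu_receiver"]])) {
    C_r <- rep(0, length(times))
  } else {
    scale <- cf[["CL_in"]] * m$C_d0 / object$geometry$V_ab
    C_r <- scale * exp_divided_diff(lambda, cf[["mu_receiver"]], times)
  }
  data.frame(time = times, C_donor = C_d, C_receiver = C_r)
}

#' Simulate replicate measurements from a transwell fit
#'
#' Draws replicate single-timepoint measurements from the fitted curves with
#' multiplicative lognormal measurement noise, emulating assay variability.
#'
#' @param object A `"transwell_fit"`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param cv Coefficient of variation of the lognormal noise (default 0.1).
#' @param ... Unused.
#' @return A data frame with one row per replicate (`C_d0`, `C_d_t`,
#'   `C_r_t`, `t`).
#' @export
simulate.transwell_fit <- function(object, nsim = 1, seed = NULL, cv = 0.1, ...) {
  check_number(nsim, "nsim", 1)
  check_number(cv, "cv", 0)
  m <- object$measurement
  fit_t <- predict(object, times = m$t)
  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- function(n) exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
    data.frame(replicate = seq_len(nsim),
               C_d0 = m$C_d0,
               C_d_t = fit_t$C_donor * noise(nsim),
               C_r_t = fit_t$C_receiver * noise(nsim),
               t = m$t)
  })
}

#' @rdname transwell_fit
#' @export
plot.transwell_fit <- function(x, ...) {
  m <- x$measurement
  curves <- predict(x, times = seq(0, 2 * m$t, length.out = 101))
  matplot(curves$time, cbind(curves$C_donor, curves$C_receiver),
          type = "l", lty = 1, col = c("steelblue4", "firebrick"),
          xlab = "time (min)", ylab = "concentration (uM)",
          main = "Transwell fit", ...)
  points(c(0, m$t, m$t), c(m$C_d0, m$C_d_t, m$C_r_t),
         pch = 19, col = c("steelblue4", "steelblue4", "firebrick"))
  abline(h = coef(x)[["R_ss"]] * m$C_d0 * exp(-coef(x)[["lambda_donor"]] * m$t),
         lty = 3, col = "grey40")
  legend("topright", bty = "n", lty = 1, col = c("steelblue4", "firebrick"),
         legend = c("donor", "receiver"))
  invisible(x)
}

#' Monolayer integrity QC from the sucrose tracer
#'
#' Computes the endothelial permeability coefficient of the co-dosed
#' \eqn{^{14}}C-sucrose tracer from its receiver/donor fraction at the
#' sampling time, using the single-timepoint clearance form
#' \eqn{P_e = V_{ab} \cdot frac / (t \cdot A)} with volumes in mL, and flags
#' whether the monolayer passed the integrity criterion
#' \eqn{P_e < 0.5\times10^{-3}} cm/min.
#'
#' @param meas A [transwell_measurement()] carrying `sucrose_receiver_frac`.
#' @param geom A [transwell_geometry()].
#' @param threshold Pass threshold, cm/min (default `5e-4`).
#'
#' @return An object of class `"sucrose_qc"` with fields `Pe` (cm/min),
#'   `pass`, and `available`. When the tracer was not measured, `Pe` and
#'   `pass` are `NA` and `available` is `FALSE` — never a silent pass.
#' @examples
#' m <- transwell_measurement(C_d0 = 2, C_d_t = 1.6, C_r_t = 0.2,
#'                            sucrose_receiver_frac = 0.05)
#' sucrose_qc(m)
#' @export
sucrose_qc <- function(meas, geom = transwell_geometry(), threshold = 5e-4) {
  stopifnot(inherits(meas, "transwell_measurement"),
            inherits(geom, "transwell_geometry"))
  check_number(threshold, "threshold", 0)
  frac <- meas$sucrose_receiver_frac
  if (is.na(frac)) {
    return(structure(list(Pe = NA_real_, pass = NA, available = FALSE,
                          threshold = threshold), class = "sucrose_qc"))
  }
  V_ab_mL <- geom$V_ab / 1000
  Pe <- V_ab_mL * frac / (meas$t * geom$A)
  structure(list(Pe = Pe, pass = Pe < threshold, available = TRUE,
                 threshold = threshold), class = "sucrose_qc")
}

#' @export
print.sucrose_qc <- function(x, ...) {
  if (!x$available) {
    cat("Sucrose QC: tracer not measured (QC unavailable)\n")
  } else {
    cat(sprintf("Sucrose QC: Pe = %.3g cm/min (threshold %.3g) -> %s\n",
                x$Pe, x$threshold, if (x$pass) "pass" else "FAIL"))
  }
  invisible(x)
}
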