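## Independent numerical oracles, kept deliberately separate from the
## package's closed-form code paths.

## Brute-force integration of the two-compartment transwell system.
ode_transwell <- function(PS_in, PS_out, V_lum, V_app, C_d0, times) {
  rhs <- function(t, y, parms) {
    flux <- PS_in * y[1] - PS_out * y[2]
    list(c(-flux / V_lum, flux / V_app))
  }
  out <- deSolve::lsoda(c(C_d = C_d0, C_r = 0), times = c(0, times), rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  out <- out[match(times, out[, "time"]), , drop = FALSE]
  data.frame(time = times, C_donor = out[, "C_d"], C_receiver = out[, "C_r"])
}

## Single-timepoint steady-state extrapolation by plain bisection on the
## receiver exit rate, with the receiver curve obtained by fixed-step RK4
## integration of the forced-donor receiver equation
##   dC_r/dt = (CL_in * C_d0 * exp(-lambda t) - mu V_ab C_r) / V_ab
## (never the closed-form receiver solution the package uses).
bisect_steady_state <- function(C_d0, C_d_t, C_r_t, t, V_lum, V_ab,
                                step = 0.01, tol = 1e-10) {
  lambda <- log(C_d0 / C_d_t) / t
  CL_in <- lambda * V_lum
  receiver_at_t <- function(mu) {
    n <- ceiling(t / step)
    h <- t / n
    cr <- 0
    tau <- 0
    f <- function(tau, cr) CL_in * C_d0 * exp(-lambda * tau) / V_ab - mu * cr
    for (i in seq_len(n)) {
      k1 <- f(tau, cr)
      k2 <- f(tau + h / 2, cr + h * k1 / 2)
      k3 <- f(tau + h / 2, cr + h * k2 / 2)
      k4 <- f(tau + h, cr + h * k3)
      cr <- cr + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
      tau <- tau + h
    }
    cr
  }
  lo <- 1e-8
  hi <- 10
  if (receiver_at_t(lo) < C_r_t) return(NULL)  # no root in bracket
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (receiver_at_t(mid) > C_r_t) lo <- mid else hi <- mid
  }
  mu <- (lo + hi) / 2
  list(lambda = lambda, mu = mu, CL_in = CL_in, CL_out = mu * V_ab,
       R_ss = CL_in / (mu * V_ab))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
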