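test_that("forward simulator handles the zero-flux and symmetric limits", {
  geom <- transwell_geometry(V_lum = 2000, V_ab = 2000)

  none <- simulate_transwell(transport_params(0, 20, 2000), geom, C_d0 = 2,
                             times = c(0, 30, 60, 600))
  expect_equal(none$C_receiver, rep(0, 4))
  expect_equal(none$C_donor, rep(2, 4))

  sym <- simulate_transwell(transport_params(20, 20, 2000), geom, C_d0 = 2,
                            times = c(0, 60, 1e5))
  expect_equal(sym$C_donor[3], 1.0, tolerance = 1e-8)
  expect_equal(sym$C_receiver[3], 1.0, tolerance = 1e-8)
})

test_that("closed-form simulator matches brute-force ODE integration", {
  geom <- transwell_geometry(V_lum = 1500, V_ab = 3000)
  times <- c(5, 15, 30, 60, 120)

  # spec-style fixed case
  s <- simulate_transwell(transport_params(10, 20, 3000), geom, 2, times)
  o <- ode_transwell(10, 20, 1500, 3000, 2, times)
  expect_rel_equal(s$C_donor, o$C_donor, 1e-6)
  expect_rel_equal(s$C_receiver, o$C_receiver, 1e-6)

  # random parameter draws
  set.seed(101)
  for (i in 1:10) {
    PS_in <- runif(1, 0, 40)
    PS_out <- runif(1, 1, 40)
    V_app <- 3000 * (1 + runif(1, 0, 3))
    s <- simulate_transwell(transport_params(PS_in, PS_out, V_app), geom, 2, times)
    o <- ode_transwell(PS_in, PS_out, 1500, V_app, 2, times)
    expect_rel_equal(s$C_donor, o$C_donor, 1e-6)
    expect_rel_equal(s$C_receiver, o$C_receiver, 1e-6)
  }
})

test_that("simulated amount V_lum*C_d + V_app*C_r is conserved", {
  geom <- transwell_geometry()
  set.seed(202)
  for (i in 1:20) {
    V_app <- geom$V_ab * (1 + runif(1, 0, 4))
    p <- transport_params(runif(1, 0, 30), runif(1, 0.5, 30), V_app)
    s <- simulate_transwell(p, geom, C_d0 = 2, times = seq(0, 240, by = 10))
    total <- geom$V_lum * s$C_donor + V_app * s$C_receiver
    expect_rel_equal(total, rep(geom$V_lum * 2, length(total)), 1e-9)
  }
})

test_that("simulator rejects invalid parameters and times", {
  expect_error(transport_params(10, 0, 2500), "PS_out")
  expect_error(transport_params(10, 20, -1), "V_app")
  expect_error(transwell_geometry(V_lum = 0), "V_lum")
  p <- transport_params(10, 20, 2400)
  expect_error(simulate_transwell(p, transwell_geometry(), 2, 60), "V_app")
  p2 <- transport_params(10, 20, 3000)
  expect_error(simulate_transwell(p2, transwell_geometry(), 2, c(60, 30)),
               "sorted")
})

test_that("one-hour ratio is receiver over donor with guarded input", {
  expect_equal(ratio_one_hour(transwell_measurement(2, 1.6, 0)), 0)
  expect_equal(ratio_one_hour(transwell_measurement(2, 1.6, 1.6)), 1)
  expect_equal(ratio_one_hour(transwell_measurement(2, 1.6, 0.2)), 0.125)
  expect_error(ratio_one_hour(transwell_measurement(2, 0, 0.2)), "degenerate")
})

test_that("steady-state fit reproduces the independent bisection oracle", {
  # worked single-timepoint example; oracle = bisection on the receiver exit
  # rate with RK4 integration of the forced-donor receiver equation
  oracle <- bisect_steady_state(2, 1.6, 0.2, 60, 1500, 2500)
  expect_equal(oracle$lambda, log(1.25) / 60)

  fit <- transwell_fit(transwell_measurement(2, 1.6, 0.2, t = 60),
                       transwell_geometry(1500, 2500))
  cf <- coef(fit)
  expect_equal(cf[["lambda_donor"]], oracle$lambda, tolerance = 1e-10)
  expect_equal(cf[["mu_receiver"]], oracle$mu, tolerance = 1e-5)
  expect_equal(cf[["R_ss"]], oracle$R_ss, tolerance = 1e-5)

  # frozen values recomputed with the oracle before the closed form was coded
  expect_equal(cf[["lambda_donor"]], 3.719059e-3, tolerance = 1e-6)
  expect_equal(cf[["mu_receiver"]], 6.035072e-3, tolerance = 1e-6)
  expect_equal(cf[["R_1h"]], 0.125)
  expect_equal(cf[["R_ss"]], 0.3697446, tolerance = 1e-6)
  expect_lt(abs(residuals(fit)[["receiver"]]), 1e-9 * 2)
})

test_that("fit is scale-invariant and monotone in the receiver concentration", {
  geom <- transwell_geometry()
  base <- coef(transwell_fit(transwell_measurement(2, 1.5, 0.15), geom))
  for (scale in c(0.01, 3, 1000)) {
    scaled <- coef(transwell_fit(
      transwell_measurement(2 * scale, 1.5 * scale, 0.15 * scale), geom))
    expect_equal(scaled[["lambda_donor"]], base[["lambda_donor"]])
    expect_equal(scaled[["mu_receiver"]], base[["mu_receiver"]],
                 tolerance = 1e-9)
    expect_equal(scaled[["R_1h"]], base[["R_1h"]])
    expect_equal(scaled[["R_ss"]], base[["R_ss"]], tolerance = 1e-9)
  }

  # receiver sweep kept below the zero-exit mass bound V_lum*(C_d0-C_d_t)/V_ab
  r_ss <- vapply(seq(0.05, 0.25, by = 0.05), function(cr) {
    coef(transwell_fit(transwell_measurement(2, 1.5, cr), geom))[["R_ss"]]
  }, numeric(1))
  expect_true(all(diff(r_ss) > 0))
})

test_that("fit handles the confluent lambda == mu case via the limit form", {
  geom <- transwell_geometry()
  lambda <- log(2 / 1.6) / 60
  # receiver datum generated exactly by the forced-donor model at mu = lambda
  C_r_t <- (lambda * geom$V_lum * 2 / geom$V_ab) * 60 * exp(-lambda * 60)
  cf <- coef(transwell_fit(transwell_measurement(2, 1.6, C_r_t), geom))
  expect_equal(cf[["mu_receiver"]], lambda, tolerance = 1e-7)
  expect_equal(cf[["R_ss"]], geom$V_lum / geom$V_ab, tolerance = 1e-7)
})

test_that("fit reports degenerate measurements as errors or warnings", {
  geom <- transwell_geometry()
  expect_error(transwell_fit(transwell_measurement(2, 2, 0.2), geom),
               "not identifiable")
  expect_error(transwell_measurement(2, 2.4, 0.2), "increase")

  expect_warning(fit0 <- transwell_fit(transwell_measurement(2, 1.6, 0), geom),
                 "zero")
  expect_equal(coef(fit0)[["R_ss"]], 0)

  # receiver above the zero-exit mass bound implied by the donor decline
  bound <- geom$V_lum * (2 - 1.6) / geom$V_ab
  expect_error(transwell_fit(transwell_measurement(2, 1.6, bound * 1.05), geom),
               "estimation failed")
})

test_that("fit methods predict, simulate and plot coherently", {
  m <- transwell_measurement(2, 1.6, 0.2, t = 60)
  fit <- transwell_fit(m)

  at_t <- predict(fit, times = 60)
  expect_equal(at_t$C_donor, 1.6, tolerance = 1e-12)
  expect_equal(at_t$C_receiver, 0.2, tolerance = 1e-9)

  sim1 <- simulate(fit, nsim = 5, seed = 11)
  sim2 <- simulate(fit, nsim = 5, seed = 11)
  expect_identical(sim1, sim2)
  noiseless <- simulate(fit, nsim = 2, seed = 1, cv = 0)
  expect_equal(noiseless$C_d_t, rep(1.6, 2), tolerance = 1e-12)

  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("sucrose QC implements the single-timepoint clearance form", {
  geom <- transwell_geometry(V_lum = 1500, V_ab = 2500, A = 4.7)
  qc0 <- sucrose_qc(transwell_measurement(2, 1.6, 0.2,
                                          sucrose_receiver_frac = 0), geom)
  expect_equal(qc0$Pe, 0)
  expect_true(qc0$pass)

  qc_pass <- sucrose_qc(transwell_measurement(2, 1.6, 0.2, t = 60,
                                              sucrose_receiver_frac = 0.05),
                        geom)
  expect_equal(qc_pass$Pe, 2.5 * 0.05 / (60 * 4.7))  # 4.43e-4 cm/min
  expect_true(qc_pass$pass)

  qc_fail <- sucrose_qc(transwell_measurement(2, 1.6, 0.2, t = 60,
                                              sucrose_receiver_frac = 0.06),
                        geom)
  expect_equal(qc_fail$Pe, 2.5 * 0.06 / (60 * 4.7))  # 5.32e-4 cm/min
  expect_false(qc_fail$pass)

  qc_na <- sucrose_qc(transwell_measurement(2, 1.6, 0.2), geom)
  expect_false(qc_na$available)
  expect_true(is.na(qc_na$pass))  # never a silent pass
})
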