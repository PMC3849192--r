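test_that("vascular correction subtracts residual blood and floors at zero", {
  expect_equal(correct_vascular(1.0, 0), 1.0)
  expect_equal(correct_vascular(1.0, 10), 0.87)
  expect_warning(floored <- correct_vascular(0.1, 10), "floored")
  expect_equal(floored, 0)
})

test_that("in vivo unbound ratio combines total ratio with fu ratio", {
  expect_equal(kpuu_in_vivo(1, 1, 1, 1), 1)
  expect_equal(kpuu_in_vivo(2, 1, 0.01, 0.05), 0.4)
  # equal unbound fractions reduce to the total ratio
  expect_equal(kpuu_in_vivo(3, 2, 0.07, 0.07), 1.5)
  expect_error(kpuu_in_vivo(1, 0, 0.1, 0.1), "undefined")
  expect_error(kpuu_in_vivo(1, 1, 0.1, 0), "undefined")
})

test_that("in vivo ratio is invariant under common rescaling", {
  base <- kpuu_in_vivo(1.4, 0.9, 0.02, 0.11)
  expect_equal(kpuu_in_vivo(1.4 * 7, 0.9 * 7, 0.02, 0.11), base)
  expect_equal(kpuu_in_vivo(1.4, 0.9, 0.02 * 0.3, 0.11 * 0.3), base)
})

test_that("free-brain prediction applies the piecewise in vitro ratios", {
  pl <- concentration_profile(c(15, 30, 60, 90, 120, 180), rep(100, 6))

  ident <- predict_free_brain_profile(pl, 1, 1)
  expect_equal(ident$values, pl$values)
  expect_equal(ident$kind, "brain-free-predicted")

  pred <- predict_free_brain_profile(pl, 0.1, 0.7)
  expect_equal(pred$values[1:3], rep(10, 3))        # R_1h up to 60 min
  expect_equal(pred$values[4], 40)                  # midpoint ratio 0.4
  expect_equal(pred$values[5:6], rep(70, 2))        # R_ss from 120 min

  # high-dose plateau: steady-state ratio 0.15 on 3300 nM free plasma
  plateau <- predict_free_brain_profile(
    concentration_profile(c(120, 180, 240), rep(3300, 3)), 0.17, 0.15)
  expect_equal(plateau$values, rep(495, 3))
})

test_that("predicted profile is linear in plasma and continuous in time", {
  t <- c(30, 59.999, 60, 60.001, 90, 119.999, 120, 120.001, 200)
  pl1 <- concentration_profile(t, rep(80, length(t)))
  pl2 <- concentration_profile(t, seq(10, 90, length.out = length(t)))
  r1h <- 0.2; rss <- 0.9

  a <- predict_free_brain_profile(pl1, r1h, rss)
  b <- predict_free_brain_profile(pl2, r1h, rss)
  both <- predict_free_brain_profile(
    concentration_profile(t, pl1$values + 2 * pl2$values), r1h, rss)
  expect_equal(both$values, a$values + 2 * b$values)

  ratio <- a$values / pl1$values
  expect_equal(ratio[2], ratio[3], tolerance = 1e-4)  # continuity at 60
  expect_equal(ratio[6], ratio[7], tolerance = 1e-4)  # continuity at 120
  expect_error(predict_free_brain_profile(pl1, -0.1, 0.5), ">=")
})

test_that("microdialysis dilution correction scales by total/dialysate flow", {
  p <- concentration_profile(c(30, 60), c(1, 2), kind = "brain-free-observed")
  expect_equal(correct_microdialysis_dilution(p, 0.15, 0)$values, c(1, 2))
  expect_equal(correct_microdialysis_dilution(p)$values, c(1, 2) * 19 / 3)
  expect_equal(correct_microdialysis_dilution(p, 0.15, 0.15)$values, c(2, 4))
  expect_error(correct_microdialysis_dilution(p, 0, 0.8), "F_dialysate")
})

test_that("fold comparison is boundary-inclusive, symmetric and guarded", {
  t <- c(30, 60, 120)
  pred <- concentration_profile(t, c(30, 31, 5), "brain-free-predicted")
  obs <- concentration_profile(t, c(10, 10, 5), "brain-free-observed")

  fc <- fold_comparison(pred, obs, k = 3)
  expect_equal(fc$table$within, c(TRUE, FALSE, TRUE))  # 3.0 in, 3.1 out
  expect_equal(fc$violations, 60)

  # symmetry in pred/obs
  fc_swap <- fold_comparison(obs, pred, k = 3)
  expect_equal(fc_swap$table$fold, fc$table$fold)

  # identical profiles within for any k >= 1
  fc_id <- fold_comparison(pred, pred, k = 1)
  expect_equal(fc_id$n_within, 3)

  # shrinking within-set as k decreases
  ks <- c(4, 3, 2, 1.5)
  counts <- vapply(ks, function(k) fold_comparison(pred, obs, k)$n_within,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  # zero observed with nonzero predicted: excluded with warning
  obs0 <- concentration_profile(t, c(10, 0, 5), "brain-free-observed")
  expect_warning(fc0 <- fold_comparison(pred, obs0, k = 3), "incomparable")
  expect_equal(fc0$n, 2)

  misaligned <- concentration_profile(c(30, 61, 120), c(10, 10, 5))
  expect_error(fold_comparison(pred, misaligned), "aligned")
})

test_that("efficacy coverage predicts free brain levels per dose", {
  ea <- efficacy_coverage(R_ss = 0.15, Cu_pl_per_dose = c(40, 400, 3300),
                          IC50 = 55, doses = c(30, 100, 300))
  expect_equal(ea$table$Cu_br_pred, c(6, 60, 495))
  expect_equal(ea$table$coverage, c(6, 60, 495) / 55)
  expect_equal(ea$table$effect_anticipated, c(FALSE, TRUE, TRUE))

  zero <- efficacy_coverage(0, c(40, 400), 55)
  expect_equal(zero$table$Cu_br_pred, c(0, 0))
  expect_false(any(zero$table$effect_anticipated))

  expect_error(efficacy_coverage(0.15, c(40, 400), 0), "IC50")
})
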