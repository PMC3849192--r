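test_that("plasma unbound fraction is the buffer/plasma signal ratio", {
  expect_equal(fu_plasma(500, 500), 1)
  expect_equal(fu_plasma(25, 500), 0.05)
  expect_warning(z <- fu_plasma(0, 500), "below quantification")
  expect_equal(z, 0)
  expect_warning(clipped <- fu_plasma(510, 500), "clipped")
  expect_equal(clipped, 1)
  expect_error(fu_plasma(25, 0), "positive")
})

test_that("homogenate fu applies the undiluted-tissue correction", {
  expect_equal(fu_brain_homogenate(1, 1, D = 10), 1)   # no binding
  expect_equal(fu_brain_homogenate(1, 1, D = 3), 1)
  expect_equal(fu_brain_homogenate(0.5, 1, D = 10), 0.1 / 1.1)  # 0.0909
  expect_equal(fu_brain_homogenate(0.3, 1, D = 1), 0.3)  # identity undiluted
  expect_error(fu_brain_homogenate(0, 1), "underflow|quantification")
  expect_error(fu_brain_homogenate(0.5, 0), "positive")
})

test_that("homogenate fu is monotone in fu_app and in dilution", {
  fu_apps <- seq(0.05, 0.95, by = 0.1)
  out <- vapply(fu_apps, fu_brain_homogenate, numeric(1), C_homog = 1, D = 10)
  expect_true(all(diff(out) > 0))

  dils <- c(1, 2, 5, 10, 20)
  out_d <- vapply(dils, function(D) fu_brain_homogenate(0.5, 1, D), numeric(1))
  expect_true(all(diff(out_d) < 0))  # stronger dilution, more correction
})

test_that("slice method computes Vu and fu with water-adhesion term", {
  # pre-multiplied input (D_slice = 1)
  r <- fu_brain_slice(1.106, C_ECF = 1, D_slice = 1)
  expect_equal(r$Vu_brain, 1.0)
  expect_equal(r$fu_brain, 1.0)

  r2 <- fu_brain_slice(2.106, C_ECF = 1, D_slice = 1)
  expect_equal(r2$Vu_brain, 2.0)
  expect_equal(r2$fu_brain, 0.5)

  # raw homogenate measurement, default 10x dilution
  r3 <- fu_brain_slice(0.21, C_ECF = 1)
  expect_equal(r3$Vu_brain, 2.1 - 0.106)
  expect_equal(r3$fu_brain, 1 / 1.994)  # 0.5015

  expect_error(fu_brain_slice(0.009, C_ECF = 1), "adherent water")
  expect_warning(high <- fu_brain_slice(0.5, C_ECF = 1, D_slice = 1),
                 "artifact")
  expect_gt(high$fu_brain, 1)
})

test_that("slice fu and Vu are exact reciprocals and dilution-consistent", {
  set.seed(33)
  for (i in 1:20) {
    raw <- runif(1, 0.05, 5)
    ecf <- runif(1, 0.2, 2)
    if (10 * raw / ecf <= 0.106) next
    r <- fu_brain_slice(raw, ecf)
    expect_equal(r$fu_brain * r$Vu_brain, 1, tolerance = 1e-15)
    pre <- fu_brain_slice(10 * raw, ecf, D_slice = 1)
    expect_equal(pre$Vu_brain, r$Vu_brain)
  }
})

test_that("unbound brain concentration is fu times total", {
  expect_equal(cu_brain_from_total(1, 5), 5)
  expect_equal(cu_brain_from_total(0, 12), 0)
  expect_equal(cu_brain_from_total(0.01, 12), 0.12)
  expect_error(cu_brain_from_total(-0.1, 12), ">=")
})
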