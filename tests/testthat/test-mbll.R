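test_that("optical density conversion follows the log-ratio definition", {
  rec <- make_recording(nch = 1, value = 5)
  od <- intensity_to_od(rec)
  expect_true(all(od$od == 0))              # constant channel: I = I0

  # one dimmed sample: dOD computed against the realized mean
  rec2 <- make_recording(nch = 1, value = 2)
  rec2$intensity[1, 1, 100] <- 0.2
  od2 <- intensity_to_od(rec2)
  i0 <- mean(rec2$intensity[1, 1, ])
  expect_equal(od2$od[1, 1, 100], -log10(0.2 / i0), tolerance = 1e-12)
  expect_equal(od2$od[1, 1, 5], -log10(2 / i0), tolerance = 1e-12)

  # scale invariance: doubling intensities leaves dOD unchanged
  rec3 <- rec2
  rec3$intensity <- rec3$intensity * 2
  expect_equal(intensity_to_od(rec3)$od, od2$od, tolerance = 1e-12)

  bad <- rec
  bad$intensity[1, 1, 3] <- 1e-12
  bad$intensity[1, 1, 3] <- 0
  expect_error(nirs_recording("x", 30, bad$intensity, bad$paradigm),
               "nonpositive")
})

test_that("DPF matches independent evaluation of the age-wavelength model", {
  cf <- dpf_coefficients()
  direct <- function(age, wl)
    223.3 + 0.05624 * age^0.8493 + (-5.723e-7) * wl^3 + 0.001245 * wl^2 +
      (-0.9025) * wl
  expect_equal(compute_dpf(30, 830, cf), direct(30, 830), tolerance = 1e-12)
  expect_equal(compute_dpf(30, 695, cf), direct(30, 695), tolerance = 1e-12)
  expect_equal(round(compute_dpf(30, 830, cf), 2), 5.68)
  expect_equal(round(compute_dpf(30, 695, cf), 2), 6.32)
  # age 0: the age term vanishes exactly
  expect_equal(compute_dpf(0, 830, cf),
               223.3 + (-5.723e-7) * 830^3 + 0.001245 * 830^2 - 0.9025 * 830,
               tolerance = 1e-12)
  # the misprinted cubic coefficient scale is rejected
  expect_error(compute_dpf(30, 830, dpf_coefficients(delta = -5.723e-3)),
               "delta")
})

test_that("DPF increases with age at fixed wavelength", {
  ages <- seq(0, 100, by = 5)
  for (wl in c(695, 830)) {
    d <- vapply(ages, compute_dpf, 0, wavelength = wl)
    expect_true(all(diff(d) > 0))
    expect_true(all(d > 0))
  }
})

test_that("MBLL forward-inverse is an identity and scales with distance", {
  set.seed(7)
  m <- default_montage()
  p <- vft_paradigm()
  n <- nirstreat:::paradigm_n_samples(p)
  hbo <- matrix(rnorm(3 * n, sd = 1e-6), 3, n,
                dimnames = list(c("C1", "C2", "C3"), NULL))
  hbr <- matrix(rnorm(3 * n, sd = 3e-7), 3, n, dimnames = dimnames(hbo))
  odarr <- nirstreat:::hemoglobin_to_od(hbo, hbr, age = 40, montage = m)
  od <- nirstreat:::new_od(odarr, list(subject_id = "x", age = 40,
                                       wavelengths = c(695, 830), paradigm = p))
  hb <- od_to_hemoglobin(od, m)
  expect_equal(hb$hbo, hbo, tolerance = 1e-10)
  expect_equal(hb$hbr, hbr, tolerance = 1e-10)

  # zero OD maps to zero concentrations
  od0 <- od; od0$od[] <- 0
  hb0 <- od_to_hemoglobin(od0, m)
  expect_true(all(hb0$hbo == 0) && all(hb0$hbr == 0))

  # doubling the source-detector distance halves the concentrations
  m2 <- m; m2$distance_cm <- 2 * m$distance_cm
  hb2 <- od_to_hemoglobin(od, m2)
  expect_equal(hb2$hbo, hbo / 2, tolerance = 1e-10)

  # singular extinction matrix is a configuration error
  expect_error(extinction_table(hbo = c(1, 2), hbr = c(2, 4)), "singular")
})
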