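test_that("Guinier fit recovers an exact Gaussian curve and the slope identity", {
  q <- default_qgrid(300)
  cv <- saxs_curve(q, 2.5 * exp(-(q * 41.1)^2 / 3))
  f <- suppressWarnings(guinier_fit(cv))
  expect_equal(f$Rg, 41.1, tolerance = 1e-8)
  expect_equal(f$I0, 2.5, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  # the printed pairing: gradient m = -563.07 A^2 corresponds to Rg = 41.1 A
  cv2 <- saxs_curve(q, exp(-563.07 * q^2))
  f2 <- suppressWarnings(guinier_fit(cv2))
  expect_equal(f2$slope_m, -563.07, tolerance = 1e-6)
  expect_equal(round(f2$Rg, 1), 41.1)

  # Rg^2 = -3 m holds to machine precision on noisy data too
  for (s in 1:5) {
    ds <- make_sphere_dataset(40, qgrid = default_qgrid(200),
                              noise = noise_model(seed = s))
    fs <- guinier_fit(ds$curve)
    expect_equal(fs$Rg^2, -3 * fs$slope_m, tolerance = 1e-12)
  }
})

test_that("Guinier fit fails cleanly without a decaying region", {
  q <- seq(0.01, 0.1, length.out = 30)
  rising <- saxs_curve(q, exp(+(q * 30)^2 / 3))
  expect_error(suppressWarnings(guinier_fit(rising)),
               class = "fs_no_guinier_region")
  few <- saxs_curve(q[1:5], exp(-(q[1:5] * 30)^2 / 3))
  expect_error(guinier_fit(few, window = c(0, 0.05)),
               class = "fs_insufficient_data")
})

test_that("automatic window selection uses the full low-q range on ideal data
          and excludes an aggregation upturn", {
  q <- default_qgrid(300)
  ideal <- saxs_curve(q, exp(-(q * 40)^2 / 3), sigma = 0.01 * exp(-(q * 40)^2 / 3))
  f <- auto_guinier_range(ideal)
  expect_equal(f$idx[1], 1L)                       # lowest q included
  expect_gt(f$window[2], 1.25)                     # window reaches ~1.3
  expect_lt(f$window[2], 1.3 + 1e-6)
  expect_equal(f$Rg, 40, tolerance = 1e-3)         # < 0.1% on noise-free input

  # splice a strong upturn onto the 3 lowest-q points (aggregation signature)
  I_up <- ideal$I
  I_up[1:3] <- I_up[1:3] * c(1.8, 1.5, 1.25)
  up <- saxs_curve(q, I_up, sigma = ideal$sigma)
  fu <- auto_guinier_range(up)
  expect_gte(fu$idx[1], 4L)
  expect_equal(fu$Rg, 40, tolerance = 5e-3)
})

test_that("dimensionless Kratky peaks at the globular reference point", {
  q <- default_qgrid(2000)
  cv <- saxs_curve(q, exp(-(q * 41.1)^2 / 3))
  f <- suppressWarnings(guinier_fit(cv))
  k <- dimensionless_kratky(cv, f)
  i <- which.max(k$y)
  expect_equal(k$x[i], sqrt(3), tolerance = 2e-3)
  expect_equal(k$y[i], 3 / exp(1), tolerance = 1e-4)
  expect_equal(unname(k$reference), c(sqrt(3), 3 / exp(1)))
  # the low-q limit vanishes quadratically
  expect_true(all(k$y[k$x < 0.1] < 0.01))

  # analytic sphere (Rg from a strict low-q fit, qRg <= 0.5, where the
  # Guinier regime is exact): the ideal hard sphere peaks slightly below the
  # globular reference point, at (1.6124, 1.0274) by numeric maximization of
  # the closed form
  R <- 50
  qs <- seq(0.001, 0.12, length.out = 4000)
  sp <- sphere_form_factor(R, qs)
  ks <- dimensionless_kratky(sp,
                             suppressWarnings(guinier_fit(sp, window = c(0, 0.5))))
  j <- which.max(ks$y)
  expect_equal(ks$x[j], 1.6124, tolerance = 0.01)
  expect_equal(ks$y[j], 1.0274, tolerance = 0.01)

  # invariance under intensity rescaling (refit on the scaled curve)
  cv10 <- saxs_curve(q, 10 * cv$I)
  k10 <- dimensionless_kratky(cv10, suppressWarnings(guinier_fit(cv10)))
  expect_equal(k10$y, k$y, tolerance = 1e-9)
})

test_that("per-frame Rg trace is constant for identical frames and groups thirds", {
  q <- default_qgrid(200)
  I <- exp(-(q * 40)^2 / 3)
  fr <- saxs_curve(q, I, sigma = 0.01 * I + 1e-6)
  ser <- saxs_series(rep(list(fr), 30))
  tr <- rg_evolution(ser)
  expect_true(all(tr$trace$ok))
  expect_equal(tr$groups$n, c(10, 10))
  expect_equal(tr$groups$sd, c(0, 0), tolerance = 1e-9)
  expect_equal(tr$groups$mean, c(40, 40), tolerance = 0.1)
})

test_that("an imposed Rg drift across frames is recovered by both window policies", {
  # cheap drift emulation with exact Guinier-model frames + noise
  q <- default_qgrid(200)
  rgs <- seq(42, 39, length.out = 30)
  frames <- lapply(seq_along(rgs), function(i) {
    ideal <- saxs_curve(q, exp(-(q * rgs[i])^2 / 3))
    simulate_noise(ideal, noise_model(a = 0.01, seed = 1000 + i))
  })
  ser <- saxs_series(frames)
  # thirds of a linear 42 -> 39 drift differ by 3 * 25/29/... = 2.07 A
  expected_diff <- mean(rgs[1:10]) - mean(rgs[21:30])
  for (pol in c("auto", "fixed")) {
    tr <- rg_evolution(ser, policy = pol)
    m <- setNames(tr$groups$mean, tr$groups$group)
    expect_gt(m["first_third"], m["last_third"])
    expect_equal(unname(m["first_third"] - m["last_third"]), expected_diff,
                 tolerance = 0.15)
  }
})
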