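test_that("Debye formula limits and closed forms", {
  q <- seq(0.01, 0.5, length.out = 40)
  one <- debye_profile(bead_model(matrix(0, 1, 3), f = 1), q)
  expect_equal(one$I, rep(1, 40))

  d <- 7.3
  two <- debye_profile(bead_model(rbind(c(0, 0, 0), c(d, 0, 0)), f = 1), q)
  expect_equal(two$I, 2 + 2 * sin(q * d) / (q * d), tolerance = 1e-12)

  expect_error(debye_profile(bead_model(matrix(0, 1, 3)), numeric(0)),
               class = "fs_argument_error")
})

test_that("Debye profile is rigid-motion invariant and scales as f^2", {
  set.seed(7)
  pos <- matrix(rnorm(30 * 3, sd = 10), ncol = 3)
  q <- seq(0.01, 0.4, length.out = 30)
  base <- debye_profile(bead_model(pos, f = 2), q)

  R <- flexscatter:::.rodrigues(c(1, 2, 3), 1.1)
  moved <- pos %*% t(R) + matrix(c(5, -3, 8), 30, 3, byrow = TRUE)
  expect_equal(debye_profile(bead_model(moved, f = 2), q)$I, base$I,
               tolerance = 1e-9)
  expect_equal(debye_profile(bead_model(pos, f = 6), q)$I, 9 * base$I,
               tolerance = 1e-9)
})

test_that("bead-filled sphere reproduces the analytic form factor", {
  R <- 50
  pts <- fill_sphere(2000, R, seed = 2)
  q <- seq(0.005, 5 / R, length.out = 60)
  db <- debye_profile(bead_model(pts, f = 1), q)
  ff <- sphere_form_factor(R, q)
  expect_lt(max(abs(db$I / db$I[1] - ff$I / ff$I[1])), 0.02)
})

test_that("sphere form factor has the textbook properties", {
  R <- 30
  q <- seq(1e-4, 0.3, length.out = 5000)
  ff <- sphere_form_factor(R, q)
  expect_equal(ff$I[1], 1, tolerance = 1e-5)
  # first zero at qR = 4.4934
  sgn <- diff(ff$I < 1e-10)
  first_zero <- q[which(ff$I == min(ff$I[q * R > 4 & q * R < 5]))]
  expect_equal(first_zero * R, 4.4934, tolerance = 0.01)
  # Guinier radius of the strictly low-q part (qRg <= 0.65, where the sphere
  # curvature error stays below 0.5%)
  g <- suppressWarnings(guinier_fit(ff, window = c(0, 0.65)))
  expect_equal(g$Rg, sqrt(3 / 5) * R, tolerance = 0.005)
})

test_that("Guinier fit of any Debye profile matches the coordinate Rg", {
  lay <- small_layout()
  for (s in c(3, 14)) {
    cf <- assemble_conformer(lay, seed = s)
    cv <- debye_profile(cf, default_qgrid(200, qmax = 0.2))
    g <- suppressWarnings(guinier_fit(cv, window = c(0, 0.5)))
    expect_equal(g$Rg, coords_metrics(cf)$Rg, tolerance = 0.01)
  }
})

test_that("chi-square fitting: closed-form scale/background and calibration", {
  q <- default_qgrid(300)
  I <- exp(-(q * 35)^2 / 3) + 0.2
  model <- saxs_curve(q, I)
  data_same <- saxs_curve(q, I, sigma = 0.01 * I)
  ft <- chi2_fit(model, data_same)
  expect_equal(ft$c, 1, tolerance = 1e-10)
  expect_equal(ft$chi2, 0, tolerance = 1e-12)
  expect_equal(ft$dof, ft$n_points - 1L)

  # scale 2 plus background 0.05, both recovered with background fitting
  data_b <- saxs_curve(q, 2 * I + 0.05, sigma = 0.01 * I)
  fb <- chi2_fit(model, data_b, fit_background = TRUE)
  expect_equal(fb$c, 2, tolerance = 1e-8)
  expect_equal(fb$b, 0.05, tolerance = 1e-8)
  expect_equal(fb$dof, fb$n_points - 2L)

  expect_error(chi2_fit(model, saxs_curve(q, I)),
               class = "fs_missing_sigma_error")
  flat <- saxs_curve(q, rep(1, length(q)))
  expect_error(chi2_fit(flat, data_same, fit_background = TRUE),
               class = "fs_rank_deficiency_error")

  # E[chi2] = 1 concentration across seeds (n = 200 points each)
  chis <- vapply(1:50, function(s) {
    noisy <- simulate_noise(saxs_curve(q[1:200], 2 * I[1:200]),
                            noise_model(a = 0.02, seed = s))
    chi2_fit(saxs_curve(q[1:200], I[1:200]), noisy)$chi2
  }, numeric(1))
  expect_lt(abs(mean(chis) - 1), 3 * sqrt(2 / 199) / sqrt(50) * 3)
  expect_equal(mean(chis), 1, tolerance = 0.05)
})

test_that("a wrong shape at matched Rg is rejected by chi-square", {
  q <- default_qgrid(500)
  rg <- 40
  chain <- gaussian_chain_form_factor(rg, q)
  noisy <- simulate_noise(chain, noise_model(a = 0.01, seed = 6))
  sphere <- sphere_form_factor(rg / sqrt(3 / 5), q)
  expect_gt(chi2_fit(sphere, noisy)$chi2, 2)
  expect_lt(chi2_fit(chain, noisy)$chi2, 1.2)
})

test_that("coordinate metrics: closed forms, invariance, and range selection", {
  two <- bead_model(rbind(c(0, 0, 0), c(6, 0, 0)), f = 1)
  m <- coords_metrics(two)
  expect_equal(m$Rg, 3)
  expect_equal(m$Dmax, 6)

  pts <- fill_sphere(10000, 50, seed = 9)
  ms <- coords_metrics(bead_model(pts, f = 1))
  expect_equal(ms$Rg, sqrt(3 / 5) * 50, tolerance = 0.5 / 38.7)

  R <- flexscatter:::.rodrigues(c(0, 0, 1), 0.7)
  moved <- bead_model(pts %*% t(R) + 10, f = 1)
  mm <- coords_metrics(moved)
  expect_equal(mm$Rg, ms$Rg, tolerance = 1e-9)
  expect_equal(mm$Dmax, ms$Dmax, tolerance = 1e-9)

  bm <- bead_model(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)),
                   f = 1, resno = 1:3)
  sel <- coords_metrics(bm, residue_range = c(2, 3))
  expect_equal(sel$Dmax, 10)
  expect_error(coords_metrics(bm, residue_range = c(5, 9)),
               class = "fs_argument_error")
})
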