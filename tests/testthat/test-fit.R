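test_that("the endpoint transform maps F0 to 0, Fmax to 1 and clips noise", {
  expect_equal(as.numeric(compute_P(43.0, 43.0, 76.2)), 0)
  expect_equal(as.numeric(compute_P(76.2, 43.0, 76.2)), 1)
  expect_equal(as.numeric(compute_P(59.6, 43.0, 76.2)), 0.5)
  # affine invariance under common rescaling
  for (s in c(0.3, 1, 12)) {
    expect_equal(as.numeric(compute_P(s * 60, s * 43, s * 76.2)),
                 as.numeric(compute_P(60, 43, 76.2)))
  }
  p <- compute_P(c(40, 50, 80), 43, 76.2)
  expect_identical(attr(p, "clipped"), c(TRUE, FALSE, TRUE))
  expect_equal(as.numeric(p), c(0, (50 - 43) / 33.2, 1))
  expect_error(compute_P(50, 76.2, 43), "Fmax > F0")
})

test_that("Gaussian size fitting works on samples and histograms", {
  r <- sample_radii(1e4, 100.6, 31.5, seed = 19)
  g <- fit_gaussian_radii(r)
  expect_lt(abs(g$r_bar - 100.6), 3 * g$r_bar_se)
  expect_lt(abs(g$sigma - 31.5), 3 * g$sigma_se)
  expect_equal(g$r_bar_se, g$sigma / sqrt(1e4))
  expect_equal(g$sigma_se, g$sigma / sqrt(2e4))
  expect_false(g$degenerate)
  # identical samples: degenerate flag, zero width
  g0 <- fit_gaussian_radii(rep(100, 50))
  expect_true(g0$degenerate)
  expect_identical(g0$sigma, 0)
  # histogram of exact Gaussian proportions recovers the parameters
  mids <- seq(5, 255, by = 10)
  counts <- round(1e5 * 10 * dnorm(mids, 100.6, 31.5))
  gh <- fit_gaussian_radii(histogram = data.frame(mid = mids, count = counts))
  expect_equal(gh$r_bar, 100.6, tolerance = 1e-3)
  expect_equal(gh$sigma, 31.5, tolerance = 1e-2)
  expect_error(fit_gaussian_radii(1:5), "at least 10")
  expect_error(fit_gaussian_radii(histogram = data.frame(mid = 1:3,
                                                         count = 1:3)),
               "5 non-empty")
})

test_that("occupancy fit recovers a noise-free generating constant", {
  a_true <- 8.96e-4
  pars <- occupancy_params(a_true, 100.8, 32.8)
  x <- seq(0.05, 2, length.out = 20)
  pts <- data.frame(ppr_star = x, P = prob_occupied_gaussian(x, pars))
  fit <- fit_occupancy_model(pts, r_bar = 100.8, sigma = 32.8)
  expect_equal(fit$alpha_hat, a_true, tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  # fixed-radius variant coincides on monodisperse data
  pts0 <- data.frame(ppr_star = x,
                     P = prob_occupied_fixed_radius(100.8, x, a_true))
  f_g <- fit_occupancy_model(pts0, r_bar = 100.8, sigma = 0)
  f_f <- fit_occupancy_model(pts0, r_bar = 100.8, sigma = 32.8,
                             variant = "fixed_radius")
  expect_equal(f_g$alpha_hat, f_f$alpha_hat, tolerance = 1e-8)
  expect_identical(f_f$model_variant, "fixed_radius")
})

test_that("occupancy fit guards identifiability and degenerate input", {
  x <- seq(0.05, 2, length.out = 10)
  expect_error(fit_occupancy_model(
    data.frame(ppr_star = rep(1, 5), P = rep(0.5, 5))), "distinct")
  expect_error(fit_occupancy_model(
    data.frame(ppr_star = x, P = rep(0, 10))), "zero")
  expect_error(fit_occupancy_model(
    data.frame(ppr_star = x, P = rep(0.05, 10))), "identifiable")
  # 'ppr' column is corrected internally
  pars <- occupancy_params(8.96e-4, 100.8, 32.8)
  pts <- data.frame(ppr = x * 0.524,
                    P = prob_occupied_gaussian(x, pars))
  fit <- fit_occupancy_model(pts, r_bar = 100.8, sigma = 32.8,
                             f_reconstitutable = 0.524)
  expect_equal(fit$alpha_hat, 8.96e-4, tolerance = 1e-6)
})

test_that("bootstrap and Jacobian standard errors agree within 2x", {
  ser <- generate_ppr_series(seq(0.05, 1.5, length.out = 20),
                             noise_sd = 0.02, seed = 23)
  fit <- fit_occupancy_model(ser, bootstrap = 200, seed = 24)
  expect_true(is.finite(fit$alpha_se_boot))
  ratio <- fit$alpha_se_boot / fit$alpha_se
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("mass derivation applies the exact delta method", {
  a <- 8.96e-4
  se <- 3.34e-5
  m <- alpha_to_mass(a, 0.70, alpha_se = se)
  expect_equal(m$M, 80142.67, tolerance = 1e-6)
  expect_equal(m$M_uncertainty, m$M * se / a)
  expect_equal(m$M_uncertainty, 2987.4, tolerance = 1e-3)
  expect_identical(alpha_to_mass(a, 0.70)$M_uncertainty, 0)
  expect_equal(alpha_to_mass(a / 2, 0.70)$M, 2 * m$M)
  # derive_mass agrees with direct conversion of the fitted constant
  ser <- generate_ppr_series(seq(0.05, 1.5, length.out = 20),
                             noise_sd = 0, seed = 1)
  fit <- fit_occupancy_model(ser)
  dm <- derive_mass(fit)
  expect_equal(dm$M, 16 * pi / (0.70 * fit$alpha_hat))
  expect_equal(dm$M, 80800, tolerance = 1e-5)
})

test_that("end-to-end mass recovery is unbiased with calibrated coverage", {
  M_true <- 80800
  masses <- numeric(50)
  covered <- logical(50)
  for (s in 1:50) {
    ser <- generate_ppr_series(seq(0.05, 1.5, length.out = 20),
                               M_true = M_true, noise_sd = 0.02, seed = 100 + s)
    fit <- fit_occupancy_model(ser)
    m <- derive_mass(fit)
    masses[s] <- m$M
    covered[s] <- abs(m$M - M_true) <= m$M_uncertainty
  }
  expect_lt(abs(mean(masses) - M_true) / M_true, 0.05)
  expect_gte(mean(covered), 0.6)
})
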