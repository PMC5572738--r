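test_that("radius sampling is seeded, positive and Gaussian", {
  expect_identical(sample_radii(1000, 100.6, 31.5, seed = 7),
                   sample_radii(1000, 100.6, 31.5, seed = 7))
  expect_identical(sample_radii(5, 100, 0, seed = 1), rep(100, 5))
  r <- sample_radii(1e5, 100.6, 31.5, seed = 11)
  expect_true(all(r > 0))
  # CLT bound on the sample mean (truncation bias is far below this)
  expect_lt(abs(mean(r) - 100.6), 3 * 31.5 / sqrt(1e5))
})

test_that("scramblase assignment reproduces the closed-form occupancy", {
  radii <- sample_radii(2e4, 100.8, 32.8, seed = 3)
  # no protein, no scramblases
  pop0 <- assign_scramblases(radii, ppr = 0, M = 80800, seed = 4)
  expect_true(all(pop0$scramblase_count == 0))
  # fully reconstitutable pool: occupied fraction matches the model
  pop <- assign_scramblases(radii, ppr = 0.5, M = 80800,
                            f_reconstitutable = 1, seed = 4)
  p_th <- prob_occupied_gaussian(
    0.5, occupancy_params(mass_to_alpha(80800), 100.8, 32.8, 1))
  se <- sqrt(p_th * (1 - p_th) / length(radii))
  expect_lt(abs(mean(pop$scramblase_count >= 1) - p_th), 3 * se)
  # refractory pool: occupied fraction converges to f * P(ppr/f)
  popf <- assign_scramblases(radii, ppr = 0.3, M = 80800,
                             f_reconstitutable = 0.524, seed = 5)
  expect_true(all(popf$scramblase_count[popf$refractory] == 0))
  p_pop <- 0.524 * prob_occupied_gaussian(
    0.3 / 0.524, occupancy_params(mass_to_alpha(80800), 100.8, 32.8))
  se2 <- sqrt(p_pop * (1 - p_pop) / length(radii))
  expect_lt(abs(mean(popf$scramblase_count >= 1) - p_pop), 3 * se2)
  # Poisson mean conservation over the non-refractory pool
  lam <- expected_scramblases(radii, 0.3 / 0.524, mass_to_alpha(80800))
  mu <- sum(lam[!popf$refractory])
  expect_lt(abs(sum(popf$scramblase_count) - mu), 3 * sqrt(mu))
})

test_that("ideal dithionite traces hit the analytic endpoints", {
  t_grid <- seq(-30, 400, by = 0.5)
  # scramblase-free, ideal symmetric labelling: exactly half is protected
  tr0 <- simulate_dithionite_trace(
    uniform_population(50, 0),
    dithionite_params(F0_target = 50, Fmax_target = 100, noise_sd = 0),
    t_grid)
  expect_equal(percent_reduction(tr0)$percent_reduction, 50, tolerance = 1e-6)
  # fully occupied, ideal: complete reduction as t -> Inf
  tr1 <- simulate_dithionite_trace(
    uniform_population(50, 1),
    dithionite_params(F0_target = 50, Fmax_target = 100, noise_sd = 0),
    t_grid)
  expect_equal(percent_reduction(tr1)$percent_reduction, 100, tolerance = 1e-4)
  # default non-ideality calibration reproduces the F0 target
  tr43 <- simulate_dithionite_trace(
    uniform_population(50, 0), dithionite_params(noise_sd = 0), t_grid)
  expect_equal(percent_reduction(tr43)$percent_reduction, 43.0,
               tolerance = 1e-4)
  expect_error(simulate_dithionite_trace(uniform_population(5, 0),
                                         t_add = 999), "t_add")
})

test_that("the protected pool never decays in scramblase-free vesicles", {
  # topological premise: inner-leaflet NBD of unoccupied vesicles is
  # never reduced, so noise-free fluorescence stays >= 100 - F0_target
  # and is non-increasing after addition
  for (F0 in c(40, 43, 50)) {
    tr <- simulate_dithionite_trace(
      uniform_population(20, 0),
      dithionite_params(F0_target = F0, Fmax_target = 80, noise_sd = 0))
    expect_true(all(tr$fluorescence >= 100 - F0 - 1e-9))
    expect_true(all(diff(tr$fluorescence) <= 1e-12))
  }
})

test_that("decay fitting recovers the generating rate from traces", {
  tr <- simulate_dithionite_trace(
    uniform_population(20, 0),
    dithionite_params(k_red = log(2) / 15.2, noise_sd = 0))
  fd <- fit_decay(tr)
  expect_equal(fd$t_half, 15.2, tolerance = 1e-3)
  tr2 <- simulate_dithionite_trace(
    uniform_population(20, 0),
    dithionite_params(k_red = 2 * log(2) / 15.2, noise_sd = 0))
  expect_equal(fit_decay(tr2)$t_half, 15.2 / 2, tolerance = 1e-3)
})

test_that("titration generator saturates between F0 and Fmax", {
  s0 <- generate_ppr_series(0, noise_sd = 0)
  expect_equal(s0$F, 43.0)
  shi <- generate_ppr_series(50, noise_sd = 0)
  expect_equal(shi$F, 76.2, tolerance = 1e-3)
  # noise-free series refits the generating constant
  ser <- generate_ppr_series(seq(0.05, 1.5, length.out = 20), noise_sd = 0)
  fit <- fit_occupancy_model(ser)
  a_true <- mass_to_alpha(80800)
  expect_equal(fit$alpha_hat, a_true, tolerance = 1e-6)
  expect_error(generate_ppr_series(1, F0 = 80, Fmax = 76.2), "F0")
})

test_that("DLS simulation bins conserve counts and refit their generator", {
  d <- simulate_dls(1e4, 100.6, 31.5, seed = 7)
  expect_identical(sum(d$histogram$count), 10000L)
  expect_true(all(d$radii > 0))
  g <- fit_gaussian_radii(d$radii)
  expect_lt(abs(g$r_bar - 100.6), 3 * 31.5 / sqrt(1e4))
  expect_lt(abs(g$sigma - 31.5), 3 * 31.5 / sqrt(2e4))
  # degenerate width puts the whole sample in one bin
  d0 <- simulate_dls(100, 100, 0, seed = 1)
  expect_identical(sum(d0$histogram$count > 0), 1L)
})

test_that("pyranine traces follow the light-driven relaxation model", {
  # no pumping: pH pinned at the initial value
  sim0 <- simulate_pyranine_trace(pump_assay_params(k_pump = 0),
                                  noise_sd = 0)
  expect_true(all(sim0$pH == 7.57))
  # presets reach the reference endpoints at 20 min
  targets <- c(no_protein = 7.57, BR = 6.90, BR_valinomycin = 6.45)
  for (nm in names(targets)) {
    sim <- simulate_pyranine_trace(pyranine_presets()[[nm]], noise_sd = 0)
    got <- trace_to_pH(sim$trace)$pH_at_report
    expect_equal(got, targets[[nm]], tolerance = 5e-3)
  }
  # fluorescence round trip recovers the true pH series
  sim <- simulate_pyranine_trace(pyranine_presets()$BR, noise_sd = 0.5,
                                 seed = 9)
  back <- trace_to_pH(sim$trace)
  expect_lt(max(abs(back$pH - sim$pH)), 5 * 0.5 / 150)
  # pH held constant outside the light window
  p <- pump_assay_params(light_schedule = list(c(100, 600)))
  simw <- simulate_pyranine_trace(p, noise_sd = 0)
  held <- simw$pH[simw$trace$time <= 100]
  expect_true(all(held == 7.57))
  tail_pH <- simw$pH[simw$trace$time >= 600]
  expect_equal(max(tail_pH) - min(tail_pH), 0)
})
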