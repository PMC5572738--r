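#' Sample vesicle radii from a Gaussian size distribution
#'
#' Draws radii from Normal(`r_bar`, `sigma`), resampling any non-positive
#' draws so all radii are physical. With the default parameters of extruded
#' POPC/POPG liposomes (r_bar ~ 100 nm, sigma ~ 32 nm) the truncation is
#' a < 0.2% effect.
#'
#' @param n Number of vesicles, >= 1.
#' @param r_bar Mean radius (nm), > 0.
#' @param sigma Radius standard deviation (nm), >= 0.
#' @param seed Integer seed; identical seeds give identical samples. NULL
#'   uses (and advances) the current RNG state.
#' @return Numeric vector of `n` positive radii (nm).
#' @export
sample_radii <- function(n, r_bar = 100.8, sigma = 32.8, seed = NULL) {
  stopifnot(is.numeric(n), n >= 1, is.numeric(r_bar), is.numeric(sigma))
  if (r_bar <= 0) stop("r_bar must be > 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    r <- stats::rnorm(n, r_bar, sigma)
    bad <- which(r <= 0)
    while (length(bad) > 0) {
      r[bad] <- stats::rnorm(length(bad), r_bar, sigma)
      bad <- bad[r[bad] <= 0]
    }
    r
  })
}

#' Assign scramblase units to a vesicle population
#'
#' Reconstitution is modelled in two stages: each vesicle is refractory to
#' protein insertion with probability `1 - f_reconstitutable` (it receives
#' no protein regardless of the amount offered); the remaining vesicles
#' receive Poisson(\eqn{\lambda(r)}) functional units with
#' \eqn{\lambda(r) = (\alpha/2)\,PPR^*\,r^2}, \eqn{\alpha = 16\pi/(A\,M)}
#' and \eqn{PPR^* = PPR / f}. As the population grows, the fraction of
#' occupied vesicles converges to
#' `f * prob_occupied_gaussian(ppr/f, ...)`.
#'
#' @param radii Vesicle radii (nm), e.g. from [sample_radii()].
#' @param ppr Measured protein-to-phospholipid ratio (g/mol), >= 0.
#' @param M Molar mass of the functional scramblase unit (g/mol).
#' @param area_per_lipid Area per phospholipid (nm^2).
#' @param f_reconstitutable Reconstitutable vesicle fraction in (0, 1].
#' @param bilayer_thickness Bilayer thickness (nm) used for per-vesicle
#'   lipid counts.
#' @param seed Integer seed for reproducibility.
#' @return A `vesicle_population`: data frame with columns `radius` (nm),
#'   `scramblase_count`, `refractory` (logical) and `lipid_count`.
#' @export
assign_scramblases <- function(radii, ppr, M, area_per_lipid = 0.70,
                               f_reconstitutable = 0.524,
                               bilayer_thickness = 4.0, seed = NULL) {
  stopifnot(is.numeric(radii), length(radii) >= 1, all(radii > 0))
  if (ppr < 0) stop("ppr must be >= 0", call. = FALSE)
  if (M <= 0) stop("M must be > 0", call. = FALSE)
  alpha <- mass_to_alpha(M, area_per_lipid)
  ppr_star <- apply_ppr_correction(ppr, f_reconstitutable)
  n <- length(radii)
  with_seed(seed, {
    refractory <- stats::runif(n) > f_reconstitutable
    lambda <- expected_scramblases(radii, ppr_star, alpha)
    counts <- integer(n)
    idx <- which(!refractory)
    if (ppr > 0 && length(idx) > 0) {
      counts[idx] <- stats::rpois(length(idx), lambda[idx])
    }
    # inner-leaflet radius clamped at 0 so rare tail draws below the
    # bilayer thickness still get a positive lipid count
    r_in <- pmax(radii - bilayer_thickness, 0)
    lipids <- pmax(round(4 * pi * (radii^2 + r_in^2) / area_per_lipid), 1)
    structure(
      data.frame(radius = radii, scramblase_count = counts,
                 refractory = refractory, lipid_count = lipids),
      class = c("vesicle_population", "data.frame")
    )
  })
}

#' Dithionite assay simulation parameters
#'
#' @param k_red First-order rate constant of NBD reduction by dithionite
#'   (s^-1). The default 0.0456 s^-1 corresponds to a reduction half-life
#'   of ~15.2 s.
#' @param outer_fraction_ideal Ideal fraction of reporter lipid facing the
#'   outer leaflet (0.5 for symmetric incorporation).
#' @param F0_target Endpoint percent reduction of a scramblase-free vesicle
#'   (% of its signal). Default 43.0, the observed protein-free endpoint.
#' @param Fmax_target Endpoint percent reduction of a scramblase-occupied
#'   vesicle. Default 76.2, the observed saturating endpoint.
#' @param noise_sd Additive Gaussian noise sd, in percent of the initial
#'   (normalized 100%) signal. Default 0.5.
#' @param baseline_drift Fractional signal loss per second (photobleaching
#'   proxy). Default 0.
#' @return An object of class `dithionite_params`.
#' @export
dithionite_params <- function(k_red = log(2) / 15.2,
                              outer_fraction_ideal = 0.5,
                              F0_target = 43.0, Fmax_target = 76.2,
                              noise_sd = 0.5, baseline_drift = 0) {
  if (k_red <= 0) stop("k_red must be > 0", call. = FALSE)
  if (outer_fraction_ideal <= 0 || outer_fraction_ideal >= 1) {
    stop("outer_fraction_ideal must lie in (0, 1)", call. = FALSE)
  }
  if (F0_target < 0 || F0_target > Fmax_target || Fmax_target > 100) {
    stop("need 0 <= F0_target <= Fmax_target <= 100", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(k_red = k_red, outer_fraction_ideal = outer_fraction_ideal,
                 F0_target = F0_target, Fmax_target = Fmax_target,
                 noise_sd = noise_sd, baseline_drift = baseline_drift),
            class = "dithionite_params")
}

#' Simulate a dithionite scramblase-assay fluorescence trace
#'
#' Fluorescence is normalized to 100% before dithionite addition. After
#' addition each vesicle's reducible NBD pool decays as
#' \eqn{e^{-k_{red}(t - t_{add})}}. The reducible pool is the outer leaflet
#' only (50% ideally) for vesicles without a scramblase, and the whole pool
#' for vesicles carrying at least one scramblase, each scaled so that the
#' endpoint reduction of a pure population matches `F0_target` /
#' `Fmax_target` respectively (the observed non-idealities; with ideal
#' targets 50/100 the simulation is exact leaflet accounting). The
#' protected (inner-leaflet) pool of scramblase-free vesicles never decays —
#' the topological premise of the assay. Per-vesicle contributions are
#' weighted by lipid count.
#'
#' @param pop A `vesicle_population` from [assign_scramblases()], or any
#'   data frame with columns `scramblase_count` and `lipid_count`.
#' @param params A [dithionite_params()] object.
#' @param t_grid Strictly increasing sampling times (s).
#' @param t_add Dithionite addition time, within `t_grid`'s range.
#' @param seed Integer seed for the measurement noise.
#' @return An [assay_trace()] with a `dithionite_addition` event;
#'   fluorescence in percent of the pre-addition signal.
#' @export
simulate_dithionite_trace <- function(pop, params = dithionite_params(),
                                      t_grid = seq(-30, 400, by = 0.5),
                                      t_add = 0, seed = NULL) {
  stopifnot(is.data.frame(pop), nrow(pop) >= 1,
            all(c("scramblase_count", "lipid_count") %in% names(pop)),
            inherits(params, "dithionite_params"))
  if (t_add < min(t_grid) || t_add > max(t_grid)) {
    stop("t_add must lie within the time grid", call. = FALSE)
  }
  w <- pop$lipid_count / sum(pop$lipid_count)
  occupied <- pop$scramblase_count >= 1
  # per-vesicle endpoint calibration: reducible fraction of each vesicle's
  # signal is its endpoint target
  reducible <- ifelse(occupied, params$Fmax_target, params$F0_target) / 100
  dt <- pmax(t_grid - t_add, 0)
  decay <- exp(-params$k_red * dt)          # surviving reducible fraction
  f_signal <- 100 * vapply(decay, function(d) {
    sum(w * (1 - reducible * (1 - d)))
  }, numeric(1))
  if (params$baseline_drift != 0) {
    f_signal <- f_signal * pmax(1 - params$baseline_drift * (t_grid - t_grid[1]), 0)
  }
  if (params$noise_sd > 0) {
    f_signal <- with_seed(seed,
      f_signal + stats::rnorm(length(t_grid), 0, params$noise_sd))
  }
  assay_trace(t_grid, pmax(f_signal, 0),
              events = data.frame(label = "dithionite_addition", time = t_add),
              meta = list(k_red = params$k_red))
}

#' Generate a synthetic protein-to-phospholipid titration
#'
#' For each PPR value, the occupancy probability is computed from the
#' Gaussian occupancy model at \eqn{PPR^* = PPR/f} with
#' \eqn{\alpha = 16\pi/(A\,M_{true})}, perturbed with additive Gaussian
#' noise (clipped to [0, 1]), and mapped to a percent fluorescence
#' reduction through the endpoint transform \eqn{F = F_0 + P (F_{max}-F_0)}.
#'
#' @param ppr_values Measured PPR values (g/mol), >= 0.
#' @param M_true Generating functional molar mass (g/mol). Default 80800.
#' @param r_bar,sigma Gaussian size-distribution parameters (nm).
#' @param f_reconstitutable Reconstitutable fraction in (0, 1].
#' @param F0,Fmax Endpoint anchors in percent reduction; `Fmax > F0`.
#' @param noise_sd Gaussian noise sd on the probability scale. Default 0.02.
#' @param area_per_lipid Area per phospholipid (nm^2).
#' @param seed Integer seed.
#' @return Data frame of `reconstitution_point`s with columns `ppr`,
#'   `ppr_star`, `P_true`, `P` (noisy, clipped), `F` (percent reduction).
#' @export
generate_ppr_series <- function(ppr_values, M_true = 80800,
                                r_bar = 100.8, sigma = 32.8,
                                f_reconstitutable = 0.524,
                                F0 = 43.0, Fmax = 76.2,
                                noise_sd = 0.02, area_per_lipid = 0.70,
                                seed = NULL) {
  stopifnot(is.numeric(ppr_values), length(ppr_values) >= 1)
  if (any(ppr_values < 0)) stop("ppr values must be >= 0", call. = FALSE)
  if (F0 >= Fmax) stop("need F0 < Fmax", call. = FALSE)
  alpha <- mass_to_alpha(M_true, area_per_lipid)
  pars <- occupancy_params(alpha, r_bar, sigma, f_reconstitutable,
                           area_per_lipid)
  ppr_star <- apply_ppr_correction(ppr_values, f_reconstitutable)
  P_true <- prob_occupied_gaussian(ppr_star, pars)
  P <- with_seed(seed, P_true + stats::rnorm(length(P_true), 0, noise_sd))
  P <- pmin(pmax(P, 0), 1)
  data.frame(ppr = ppr_values, ppr_star = ppr_star, P_true = P_true,
             P = P, F = F0 + P * (Fmax - F0))
}

#' Simulate a dynamic light scattering size measurement
#'
#' Draws a Gaussian radius sample (resampling non-positive draws) and bins
#' it into a histogram, emulating a DLS size distribution of an extruded
#' liposome preparation.
#'
#' @inheritParams sample_radii
#' @param bin_width Histogram bin width (nm), > 0. Default 10.
#' @return List with `radii` (nm), `histogram` (data frame: `lower`,
#'   `upper`, `mid`, `count`; counts sum to `n`) and `bin_width`.
#' @export
simulate_dls <- function(n, r_bar = 100.6, sigma = 31.5, seed = NULL,
                         bin_width = 10) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  radii <- sample_radii(n, r_bar, sigma, seed)
  breaks <- seq(0, (floor(max(radii) / bin_width) + 1) * bin_width,
                by = bin_width)
  h <- graphics::hist(radii, breaks = breaks, plot = FALSE)
  list(radii = radii,
       histogram = data.frame(lower = utils::head(h$breaks, -1),
                              upper = h$breaks[-1], mid = h$mids,
                              count = h$counts),
       bin_width = bin_width)
}

#' Proton-pumping assay parameters
#'
#' Parameters of the light-driven acidification model: during illumination
#' the intravesicular pH relaxes exponentially toward `pH_asymptote` at
#' rate `k_pump`; in the dark it is held (passive leak neglected over the
#' assay duration).
#'
#' @param pH_init Initial intravesicular pH, in [5, 9].
#' @param pH_asymptote Steady-state pH under continuous illumination.
#' @param k_pump Relaxation rate constant (s^-1), >= 0.
#' @param valinomycin Logical; TRUE marks the K+ -ionophore condition in
#'   which the dissipated membrane potential permits faster and deeper
#'   acidification (encoded parametrically via `k_pump`/`pH_asymptote`).
#' @param light_schedule List of `c(on, off)` illumination intervals (s).
#' @return An object of class `pump_assay_params`.
#' @seealso [pyranine_presets()] for conditions reproducing the reference
#'   endpoints.
#' @export
pump_assay_params <- function(pH_init = 7.57, pH_asymptote = 6.90,
                              k_pump = 0.005, valinomycin = FALSE,
                              light_schedule = list(c(0, 1200))) {
  if (pH_init < 5 || pH_init > 9 || pH_asymptote < 5 || pH_asymptote > 9) {
    stop("pH values must lie in [5, 9]", call. = FALSE)
  }
  if (k_pump < 0) stop("k_pump must be >= 0", call. = FALSE)
  stopifnot(is.list(light_schedule))
  structure(list(pH_init = pH_init, pH_asymptote = pH_asymptote,
                 k_pump = k_pump, valinomycin = valinomycin,
                 light_schedule = light_schedule),
            class = "pump_assay_params")
}

#' Preset proton-pumping conditions
#'
#' Three canonical conditions of the pyranine assay, parameterized so the
#' analytic pH trajectory reaches the reference pH at 20 min (1200 s) of
#' continuous illumination: protein-free liposomes (no acidification,
#' pH_20 ~ 7.57), proton-pump proteoliposomes (pH_20 ~ 6.90) and the same
#' with valinomycin (faster, deeper acidification, pH_20 ~ 6.45).
#'
#' @return Named list of [pump_assay_params()]: `no_protein`, `BR`,
#'   `BR_valinomycin`.
#' @export
pyranine_presets <- function() {
  list(
    no_protein = pump_assay_params(pH_init = 7.57, pH_asymptote = 7.57,
                                   k_pump = 0),
    BR = pump_assay_params(pH_init = 7.57, pH_asymptote = 6.90,
                           k_pump = 0.005),
    BR_valinomycin = pump_assay_params(pH_init = 7.57, pH_asymptote = 6.45,
                                       k_pump = 0.012, valinomycin = TRUE)
  )
}

#' Simulate a pyranine fluorescence trace under a light schedule
#'
#' Propagates the intravesicular pH through the piecewise relaxation model
#' of [pump_assay_params()] and maps it to fluorescence through a linear
#' pyranine calibration, adding Gaussian measurement noise. pH excursions
#' outside the calibration's valid range are recorded as a flag in the
#' trace metadata rather than an error.
#'
#' @param params A [pump_assay_params()] object.
#' @param calibration A `pyranine_calibration` (see
#'   [fit_pyranine_calibration()] / [default_pyranine_calibration()]).
#' @param t_grid Strictly increasing sampling times (s).
#' @param noise_sd Gaussian noise sd on fluorescence (a.u.). Default 0.5.
#' @param seed Integer seed.
#' @return List with `trace` (an [assay_trace()] with light_on/light_off
#'   events) and `pH` (the noise-free pH series).
#' @export
simulate_pyranine_trace <- function(params,
                                    calibration = default_pyranine_calibration(),
                                    t_grid = seq(0, 1260, by = 1),
                                    noise_sd = 0.5, seed = NULL) {
  stopifnot(inherits(params, "pump_assay_params"),
            inherits(calibration, "pyranine_calibration"))
  in_light <- function(t) {
    any(vapply(params$light_schedule,
               function(iv) t > iv[1] && t <= iv[2], logical(1)))
  }
  pH <- numeric(length(t_grid))
  pH[1] <- params$pH_init
  for (i in seq_along(t_grid)[-1]) {
    dt <- t_grid[i] - t_grid[i - 1]
    if (in_light(t_grid[i])) {
      pH[i] <- params$pH_asymptote +
        (pH[i - 1] - params$pH_asymptote) * exp(-params$k_pump * dt)
    } else {
      pH[i] <- pH[i - 1]
    }
  }
  out_of_range <- any(pH < calibration$valid_range[1] |
                      pH > calibration$valid_range[2])
  f <- calibration$intercept + calibration$slope * pH
  if (noise_sd > 0) {
    f <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  }
  ev <- do.call(rbind, lapply(params$light_schedule, function(iv) {
    data.frame(label = c("light_on", "light_off"),
               time = pmin(pmax(iv, min(t_grid)), max(t_grid)))
  }))
  list(trace = assay_trace(t_grid, f, events = ev,
                           meta = list(pH_out_of_calibration = out_of_range,
                                       valinomycin = params$valinomycin)),
       pH = pH)
}
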