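#' Default run configuration
#'
#' Bundles the defaults shared by the simulators and the fitting pipeline.
#' The configuration round-trips losslessly through JSON.
#'
#' @param seed Integer seed applied to every stochastic stage.
#' @param area_per_lipid,bilayer_thickness Vesicle geometry defaults (nm^2,
#'   nm).
#' @param F0,Fmax Endpoint anchors (percent reduction).
#' @param k_red Dithionite reduction rate constant (s^-1).
#' @param noise_sd Trace noise sd (percent of initial signal).
#' @param r_bar,sigma Gaussian size-distribution defaults (nm).
#' @param f_reconstitutable Reconstitutable vesicle fraction.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, area_per_lipid = 0.70,
                       bilayer_thickness = 4.0, F0 = 43.0, Fmax = 76.2,
                       k_red = log(2) / 15.2, noise_sd = 0.5,
                       r_bar = 100.8, sigma = 32.8,
                       f_reconstitutable = 0.524) {
  cfg <- list(seed = as.integer(seed), area_per_lipid = area_per_lipid,
              bilayer_thickness = bilayer_thickness, F0 = F0, Fmax = Fmax,
              k_red = k_red, noise_sd = noise_sd, r_bar = r_bar,
              sigma = sigma, f_reconstitutable = f_reconstitutable)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  # exercise the owning constructors so every default satisfies its
  # type's invariants
  vesicle_geometry(cfg$r_bar, cfg$area_per_lipid, cfg$bilayer_thickness)
  dithionite_params(cfg$k_red, 0.5, cfg$F0, cfg$Fmax, cfg$noise_sd)
  occupancy_params(1e-4, cfg$r_bar, cfg$sigma, cfg$f_reconstitutable,
                   cfg$area_per_lipid)
  invisible(cfg)
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Generate fixture files for one assay kind
#'
#' Writes deterministic CSV fixtures (plus a JSON manifest recording the
#' parameters, seed and package version) for one of the four simulated
#' experiment kinds.
#'
#' @param kind One of `"dithionite"`, `"dls"`, `"pump"`, `"ppr-series"`.
#' @param config A [run_config()].
#' @param out_dir Writable output directory (created if missing).
#' @param seed Overrides `config$seed` when given.
#' @param n Population / sample size (vesicles for dithionite, radii for
#'   dls).
#' @param ppr For `"dithionite"`: the PPR of the simulated reconstitution.
#'   For `"ppr-series"`: the vector of titration PPR values.
#' @return Invisibly, the paths written (named character vector).
#' @export
run_simulate <- function(kind = c("dithionite", "dls", "pump", "ppr-series"),
                         config = run_config(), out_dir = ".",
                         seed = NULL, n = 5000,
                         ppr = seq(0.05, 1.5, length.out = 20)) {
  kind <- match.arg(kind)
  validate_config(config)
  if (is.null(seed)) seed <- config$seed
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  if (kind == "dithionite") {
    radii <- sample_radii(n, config$r_bar, config$sigma, seed)
    pop <- assign_scramblases(radii, ppr = ppr[1], M = 80800,
                              area_per_lipid = config$area_per_lipid,
                              f_reconstitutable = config$f_reconstitutable,
                              bilayer_thickness = config$bilayer_thickness,
                              seed = seed + 1)
    tr <- simulate_dithionite_trace(
      pop, dithionite_params(config$k_red, 0.5, config$F0, config$Fmax,
                             config$noise_sd),
      seed = seed + 2)
    paths["trace"] <- file.path(out_dir, "dithionite_trace.csv")
    write_assay_trace(tr, paths["trace"])
  } else if (kind == "dls") {
    dls <- simulate_dls(n, config$r_bar, config$sigma, seed)
    paths["dls"] <- file.path(out_dir, "dls_radii.csv")
    write_dls(dls$radii, paths["dls"])
  } else if (kind == "pump") {
    for (preset in names(pyranine_presets())) {
      sim <- simulate_pyranine_trace(pyranine_presets()[[preset]],
                                     seed = seed)
      paths[preset] <- file.path(out_dir,
                                 sprintf("pyranine_%s.csv", preset))
      write_assay_trace(sim$trace, paths[preset])
    }
  } else { # ppr-series
    if (length(ppr) == 0) {
      stop("ppr-series needs at least one PPR value", call. = FALSE)
    }
    ser <- generate_ppr_series(ppr, r_bar = config$r_bar,
                               sigma = config$sigma,
                               f_reconstitutable = config$f_reconstitutable,
                               F0 = config$F0, Fmax = config$Fmax,
                               area_per_lipid = config$area_per_lipid,
                               seed = seed)
    paths["titration"] <- file.path(out_dir, "titration.csv")
    write_titration(ser, paths["titration"])
  }
  manifest <- list(kind = kind, seed = seed, n = n, ppr = ppr,
                   config = unclass(config),
                   package_version =
                     as.character(utils::packageVersion("scramblr")),
                   files = as.list(paths))
  mpath <- file.path(out_dir, sprintf("manifest_%s.json",
                                      gsub("-", "_", kind)))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  paths["manifest"] <- mpath
  invisible(paths)
}

#' Run the full titration-analysis pipeline
#'
#' Orchestrates the inverse problem end to end: fit the Gaussian size
#' distribution to DLS radii, transform the titration endpoints to
#' occupancy probabilities, fit the occupancy constant, and derive the
#' functional molar mass.
#'
#' @param titration_csv Path to a titration CSV (`ppr_g_per_mol`,
#'   `reduction_pct`).
#' @param dls_csv Optional path to a DLS CSV (`radius_nm`); when NULL the
#'   configured `r_bar`/`sigma` are used directly.
#' @param config A [run_config()].
#' @param out Optional path for the JSON report.
#' @param verbose Print one line per stage with record counts.
#' @return The report as a list: `size_fit`, `points` (with P per point),
#'   `fit` (alpha and SE), `mass`, and the applied `config`.
#' @export
run_full_pipeline <- function(titration_csv, dls_csv = NULL,
                              config = run_config(), out = NULL,
                              verbose = TRUE) {
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  size_fit <- if (!is.null(dls_csv)) {
    radii <- stage("dls", read_dls(dls_csv))
    say("dls: read %d radii", length(radii))
    stage("size_fit", fit_gaussian_radii(samples = radii))
  } else NULL
  r_bar <- if (!is.null(size_fit)) size_fit$r_bar else config$r_bar
  sigma <- if (!is.null(size_fit)) size_fit$sigma else config$sigma
  say("size: r_bar = %.1f nm, sigma = %.1f nm", r_bar, sigma)

  tit <- stage("titration", read_titration(titration_csv))
  say("titration: read %d points", nrow(tit))
  P <- stage("transform", compute_P(tit$F, config$F0, config$Fmax))
  points <- data.frame(
    ppr = tit$ppr,
    ppr_star = apply_ppr_correction(tit$ppr, config$f_reconstitutable),
    F = tit$F, P = as.numeric(P), clipped = attr(P, "clipped"))
  fit <- stage("fit", fit_occupancy_model(
    points, r_bar = r_bar, sigma = sigma,
    f_reconstitutable = config$f_reconstitutable,
    area_per_lipid = config$area_per_lipid))
  mass <- derive_mass(fit)
  say("fit: alpha = %.3e +/- %.2e -> M = %.0f +/- %.0f g/mol",
      fit$alpha_hat, fit$alpha_se, mass$M, mass$M_uncertainty)
  report <- list(
    size_fit = if (!is.null(size_fit)) {
      list(r_bar = size_fit$r_bar, sigma = size_fit$sigma,
           r_bar_se = size_fit$r_bar_se, sigma_se = size_fit$sigma_se,
           n = size_fit$n)
    } else NULL,
    points = points,
    fit = list(alpha_hat = fit$alpha_hat, alpha_se = fit$alpha_se,
               model_variant = fit$model_variant,
               n_points = fit$n_points,
               residual_rms = sqrt(mean(fit$residuals^2))),
    mass = list(M = mass$M, M_uncertainty = mass$M_uncertainty),
    config = unclass(config))
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  report
}
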