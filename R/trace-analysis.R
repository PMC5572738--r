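#' Percent fluorescence reduction of a dithionite trace
#'
#' Compares the mean fluorescence in a pre-addition baseline window with a
#' post-addition plateau window:
#' \deqn{\%reduction = 100\,(1 - \bar F_{plateau} / \bar F_{baseline}).}
#' Protein-free liposomes give ~50% (outer leaflet only); scramblase-
#' containing vesicles give more. The result is invariant under
#' multiplicative rescaling of the trace.
#'
#' @param trace An [assay_trace()] carrying a `dithionite_addition` event.
#' @param baseline_window Length-2 numeric `c(from, to)` in seconds;
#'   default the 30 s preceding the addition.
#' @param plateau_window Length-2 numeric; default 300-400 s after the
#'   addition.
#' @param slope_tol Maximum tolerated |plateau slope| in percent of
#'   baseline per second before the result is flagged as not converged.
#'   Default 0.02.
#' @return A `reduction_result` list: `percent_reduction`,
#'   `baseline_mean`, `plateau_mean`, `plateau_slope`, `converged`, and
#'   the windows used.
#' @export
percent_reduction <- function(trace, baseline_window = NULL,
                              plateau_window = NULL, slope_tol = 0.02) {
  stopifnot(inherits(trace, "assay_trace"))
  t_add <- event_time(trace, "dithionite_addition")
  if (is.null(baseline_window)) baseline_window <- c(t_add - 30, t_add)
  if (is.null(plateau_window)) plateau_window <- c(t_add + 300, t_add + 400)
  if (baseline_window[2] > t_add) {
    baseline_window[2] <- t_add
  }
  in_win <- function(w) trace$time >= w[1] & trace$time <= w[2]
  ib <- in_win(baseline_window)
  ip <- in_win(plateau_window)
  if (!any(ib)) stop("baseline window contains no samples", call. = FALSE)
  if (!any(ip)) stop("plateau window contains no samples", call. = FALSE)
  b <- mean(trace$fluorescence[ib])
  p <- mean(trace$fluorescence[ip])
  if (b <= 0) stop("non-positive baseline fluorescence", call. = FALSE)
  slope <- if (sum(ip) >= 3) {
    stats::coef(stats::lm(trace$fluorescence[ip] ~ trace$time[ip]))[[2]] / b * 100
  } else 0
  structure(list(percent_reduction = 100 * (1 - p / b),
                 baseline_mean = b, plateau_mean = p,
                 plateau_slope = slope,
                 converged = abs(slope) <= slope_tol,
                 baseline_window = baseline_window,
                 plateau_window = plateau_window),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("Fluorescence reduction: %.1f%%%s\n", x$percent_reduction,
              if (x$converged) "" else " [plateau not converged]"))
  invisible(x)
}

#' Fit a single-exponential decay to the post-addition fluorescence
#'
#' Least-squares fit of \eqn{F(t) = F_\infty + \Delta F\,
#' e^{-k_{red}(t - t_{add})}} to all samples after dithionite addition,
#' via Levenberg-Marquardt. The half-life is \eqn{t_{1/2} = \ln 2/k_{red}};
#' its observed value (~15 s for dithionite on NBD-PC liposomes) bounds the
#' scramblase rate from below because scrambling outpaces reduction.
#'
#' @param trace An [assay_trace()].
#' @param t_add Addition time (s); defaults to the trace's
#'   `dithionite_addition` event.
#' @return List with `k_red` (s^-1), `t_half` (s), `F_plateau`, `dF`,
#'   `residual_rms` and the underlying `fit` object.
#' @export
fit_decay <- function(trace, t_add = NULL) {
  stopifnot(inherits(trace, "assay_trace"))
  if (is.null(t_add)) t_add <- event_time(trace, "dithionite_addition")
  sel <- trace$time >= t_add
  if (sum(sel) < 10) {
    stop("need at least 10 samples after the addition", call. = FALSE)
  }
  tt <- trace$time[sel] - t_add
  ff <- trace$fluorescence[sel]
  # initialization: plateau from the tail, rate from a log-linear fit
  fp0 <- mean(ff[tt >= stats::quantile(tt, 0.8)])
  df0 <- ff[1] - fp0
  if (df0 <= 0) df0 <- max(ff) - min(ff) + 1e-9
  pos <- which(ff - fp0 > 0.01 * abs(df0))
  k0 <- if (length(pos) >= 3) {
    max(1e-6, -stats::coef(stats::lm(log(ff[pos] - fp0) ~ tt[pos]))[[2]])
  } else 0.05
  fit <- tryCatch(
    minpack.lm::nlsLM(ff ~ fp + df * exp(-k * tt),
                      start = list(fp = fp0, df = df0, k = k0),
                      lower = c(-Inf, 0, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf(
        "exponential fit failed (%s); starts: fp=%.3g df=%.3g k=%.3g",
        conditionMessage(e), fp0, df0, k0), call. = FALSE)
    })
  cf <- stats::coef(fit)
  list(k_red = cf[["k"]], t_half = log(2) / cf[["k"]],
       F_plateau = cf[["fp"]], dF = cf[["df"]],
       residual_rms = sqrt(mean(stats::resid(fit)^2)), fit = fit)
}

#' Lower bound on the scrambling rate per functional unit
#'
#' Because fluorescence loss in scramblase-occupied vesicles proceeds at
#' the dithionite-limited rate, scrambling must supply inner-leaflet lipids
#' at least as fast as the whole pool is reduced:
#' \deqn{rate > (\ln 2 / t_{1/2})\, N_{lipids}.}
#' With a 15.2 s half-life and 3.5e5 lipids per vesicle this exceeds
#' 1e4 lipids per second.
#'
#' @param t_half Reduction half-life (s), > 0.
#' @param n_lipids_per_vesicle Phospholipids per vesicle, >= 1.
#' @return Lower bound on the scrambling rate (lipids s^-1 per unit).
#' @export
scrambling_rate_lower_bound <- function(t_half, n_lipids_per_vesicle) {
  stopifnot(is.numeric(t_half), is.numeric(n_lipids_per_vesicle))
  if (any(t_half <= 0)) stop("t_half must be > 0", call. = FALSE)
  if (any(n_lipids_per_vesicle < 1)) {
    stop("n_lipids_per_vesicle must be >= 1", call. = FALSE)
  }
  (log(2) / t_half) * n_lipids_per_vesicle
}

#' Fit a linear pyranine fluorescence-pH calibration
#'
#' Pyranine fluorescence is linear in pH over the working range of the
#' proton-pumping assay; an ordinary least-squares line maps between them.
#'
#' @param pH Calibration pH values (>= 3 points spanning >= 0.5 pH units).
#' @param fluorescence Matching fluorescence readings (a.u.).
#' @return A `pyranine_calibration`: `slope` (a.u. per pH), `intercept`
#'   (a.u.), `valid_range` (pH), `r_squared`.
#' @export
fit_pyranine_calibration <- function(pH, fluorescence) {
  stopifnot(is.numeric(pH), is.numeric(fluorescence),
            length(pH) == length(fluorescence))
  if (length(pH) < 3) stop("need at least 3 calibration points", call. = FALSE)
  if (diff(range(pH)) < 0.5) {
    stop("calibration points must span at least 0.5 pH units", call. = FALSE)
  }
  fit <- stats::lm(fluorescence ~ pH)
  pyranine_calibration(stats::coef(fit)[[2]], stats::coef(fit)[[1]],
                       valid_range = range(pH),
                       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' @rdname fit_pyranine_calibration
#' @param slope,intercept Line parameters (slope != 0).
#' @param valid_range Ordered pH range over which the line was calibrated.
#' @param r_squared Coefficient of determination of the calibration fit.
#' @export
pyranine_calibration <- function(slope, intercept, valid_range = c(6, 8),
                                 r_squared = NA_real_) {
  if (slope == 0) stop("slope must be non-zero", call. = FALSE)
  if (valid_range[1] >= valid_range[2]) {
    stop("valid_range must be ordered", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 valid_range = valid_range, r_squared = r_squared),
            class = "pyranine_calibration")
}

#' @rdname fit_pyranine_calibration
#' @details `default_pyranine_calibration()` returns the calibration used
#'   by the simulator presets: 150 a.u. per pH unit, valid over pH 6-8.
#' @export
default_pyranine_calibration <- function() {
  pyranine_calibration(slope = 150, intercept = -700,
                       valid_range = c(6, 8), r_squared = 1)
}

#' Convert a pyranine fluorescence trace to intravesicular pH
#'
#' Inverts the linear calibration, \eqn{pH(t) = (F(t) - b)/m}, and reports
#' the pH at a fixed time point (by convention 20 min after the start of
#' illumination, "pH_20"), looked up at the nearest sample.
#'
#' @param trace An [assay_trace()] of pyranine fluorescence.
#' @param cal A `pyranine_calibration`.
#' @param t_report Report time in seconds (default 1200 = 20 min); must lie
#'   within the trace.
#' @return List with `pH` (series), `pH_at_report`, `t_report`, and
#'   `out_of_range` (TRUE if any converted pH leaves the calibrated range).
#' @export
trace_to_pH <- function(trace, cal = default_pyranine_calibration(),
                        t_report = 1200) {
  stopifnot(inherits(trace, "assay_trace"),
            inherits(cal, "pyranine_calibration"))
  if (t_report < min(trace$time) || t_report > max(trace$time)) {
    stop("t_report lies outside the trace", call. = FALSE)
  }
  pH <- (trace$fluorescence - cal$intercept) / cal$slope
  oor <- any(pH < cal$valid_range[1] | pH > cal$valid_range[2])
  if (oor) {
    warning("converted pH leaves the calibrated range", call. = FALSE)
  }
  i <- which.min(abs(trace$time - t_report))
  list(pH = pH, pH_at_report = pH[i], t_report = t_report,
       out_of_range = oor)
}

#' Summarize an absorbance spectrum of a purified retinal protein
#'
#' The 560 nm absorbance reports the folded, retinal-bound chromoprotein
#' and the 280 nm absorbance total protein; their ratio against the ratio
#' expected for a pure preparation gives a spectroscopic purity estimate.
#' Concentration uses Beer-Lambert at 560 nm with a 1 cm path.
#'
#' @param A560,A280 Peak absorbances (A280 > 0, A560 >= 0).
#' @param pure_ratio A560/A280 ratio of a pure reference preparation.
#'   Default 0.5 (this convention reproduces the customary 98% figure for
#'   A560/A280 = 0.6/1.22; the extinction-coefficient ratio 54/66 is an
#'   alternative, see the methods vignette).
#' @param epsilon_560,epsilon_280 Molar extinction coefficients
#'   (M^-1 cm^-1).
#' @return A `spectrum_summary`: absorbances, `purity` in [0, 1],
#'   `concentration` (mol/L) and the extinction coefficients.
#' @examples
#' estimate_purity(0.6, 1.22)$purity  # ~0.98
#' @export
estimate_purity <- function(A560, A280, pure_ratio = 0.5,
                            epsilon_560 = 54000, epsilon_280 = 66000) {
  stopifnot(is.numeric(A560), is.numeric(A280))
  if (A280 <= 0) stop("A280 must be > 0", call. = FALSE)
  if (A560 < 0) stop("A560 must be >= 0", call. = FALSE)
  if (pure_ratio <= 0) stop("pure_ratio must be > 0", call. = FALSE)
  structure(list(A560 = A560, A280 = A280,
                 purity = min(1, (A560 / A280) / pure_ratio),
                 concentration = A560 / epsilon_560,
                 epsilon_560 = epsilon_560, epsilon_280 = epsilon_280,
                 pure_ratio = pure_ratio),
            class = "spectrum_summary")
}
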