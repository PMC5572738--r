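#' Convert percent fluorescence reduction to occupancy probability
#'
#' The endpoint transform
#' \deqn{P(\ge 1\,scramblase) = (F - F_0)/(F_{max} - F_0)}
#' anchors the titration between the protein-free endpoint \eqn{F_0} and
#' the saturating endpoint \eqn{F_{max}}. Values falling outside [0, 1]
#' from measurement noise are clipped and flagged via the `"clipped"`
#' attribute; P is invariant under a common positive rescaling of
#' (F, F0, Fmax).
#'
#' @param F Percent fluorescence reduction at a given PPR.
#' @param F0 Protein-free endpoint (percent). Default 43.0.
#' @param Fmax Saturating endpoint (percent), > `F0`. Default 76.2.
#' @return Numeric probabilities in [0, 1] with a logical `"clipped"`
#'   attribute. Vectorized over `F`.
#' @examples
#' compute_P(59.6, 43.0, 76.2)  # 0.5
#' @export
compute_P <- function(F, F0 = 43.0, Fmax = 76.2) {
  stopifnot(is.numeric(F), is.numeric(F0), is.numeric(Fmax))
  if (Fmax <= F0) stop("need Fmax > F0", call. = FALSE)
  P <- (F - F0) / (Fmax - F0)
  clipped <- P < 0 | P > 1
  P <- pmin(pmax(P, 0), 1)
  attr(P, "clipped") <- clipped
  P
}

#' Fit a Gaussian to vesicle radius data
#'
#' Raw samples are fitted by maximum likelihood (sample mean and standard
#' deviation, with standard errors \eqn{\sigma/\sqrt{n}} and
#' \eqn{\sigma/\sqrt{2n}}); histograms by weighted least squares of a
#' scaled Gaussian density to the bin counts.
#'
#' @param samples Numeric radius samples (nm); >= 10 required.
#' @param histogram Data frame with columns `mid` and `count`
#'   (>= 5 non-empty bins); used when `samples` is NULL.
#' @return A `gaussian_size_fit`: `r_bar`, `sigma`, `r_bar_se`, `sigma_se`,
#'   `n`, `method`, and `degenerate` (TRUE when all samples coincide).
#' @export
fit_gaussian_radii <- function(samples = NULL, histogram = NULL) {
  if (!is.null(samples)) {
    stopifnot(is.numeric(samples))
    n <- length(samples)
    if (n < 10) stop("need at least 10 radius samples", call. = FALSE)
    m <- mean(samples)
    s <- stats::sd(samples)
    return(structure(list(r_bar = m, sigma = s,
                          r_bar_se = s / sqrt(n),
                          sigma_se = s / sqrt(2 * n),
                          n = n, method = "mle",
                          degenerate = s == 0),
                     class = "gaussian_size_fit"))
  }
  if (is.null(histogram)) {
    stop("provide either samples or a histogram", call. = FALSE)
  }
  stopifnot(is.data.frame(histogram),
            all(c("mid", "count") %in% names(histogram)))
  h <- histogram[histogram$count > 0, ]
  if (nrow(h) < 5) stop("need at least 5 non-empty bins", call. = FALSE)
  n <- sum(h$count)
  mu0 <- sum(h$mid * h$count) / n
  s0 <- sqrt(sum((h$mid - mu0)^2 * h$count) / n)
  # Poisson-motivated weights 1/max(count, 1)
  fit <- minpack.lm::nlsLM(
    count ~ A * exp(-(mid - mu)^2 / (2 * s^2)), data = h,
    start = list(A = max(h$count), mu = mu0, s = s0),
    weights = 1 / pmax(h$count, 1),
    lower = c(0, 0, 1e-6))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  structure(list(r_bar = cf[["mu"]], sigma = cf[["s"]],
                 r_bar_se = unname(se[2]), sigma_se = unname(se[3]),
                 n = n, method = "histogram_wls", degenerate = FALSE),
            class = "gaussian_size_fit")
}

#' @export
print.gaussian_size_fit <- function(x, ...) {
  cat(sprintf("Gaussian size fit (%s, n = %d): r_bar = %.1f +/- %.2f nm, sigma = %.1f +/- %.2f nm\n",
              x$method, x$n, x$r_bar, x$r_bar_se, x$sigma, x$sigma_se))
  invisible(x)
}

#' Fit the occupancy model to a PPR titration
#'
#' Nonlinear least squares of the occupancy probability over the single
#' free constant \eqn{\alpha}, with the size-distribution parameters held
#' fixed at their externally measured (DLS) values. Initialization inverts
#' the fixed-radius model at the smallest informative titration point;
#' \eqn{\alpha} is bounded to (1e-8, 1). The standard error comes from the
#' Jacobian-based covariance with residual variance; an optional bootstrap
#' (resampling points) provides an alternative.
#'
#' @param points Data frame with a `P` column and either `ppr_star` or
#'   `ppr` (the latter corrected by `f_reconstitutable`). At least 3
#'   distinct ppr_star values and one point with P > 0.2 are required for
#'   identifiability.
#' @param r_bar,sigma Fixed Gaussian size-distribution parameters (nm).
#' @param f_reconstitutable Reconstitutable fraction used to derive
#'   `ppr_star` from `ppr` when needed.
#' @param variant `"gaussian"` (default) fits the Gaussian-averaged model;
#'   `"fixed_radius"` the monodisperse mono-exponential.
#' @param weights Optional per-point weights for the least squares.
#' @param area_per_lipid Area per phospholipid (nm^2) used by
#'   [derive_mass()].
#' @param bootstrap Number of bootstrap replicates for the alternative SE
#'   (0 = skip).
#' @param seed Seed for the bootstrap resampling.
#' @return A `fit_result`: `alpha_hat`, `alpha_se`, `mass`, `mass_se`,
#'   `residuals`, `fitted`, `model_variant`, `n_points`, `alpha_se_boot`
#'   (NA unless bootstrapped), `clipped` (which input points had clipped
#'   P), and the `nls` object as `fit`.
#' @export
fit_occupancy_model <- function(points, r_bar = 100.8, sigma = 32.8,
                                f_reconstitutable = 0.524,
                                variant = c("gaussian", "fixed_radius"),
                                weights = NULL, area_per_lipid = 0.70,
                                bootstrap = 0, seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(points), "P" %in% names(points))
  if (!"ppr_star" %in% names(points)) {
    if (!"ppr" %in% names(points)) {
      stop("points must contain 'ppr_star' or 'ppr'", call. = FALSE)
    }
    points$ppr_star <- apply_ppr_correction(points$ppr, f_reconstitutable)
  }
  x <- points$ppr_star
  P <- points$P
  if (length(unique(x)) < 3) {
    stop("need at least 3 distinct ppr_star values", call. = FALSE)
  }
  if (all(P <= 0)) stop("all occupancy probabilities are zero", call. = FALSE)
  if (max(P) <= 0.2) {
    stop("no point with P > 0.2: alpha is not identifiable", call. = FALSE)
  }
  sig <- if (variant == "fixed_radius") 0 else sigma
  model_P <- function(a, xx) {
    d <- 1 + sig^2 * a * xx
    1 - exp(-(r_bar^2 * xx * a / 2) / d) / sqrt(d)
  }
  # init from the smallest informative point via the fixed-radius inversion
  ok <- which(x > 0 & P > 0 & P < 1)
  a0 <- if (length(ok) > 0) {
    i <- ok[which.min(x[ok])]
    -2 * log(1 - P[i]) / (x[i] * r_bar^2)
  } else 1e-4
  a0 <- min(max(a0, 1e-7), 0.5)
  df <- data.frame(x = x, P = P)
  args <- list(P ~ model_P(a, x), data = df, start = list(a = a0),
               lower = 1e-8, upper = 1,
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) {
      stop(sprintf("occupancy fit did not converge (%s); start alpha = %.3g",
                   conditionMessage(e), a0), call. = FALSE)
    })
  alpha_hat <- stats::coef(fit)[["a"]]
  alpha_se <- tryCatch(sqrt(diag(stats::vcov(fit)))[[1]],
                       error = function(e) NA_real_)
  boot_se <- NA_real_
  if (bootstrap > 0) {
    boot_se <- with_seed(seed, {
      reps <- vapply(seq_len(bootstrap), function(b) {
        idx <- sample.int(nrow(df), replace = TRUE)
        tryCatch(stats::coef(
          minpack.lm::nlsLM(P ~ model_P(a, x), data = df[idx, ],
                            start = list(a = alpha_hat),
                            lower = 1e-8, upper = 1))[["a"]],
          error = function(e) NA_real_)
      }, numeric(1))
      stats::sd(reps, na.rm = TRUE)
    })
  }
  mass <- alpha_to_mass(alpha_hat, area_per_lipid,
                        alpha_se = ifelse(is.na(alpha_se), 0, alpha_se))
  structure(list(alpha_hat = alpha_hat, alpha_se = alpha_se,
                 mass = mass$M, mass_se = mass$M_uncertainty,
                 alpha_se_boot = boot_se,
                 residuals = P - model_P(alpha_hat, x),
                 fitted = model_P(alpha_hat, x),
                 model_variant = variant, n_points = nrow(df),
                 clipped = if (!is.null(attr(P, "clipped")))
                   attr(P, "clipped") else rep(FALSE, length(P)),
                 r_bar = r_bar, sigma = sig,
                 area_per_lipid = area_per_lipid, fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Occupancy model fit (%s, %d points)\n", x$model_variant,
              x$n_points))
  cat(sprintf("  alpha = %.3e +/- %.2e mol g^-1 nm^-2\n",
              x$alpha_hat, x$alpha_se))
  cat(sprintf("  functional mass M = %.0f +/- %.0f g/mol\n",
              x$mass, x$mass_se))
  invisible(x)
}

#' Derive the functional molar mass from an occupancy fit
#'
#' Applies \eqn{M = 16\pi/(A\,\hat\alpha)} with delta-method uncertainty
#' \eqn{\sigma_M = M\,\sigma_\alpha/\hat\alpha} (exact for the inverse
#' map).
#'
#' @param fit A `fit_result` from [fit_occupancy_model()].
#' @param area_per_lipid Area per phospholipid (nm^2); defaults to the
#'   value stored in the fit.
#' @return A `functional_mass` (see [alpha_to_mass()]).
#' @export
derive_mass <- function(fit, area_per_lipid = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  if (is.null(area_per_lipid)) area_per_lipid <- fit$area_per_lipid
  alpha_to_mass(fit$alpha_hat, area_per_lipid,
                alpha_se = ifelse(is.na(fit$alpha_se), 0, fit$alpha_se))
}
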