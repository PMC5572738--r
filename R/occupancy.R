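#' Occupancy model parameters
#'
#' Parameters of the Poisson/Gaussian vesicle-occupancy model: a vesicle of
#' radius r receives a Poisson-distributed number of functional scramblase
#' units with mean \eqn{\lambda(r) = (\alpha/2)\,PPR^* r^2}, and radii are
#' Gaussian with mean `r_bar` and standard deviation `sigma`.
#'
#' @param alpha Fit constant of the occupancy model, in mol g^-1 nm^-2;
#'   inversely proportional to the molar mass of the functional unit.
#' @param r_bar Mean vesicle radius (nm).
#' @param sigma Radius standard deviation (nm).
#' @param f_reconstitutable Fraction of vesicles competent for protein
#'   insertion, in (0, 1]. Default 0.524; its complement is the refractory
#'   pool that caps the maximal fluorescence reduction.
#' @param area_per_lipid Area per phospholipid (nm^2), default 0.70.
#'
#' @return An object of class `occupancy_params`.
#' @export
occupancy_params <- function(alpha, r_bar, sigma,
                             f_reconstitutable = 0.524,
                             area_per_lipid = 0.70) {
  stopifnot(is.numeric(alpha), is.numeric(r_bar), is.numeric(sigma))
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (r_bar <= 0) stop("r_bar must be > 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (f_reconstitutable <= 0 || f_reconstitutable > 1) {
    stop("f_reconstitutable must lie in (0, 1]", call. = FALSE)
  }
  if (area_per_lipid <= 0) stop("area_per_lipid must be > 0", call. = FALSE)
  structure(
    list(alpha = alpha, r_bar = r_bar, sigma = sigma,
         f_reconstitutable = f_reconstitutable,
         area_per_lipid = area_per_lipid),
    class = "occupancy_params"
  )
}

#' Expected number of scramblase units in a vesicle of given radius
#'
#' The Poisson mean \eqn{\lambda(r) = (\alpha/2)\, PPR^* r^2}: protein mass
#' distributes over vesicles in proportion to their lipid (surface) content,
#' so the expected copy number scales with the corrected protein-to-
#' phospholipid ratio and the squared radius.
#'
#' @param r Vesicle radius (nm).
#' @param ppr_star Corrected protein-to-phospholipid ratio PPR* (g protein
#'   per mol phospholipid); see [apply_ppr_correction()].
#' @param alpha Occupancy fit constant (mol g^-1 nm^-2).
#' @return Expected scramblase count (unitless, >= 0). Vectorized over `r`
#'   and `ppr_star`.
#' @export
expected_scramblases <- function(r, ppr_star, alpha) {
  stopifnot(is.numeric(r), is.numeric(ppr_star), is.numeric(alpha))
  if (any(r <= 0)) stop("radius must be > 0", call. = FALSE)
  if (any(ppr_star < 0)) stop("ppr_star must be >= 0", call. = FALSE)
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  (alpha / 2) * ppr_star * r^2
}

#' Occupancy probability for a fixed vesicle radius
#'
#' Probability that a vesicle of radius `r` carries at least one functional
#' scramblase, \eqn{P = 1 - e^{-\lambda(r)}} under Poisson placement. This is
#' the mono-exponential limit of the occupancy model for a monodisperse
#' population.
#'
#' @inheritParams expected_scramblases
#' @return Probability in [0, 1). Vectorized.
#' @export
prob_occupied_fixed_radius <- function(r, ppr_star, alpha) {
  1 - exp(-expected_scramblases(r, ppr_star, alpha))
}

#' Occupancy probability for a Gaussian vesicle size distribution
#'
#' The Gaussian-radius average of [prob_occupied_fixed_radius()], in closed
#' form:
#' \deqn{P(\ge 1) = 1 - \frac{1}{\sqrt{1 + \sigma^2 \alpha PPR^*}}
#'   \exp\!\left(- \frac{\bar r^2\, PPR^*\, \alpha/2}
#'                      {1 + \sigma^2\, PPR^*\, \alpha}\right)}
#' which is the exact expectation of \eqn{1 - e^{-(\alpha/2) PPR^* r^2}} over
#' \eqn{r \sim N(\bar r, \sigma)}. The exponent is negative, so the
#' expression stays in [0, 1) and reduces to the fixed-radius form as
#' \eqn{\sigma \to 0}. The untruncated Gaussian is integrated; for
#' \eqn{\sigma/\bar r \lesssim 0.33} the mass at non-positive radii is
#' negligible (see the methods vignette).
#'
#' @param ppr_star Corrected protein-to-phospholipid ratio (g/mol).
#' @param params An [occupancy_params()] object.
#' @return Probability in [0, 1). Vectorized over `ppr_star`.
#' @examples
#' p <- occupancy_params(alpha = 8.96e-4, r_bar = 100.8, sigma = 32.8)
#' prob_occupied_gaussian(c(0, 0.1, 1, 2), p)
#' @export
prob_occupied_gaussian <- function(ppr_star, params) {
  stopifnot(inherits(params, "occupancy_params"), is.numeric(ppr_star))
  if (any(ppr_star < 0)) stop("ppr_star must be >= 0", call. = FALSE)
  a <- params$alpha
  denom <- 1 + params$sigma^2 * a * ppr_star
  if (any(denom <= 0)) stop("degenerate variance term", call. = FALSE)
  1 - exp(-(params$r_bar^2 * ppr_star * a / 2) / denom) / sqrt(denom)
}

#' Convert the occupancy fit constant to a functional molar mass
#'
#' With lipids counted on both leaflets at equal radius (\eqn{8\pi r^2 / A})
#' and protein partitioned in proportion to lipid content, the Poisson mean
#' per vesicle is \eqn{\lambda = PPR^* (8\pi r^2/A) / M}. Matching this to
#' \eqn{\lambda = (\alpha/2) PPR^* r^2} gives
#' \deqn{M = \frac{16\pi}{A\,\alpha}.}
#' The uncertainty propagates exactly under the inverse map:
#' \eqn{\sigma_M / M = \sigma_\alpha / \alpha}.
#'
#' @param alpha Occupancy fit constant (mol g^-1 nm^-2).
#' @param area_per_lipid Area per phospholipid (nm^2), default 0.70.
#' @param alpha_se Optional standard error of `alpha` (same units).
#' @return An object of class `functional_mass` with fields `M` (g/mol) and
#'   `M_uncertainty` (g/mol; 0 when `alpha_se` is not given).
#' @examples
#' alpha_to_mass(8.96e-4)  # ~8.0e4 g/mol, a trimer of a ~27 kDa monomer
#' @export
alpha_to_mass <- function(alpha, area_per_lipid = 0.70, alpha_se = 0) {
  stopifnot(is.numeric(alpha), is.numeric(area_per_lipid))
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  if (any(area_per_lipid <= 0)) stop("area_per_lipid must be > 0", call. = FALSE)
  if (any(alpha_se < 0)) stop("alpha_se must be >= 0", call. = FALSE)
  M <- 16 * pi / (area_per_lipid * alpha)
  structure(list(M = M, M_uncertainty = M * alpha_se / alpha),
            class = "functional_mass")
}

#' @rdname alpha_to_mass
#' @param M Functional molar mass (g/mol).
#' @return `mass_to_alpha()` returns the fit constant `alpha`; it is the
#'   exact inverse of `alpha_to_mass()`.
#' @export
mass_to_alpha <- function(M, area_per_lipid = 0.70) {
  if (inherits(M, "functional_mass")) M <- M$M
  stopifnot(is.numeric(M), is.numeric(area_per_lipid))
  if (any(M <= 0)) stop("M must be > 0", call. = FALSE)
  if (any(area_per_lipid <= 0)) stop("area_per_lipid must be > 0", call. = FALSE)
  16 * pi / (area_per_lipid * M)
}

#' Correct the protein-to-phospholipid ratio for the refractory vesicle pool
#'
#' A fraction of vesicles never receives protein during detergent-mediated
#' reconstitution; the protein is shared over the reconstitutable pool only,
#' so the effective ratio is \eqn{PPR^* = PPR / f}. With the default
#' f = 0.524, PPR* = PPR / 0.524.
#'
#' @param ppr Measured protein-to-phospholipid ratio (g protein per mol
#'   phospholipid), >= 0.
#' @param f_reconstitutable Reconstitutable vesicle fraction in (0, 1].
#' @return Corrected ratio PPR* (g/mol), >= `ppr`. Vectorized.
#' @export
apply_ppr_correction <- function(ppr, f_reconstitutable = 0.524) {
  stopifnot(is.numeric(ppr), is.numeric(f_reconstitutable))
  if (any(ppr < 0)) stop("ppr must be >= 0", call. = FALSE)
  if (any(f_reconstitutable <= 0) || any(f_reconstitutable > 1)) {
    stop("f_reconstitutable must lie in (0, 1]", call. = FALSE)
  }
  ppr / f_reconstitutable
}

#' @export
print.functional_mass <- function(x, ...) {
  cat(sprintf("Functional molar mass: %.0f +/- %.0f g/mol\n",
              x$M, x$M_uncertainty))
  invisible(x)
}
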