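# Independent numerical oracle for the Gaussian-averaged occupancy
# probability: quadrature of the Poisson non-occupancy over the Gaussian
# radius density. Bounds cover +/- 15 sd around the mean, where the
# integrand's mass lives.
quad_occupancy <- function(ppr_star, alpha, r_bar, sigma) {
  if (sigma == 0) return(1 - exp(-(alpha / 2) * ppr_star * r_bar^2))
  stats::integrate(
    function(r) stats::dnorm(r, r_bar, sigma) *
      (1 - exp(-(alpha / 2) * ppr_star * r^2)),
    lower = r_bar - 15 * sigma, upper = r_bar + 15 * sigma,
    rel.tol = 1e-12, abs.tol = 1e-13, subdivisions = 2000L)$value
}

# A minimal monodisperse vesicle population for trace simulations.
uniform_population <- function(n, count, radius = 100, lipids = 349000) {
  data.frame(radius = rep(radius, n),
             scramblase_count = rep(as.integer(count), n),
             refractory = rep(FALSE, n),
             lipid_count = rep(lipids, n))
}
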