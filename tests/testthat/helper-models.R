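# shared fixtures: the default study-scale parameter sets used across tests

default_area <- function() cell_area_model(2, 500)
grid_area <- function() cell_area_model(2, 1500)

# cycle model without the G2 area coupling: areas exactly gamma, counts
# exactly negative binomial
flat_cycle <- function() cell_cycle_model(g2_area_factor = 1)

# NB pmf by numerical integration of the Poisson law over the gamma area
# density (independent quadrature oracle for the gamma-Poisson mixture)
nb_pmf_quadrature <- function(n, alpha, beta, rate_per_area) {
  vapply(n, function(k) {
    # finite upper limit covering both the gamma mass and the Poisson bump
    # around a = k / rate (an infinite range lets the quadrature miss it)
    upper <- max(stats::qgamma(1 - 1e-14, alpha, scale = beta),
                 (k + 12 * sqrt(k + 1) + 30) / max(rate_per_area, 1e-12))
    stats::integrate(function(a) {
      stats::dpois(k, rate_per_area * a) * stats::dgamma(a, alpha, scale = beta)
    }, 0, upper, rel.tol = 1e-11, subdivisions = 2000L)$value
  }, numeric(1))
}

local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("nlvtab")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
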