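test_that("endosome count pmf matches the Poisson closed form", {
  expect_equal(endosome_count_pmf(0, mu = 0, area = 100, t = 1), 1)
  expect_equal(endosome_count_pmf(0, mu = log(2), area = 1, t = 1), 0.5)
  # direct factorial/exponential arithmetic: Poisson(2) at 3 = 4 e^-2 / 3
  expect_equal(endosome_count_pmf(3, mu = 0.5, area = 4, t = 1),
               4 * exp(-2) / 3, tolerance = 1e-12)
  k <- 0:200
  expect_equal(sum(endosome_count_pmf(k, mu = 0.5, area = 20, t = 2)), 1,
               tolerance = 1e-9)
  expect_error(endosome_count_pmf(-1, 1, 1, 1), "non-negative")
  expect_error(endosome_count_pmf(1, -0.1, 1, 1), ">=")
})

test_that("capture probability is 1 - exp(-delta) with a tight linearisation", {
  expect_equal(capture_probability(0), 0)
  expect_equal(capture_probability(log(2)), 0.5)
  expect_equal(capture_probability(0.01, linearised = TRUE), 0.01)
  # Taylor remainder: relative error of the linearised form <= delta/2
  d <- 0.01
  rel <- abs(capture_probability(d) - d) / d
  expect_lt(rel, d / 2 + 1e-6)
  expect_error(capture_probability(-0.1), "non-negative")
})

test_that("single-cell NLV law is the thinned Poisson with rate lam*A*C*t", {
  e <- exposure_condition(2, 1)
  expect_equal(nlv_pmf_single_cell(0, lam = 0, area = 1000, e), 1)
  # structural identity with the endosome law under mu*t -> lam*C*t
  k <- 0:40
  expect_equal(nlv_pmf_single_cell(k, lam = 0.002, area = 800, e),
               endosome_count_pmf(k, mu = 0.002 * 2, area = 800, t = 1))
  # mean by adaptive summation
  lam <- 7.3 / (1000 * 2) # lam*A*C*t = 7.3
  k <- 0:200
  pmf <- nlv_pmf_single_cell(k, lam, 1000, e)
  expect_equal(sum(k * pmf), 7.3, tolerance = 1e-9)
})

test_that("gamma-Poisson mixture equals the negative binomial termwise", {
  e <- exposure_condition(2, 1)
  pmf <- nlv_pmf_population(0:60, default_area(), uptake_model(lam = 0.002), e)
  oracle <- nb_pmf_quadrature(0:60, 2, 500, 0.002 * 2)
  expect_lt(max(abs(pmf - oracle)), 1e-8)
  # mean matches lam * alpha*beta * Ct
  k <- 0:400
  pk <- nlv_pmf_population(k, default_area(), uptake_model(lam = 0.002), e)
  expect_equal(sum(k * pk), 0.002 * 2 * 500 * 2, tolerance = 1e-6)
})

test_that("mixture identity holds across the parameter sweep and pmfs normalise", {
  for (alpha in c(0.5, 2, 8)) {
    for (blct in c(0.1, 1, 10)) {
      beta <- 500
      lam_ct <- blct / beta # rate per unit area
      e <- exposure_condition(lam_ct / 0.001, 1)
      up <- uptake_model(lam = 0.001)
      am <- cell_area_model(alpha, beta)
      n <- 0:60
      expect_lt(max(abs(nlv_pmf_population(n, am, up, e) -
                        nb_pmf_quadrature(n, alpha, beta, lam_ct))), 1e-8)
      k <- 0:2000
      expect_equal(sum(nlv_pmf_population(k, am, up, e)), 1, tolerance = 1e-9)
    }
  }
})

test_that("zero dose gives a point mass at zero NLVs", {
  e <- exposure_condition(2, 1)
  pmf <- nlv_pmf_population(0:5, default_area(), uptake_model(lam = 0), e)
  expect_equal(pmf, c(1, 0, 0, 0, 0, 0))
  expect_error(exposure_condition(Inf, 1), "finite")
})

test_that("NB mean identity pr/(1-p) = lam*alpha*beta*Ct holds to machine precision", {
  expect_equal(nb_mean(default_area(), uptake_model(lam = 0),
                       exposure_condition(1, 1)), 0)
  # linearity in the dose-time product
  m1 <- nb_mean(default_area(), uptake_model(lam = 0.002), exposure_condition(2, 1))
  m2 <- nb_mean(default_area(), uptake_model(lam = 0.002), exposure_condition(2, 2))
  expect_equal(m2, 2 * m1)
  set.seed(11)
  for (i in 1:50) {
    am <- cell_area_model(runif(1, 0.3, 10), runif(1, 10, 3000))
    up <- uptake_model(lam = runif(1, 1e-5, 1e-2))
    e <- exposure_condition(runif(1, 0.1, 10), runif(1, 0.1, 5))
    nb <- nb_params(am, up, e)
    expect_equal(nb$p * nb$r / (1 - nb$p), nb_mean(am, up, e),
                 tolerance = 1e-12)
  }
})

test_that("the NB law is over-dispersed whenever dose is positive", {
  nb <- nb_params(default_area(), uptake_model(lam = 0.002),
                  exposure_condition(2, 1))
  k <- 0:500
  pk <- dnbinom(k, size = nb$r, prob = 1 - nb$p)
  m <- sum(k * pk); v <- sum(k^2 * pk) - m^2
  expect_equal(v / m, 1 / (1 - nb$p), tolerance = 1e-6)
  expect_gt(v / m, 1)
})

test_that("uptake model enforces lam = mu * kappa", {
  expect_equal(uptake_model(mu = 1.5, kappa = 0.002)$lam, 0.003)
  expect_error(uptake_model(lam = 0.01, mu = 1, kappa = 0.002), "mu \\* kappa")
  expect_error(uptake_model(), "supply")
})

test_that("compound intensity distribution obeys Wald's identity and both routes agree", {
  am <- default_area()
  e <- exposure_condition(4, 2)
  up <- uptake_model(lam = 0.001) # nb mean = 8
  nb <- nb_params(am, up, e)
  expect_equal(nb$mean, 8)
  im <- intensity_model("lognormal", meanlog = log(500), sdlog = 0.5)

  ds <- cell_intensity_distribution(nb, im, "stochastic", n_samples = 1e5,
                                    seed = 3)
  mc_se <- sqrt(ds$var_analytic / 1e5)
  expect_lt(abs(mean(ds) - nb$mean * intensity_mean(im)), 3 * mc_se)

  dn <- cell_intensity_distribution(nb, im, "numeric")
  expect_equal(mean(dn), dn$mean_analytic, tolerance = 1e-3)
  expect_equal(sum(dn$grid$mass), 1, tolerance = 1e-9)
  expect_equal(dn$grid$mass[1], dn$p_zero, tolerance = 1e-4)

  qs <- seq(0, intensity_quantile(im, 0.999) * 30, length.out = 400)
  expect_lt(max(abs(cell_intensity_cdf(ds, qs) - cell_intensity_cdf(dn, qs))),
            0.01)
})

test_that("a degenerate NB puts all intensity mass at zero", {
  nb <- nb_params(default_area(), uptake_model(lam = 0), exposure_condition(1, 1))
  d <- cell_intensity_distribution(nb, intensity_model(), "stochastic",
                                   n_samples = 1000, seed = 1)
  expect_true(all(d$samples == 0))
  expect_equal(d$p_zero, 1)
  expect_error(cell_intensity_distribution(nb, intensity_model(), "wrong"),
               "arg")
})
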