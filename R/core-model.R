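#' Poisson law of endosome formation
#'
#' Endocytosis is modelled as a spatial Poisson process over the cell
#' membrane, so the number of endosomes a cell of area `area` forms in `t`
#' hours is Poisson with rate `mu * area * t`.
#'
#' @param n Endosome count(s); non-negative integers.
#' @param mu Endosome generation rate per area unit per hour, `>= 0`.
#' @param area Cell area, area units, `>= 0`.
#' @param t Duration, hours, `>= 0`.
#' @return Probability mass at `n`, vectorised over `n`.
#' @examples
#' endosome_count_pmf(0:5, mu = 0.5, area = 4, t = 1)
#' @export
endosome_count_pmf <- function(n, mu, area, t) {
  check_counts(n)
  check_number(mu, "mu", 0)
  check_number(area, "area", 0)
  check_number(t, "t", 0)
  dpois(n, mu * area * t)
}

#' Probability that a forming endosome captures at least one particle
#'
#' Particle arrival at the site of a forming endosome is Poisson with mean
#' `delta` arrivals per formation window, so the capture probability is
#' `1 - exp(-delta)`. For the rare-capture regime (`delta` small) the
#' linearised form `delta` itself is the thinning probability used to reduce
#' the coupled formation/arrival process to a single thinned Poisson law.
#'
#' @param delta Mean particle arrivals per forming endosome, `>= 0`.
#'   Vectorised.
#' @param linearised If `TRUE`, return the small-`delta` linearisation
#'   `delta` instead of the exact `1 - exp(-delta)`.
#' @return Capture probability (or its linearisation).
#' @examples
#' capture_probability(log(2)) # 0.5
#' capture_probability(0.01, linearised = TRUE)
#' @export
capture_probability <- function(delta, linearised = FALSE) {
  if (!is.numeric(delta) || anyNA(delta) || any(delta < 0)) {
    stop_bad_arg("`delta` must be non-negative")
  }
  if (linearised) delta else -expm1(-delta)
}

#' Per-cell NLV distribution (known area)
#'
#' Thinning the endosome-formation Poisson process by the rare-capture
#' probability leaves the number of nanoparticle-loaded vesicles (NLVs)
#' formed by a single cell of known area Poisson with rate
#' `lam * area * C * t`.
#'
#' @param n NLV count(s); non-negative integers.
#' @param lam NLV formation rate constant (per nM per h per area unit).
#' @param area Cell area, area units.
#' @param exposure An [exposure_condition()].
#' @return Probability mass at `n`.
#' @examples
#' nlv_pmf_single_cell(0:10, lam = 0.002, area = 1000, exposure_condition(2, 1))
#' @export
nlv_pmf_single_cell <- function(n, lam, area, exposure) {
  check_counts(n)
  check_number(lam, "lam", 0)
  check_number(area, "area", 0)
  stopifnot(inherits(exposure, "exposure_condition"))
  dpois(n, lam * area * exposure$dtp)
}

#' Population NLV distribution (negative binomial)
#'
#' Mixing the per-cell Poisson law over the gamma distribution of cell area
#' yields a negative binomial for NLVs per cell across the population, with
#' `r = shape` and `p = scale*lam*C*t / (1 + scale*lam*C*t)`.
#'
#' @param n NLV count(s); non-negative integers.
#' @param areas A [cell_area_model()].
#' @param uptake An [uptake_model()].
#' @param exposure An [exposure_condition()].
#' @return Probability mass at `n`.
#' @examples
#' nlv_pmf_population(0:20, cell_area_model(2, 500),
#'                    uptake_model(lam = 0.002), exposure_condition(2, 1))
#' @export
nlv_pmf_population <- function(n, areas, uptake, exposure) {
  check_counts(n)
  nb <- nb_params(areas, uptake, exposure)
  dnbinom(n, size = nb$r, prob = 1 - nb$p)
}

#' Mean NLVs per cell
#'
#' The negative-binomial mean reduces to `lam * shape*scale * C*t`: mean
#' uptake is linear in the dose-time product with slope
#' `lam * mean cell area`. This linearity is what calibrates `lam` from
#' per-condition mean counts.
#'
#' @inheritParams nlv_pmf_population
#' @return Expected NLV count per cell.
#' @examples
#' nb_mean(cell_area_model(2, 500), uptake_model(lam = 0.002),
#'         exposure_condition(2, 1)) # 4
#' @export
nb_mean <- function(areas, uptake, exposure) {
  stopifnot(inherits(areas, "cell_area_model"),
            inherits(uptake, "uptake_model"),
            inherits(exposure, "exposure_condition"))
  uptake$lam * areas$shape * areas$scale * exposure$dtp
}

# Adaptive support for a negative binomial: 0..K with tail mass < tail_tol.
nb_support <- function(nb, tail_tol = 1e-12) {
  v <- nb$mean / (1 - nb$p)
  k <- max(10, ceiling(nb$mean + 12 * sqrt(max(v, 1e-12))))
  while (pnbinom(k, size = nb$r, prob = 1 - nb$p, lower.tail = FALSE) > tail_tol) {
    k <- k * 2L
    if (k > 1e8) stop_bad_arg("NB support truncation failed to converge")
  }
  0:k
}

#' Distribution of total per-cell NLV fluorescence
#'
#' The total nanoparticle fluorescence of a cell is a compound sum: draw the
#' NLV count `N` from the population negative binomial, then add `N`
#' independent per-vesicle intensities. Cells with `N = 0` contribute an
#' atom at zero intensity. Two evaluation routes are provided:
#' `"stochastic"` samples the compound sum; `"numeric"` computes the
#' negative-binomially weighted sum of N-fold convolutions of the intensity
#' density on a uniform grid via the FFT (using the closed-form NB
#' probability generating function applied to the discretised intensity
#' characteristic function).
#'
#' @param nb An [nb_params()] object.
#' @param intensity An [intensity_model()].
#' @param method `"stochastic"` or `"numeric"`.
#' @param n_samples Number of Monte Carlo cells for `"stochastic"`
#'   (default `1e5`).
#' @param grid_points Number of grid points for `"numeric"` (default 4096,
#'   minimum 2048). The grid spans 0 to the `1 - 1e-6` quantile of the
#'   compound sum (normal-approximation bound).
#' @param seed Optional RNG seed for `"stochastic"`.
#' @return An object of class `cell_intensity_dist` with the zero atom mass
#'   `p_zero`, and either `samples` (stochastic) or a `grid` tibble with
#'   columns `intensity`, `mass`, `cdf` (numeric).
#' @examples
#' nb <- nb_params(cell_area_model(2, 500), uptake_model(lam = 0.002),
#'                 exposure_condition(2, 1))
#' d <- cell_intensity_distribution(nb, intensity_model(), "numeric")
#' mean(d)
#' @export
cell_intensity_distribution <- function(nb, intensity,
                                        method = c("stochastic", "numeric"),
                                        n_samples = 1e5, grid_points = 4096,
                                        seed = NULL) {
  stopifnot(inherits(nb, "nb_params"), inherits(intensity, "intensity_model"))
  method <- match.arg(method)
  m_i <- intensity_mean(intensity)
  v_i <- intensity_var(intensity)
  v_n <- nb$mean / (1 - nb$p)
  mean_c <- nb$mean * m_i
  var_c <- nb$mean * v_i + v_n * m_i^2 # Wald's identities
  out <- list(nb = nb, intensity = intensity, method = method,
              mean_analytic = mean_c, var_analytic = var_c,
              p_zero = (1 - nb$p)^nb$r)
  if (method == "stochastic") {
    check_number(n_samples, "n_samples", 1)
    out$samples <- with_seed(seed, {
      counts <- rnbinom(n_samples, size = nb$r, prob = 1 - nb$p)
      tot <- numeric(n_samples)
      pos <- counts > 0
      if (any(pos)) {
        draws <- intensity_rand(intensity, sum(counts))
        sums <- rowsum(draws, rep.int(which(pos), counts[pos]))
        tot[as.integer(rownames(sums))] <- sums[, 1]
      }
      tot
    })
  } else {
    check_number(grid_points, "grid_points", 2048)
    m <- as.integer(grid_points)
    # upper bound: beyond the compound-sum 1-1e-6 quantile; the compound sum
    # is right-skewed so pad the normal bound generously, and never sit
    # below the single-vesicle tail
    xmax <- max(mean_c + 10 * sqrt(var_c),
                2 * intensity_quantile(intensity, 1 - 1e-6), m_i)
    h <- xmax / m
    edges <- (seq_len(m) - 0.5) * h
    w <- diff(c(0, intensity_cdf(intensity, edges))) # mass at grid k = k*h
    pad <- c(w, numeric(m))
    phi <- fft(pad)
    # NB pgf G(z) = ((1-p)/(1-p z))^r applied to the lattice characteristic fn
    gz <- ((1 - nb$p) / (1 - nb$p * phi))^nb$r
    dens <- Re(fft(gz, inverse = TRUE)) / (2 * m)
    dens <- pmax(dens[seq_len(m + 1)], 0)
    dens <- dens / sum(dens)
    out$grid <- tibble::tibble(
      intensity = (seq_len(m + 1) - 1) * h,
      mass = dens,
      cdf = cumsum(dens)
    )
  }
  structure(out, class = "cell_intensity_dist")
}

#' @export
mean.cell_intensity_dist <- function(x, ...) {
  if (x$method == "stochastic") mean(x$samples)
  else sum(x$grid$intensity * x$grid$mass)
}

#' CDF of a per-cell intensity distribution
#'
#' @param dist A `cell_intensity_dist`.
#' @param q Intensity quantiles at which to evaluate the CDF.
#' @return `P(I_cell <= q)`.
#' @export
cell_intensity_cdf <- function(dist, q) {
  stopifnot(inherits(dist, "cell_intensity_dist"))
  if (dist$method == "stochastic") {
    ecdf(dist$samples)(q)
  } else {
    idx <- findInterval(q, dist$grid$intensity)
    ifelse(idx < 1, 0, dist$grid$cdf[pmax(idx, 1)])
  }
}

#' @export
print.cell_intensity_dist <- function(x, ...) {
  cat(sprintf("<cell_intensity_dist> method = %s, mean = %g (analytic %g), P(I=0) = %g\n",
              x$method, mean(x), x$mean_analytic, x$p_zero))
  invisible(x)
}

#' @export
tidy.cell_intensity_dist <- function(x, ...) {
  if (x$method == "numeric") return(x$grid)
  tibble::tibble(intensity = x$samples)
}

#' @export
autoplot.cell_intensity_dist <- function(object, ...) {
  if (object$method == "numeric") {
    df <- object$grid[-1, ]
    h <- df$intensity[2] - df$intensity[1]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$intensity, y = .data$mass / h)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "total NLV intensity per cell", y = "density",
                    subtitle = sprintf("P(I = 0) = %.3f", object$p_zero))
  } else {
    ggplot2::ggplot(tibble::tibble(intensity = object$samples),
                    ggplot2::aes(x = .data$intensity)) +
      ggplot2::geom_histogram(bins = 60) +
      ggplot2::labs(x = "total NLV intensity per cell", y = "cells")
  }
}
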