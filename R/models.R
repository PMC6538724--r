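#' Exposure condition
#'
#' Describes one nanoparticle exposure: an administered concentration (nM)
#' applied for a fixed duration (h). Their product, the dose-time product
#' (DTP, nM h), is the single covariate that drives mean uptake in the
#' negative-binomial model.
#'
#' @param concentration Administered nanoparticle concentration, nM. Must be
#'   positive.
#' @param duration Exposure duration, hours. Must be positive.
#' @return An object of class `exposure_condition` with fields
#'   `concentration`, `duration` and the derived `dtp`.
#' @examples
#' exposure_condition(2, 1)$dtp # 2 nM h
#' @export
exposure_condition <- function(concentration, duration) {
  check_number(concentration, "concentration", 0, strict_min = TRUE)
  check_number(duration, "duration", 0, strict_min = TRUE)
  structure(
    list(concentration = concentration, duration = duration,
         dtp = concentration * duration),
    class = "exposure_condition"
  )
}

#' @export
print.exposure_condition <- function(x, ...) {
  cat(sprintf("<exposure_condition> C = %g nM, t = %g h (DTP = %g nM h)\n",
              x$concentration, x$duration, x$dtp))
  invisible(x)
}

#' Gamma model of the cell-area distribution
#'
#' Cell areas across an adherent population are well described by a gamma
#' distribution with shape `shape` and scale `scale` (area units, square
#' micrometres for typical segmentation output). The population mean area is
#' `shape * scale`.
#'
#' @param shape Gamma shape parameter (dimensionless), > 0.
#' @param scale Gamma scale parameter (area units), > 0.
#' @return An object of class `cell_area_model`.
#' @examples
#' am <- cell_area_model(2, 500)
#' area_mean(am) # 1000
#' @export
cell_area_model <- function(shape, scale) {
  check_number(shape, "shape", 0, strict_min = TRUE)
  check_number(scale, "scale", 0, strict_min = TRUE)
  structure(list(shape = shape, scale = scale), class = "cell_area_model")
}

#' @rdname cell_area_model
#' @param model A `cell_area_model`.
#' @export
area_mean <- function(model) {
  stopifnot(inherits(model, "cell_area_model"))
  model$shape * model$scale
}

#' @export
print.cell_area_model <- function(x, ...) {
  cat(sprintf("<cell_area_model> shape = %g, scale = %g (mean area %g)\n",
              x$shape, x$scale, x$shape * x$scale))
  invisible(x)
}

#' Uptake rate model
#'
#' Holds the rate constant lambda for nanoparticle-loaded vesicle (NLV)
#' formation: NLVs form per cell at rate `lam * area * concentration` per
#' hour. Lambda factorises as `mu * kappa`, where `mu` is the endosome
#' generation rate per unit area per hour and `kappa` the (per-nM) capture
#' probability of a forming endosome; the factors are optional and only
#' needed by the mechanistic simulator. `delta` is the simulator-facing mean
#' number of particle arrivals during one endosome formation window.
#'
#' @param lam NLV formation rate, per nM per h per area unit. `>= 0`.
#' @param mu Optional endosome generation rate per area unit per hour.
#' @param kappa Optional capture proportionality per nM.
#' @param delta Optional mean particle arrivals per forming endosome.
#' @return An object of class `uptake_model`.
#' @examples
#' uptake_model(lam = 0.00107)
#' uptake_model(mu = 1, kappa = 0.002) # lam filled in as mu * kappa
#' @export
uptake_model <- function(lam = NULL, mu = NULL, kappa = NULL, delta = NULL) {
  if (!is.null(mu)) check_number(mu, "mu", 0)
  if (!is.null(kappa)) check_number(kappa, "kappa", 0)
  if (!is.null(delta)) check_number(delta, "delta", 0)
  if (is.null(lam)) {
    if (is.null(mu) || is.null(kappa)) {
      stop_bad_arg("supply `lam`, or both `mu` and `kappa`")
    }
    lam <- mu * kappa
  }
  check_number(lam, "lam", 0)
  if (!is.null(mu) && !is.null(kappa) &&
      abs(lam - mu * kappa) > 1e-12 * max(1, abs(lam))) {
    stop_bad_arg("`lam` must equal `mu * kappa` when both factors are given")
  }
  structure(list(lam = lam, mu = mu, kappa = kappa, delta = delta),
            class = "uptake_model")
}

#' @export
print.uptake_model <- function(x, ...) {
  cat(sprintf("<uptake_model> lambda = %g per nM per h per area unit\n", x$lam))
  invisible(x)
}

#' Negative-binomial parameters of the per-cell NLV distribution
#'
#' Mixing the per-cell Poisson NLV law over a gamma cell-area distribution
#' gives a negative binomial with shape `r = alpha` and success probability
#' `p = beta*lam*C*t / (1 + beta*lam*C*t)`; its mean is
#' `p*r/(1-p) = lam * alpha*beta * C*t`.
#'
#' @param areas A [cell_area_model()].
#' @param uptake An [uptake_model()].
#' @param exposure An [exposure_condition()].
#' @return An object of class `nb_params` with fields `r`, `p` and `mean`.
#' @examples
#' nb <- nb_params(cell_area_model(2, 500), uptake_model(lam = 0.002),
#'                 exposure_condition(2, 1))
#' nb$mean # 0.002 * 1000 * 2 = 4
#' @export
nb_params <- function(areas, uptake, exposure) {
  stopifnot(inherits(areas, "cell_area_model"),
            inherits(uptake, "uptake_model"),
            inherits(exposure, "exposure_condition"))
  blct <- areas$scale * uptake$lam * exposure$dtp
  if (!is.finite(blct)) stop_bad_arg("non-finite dose-time product")
  p <- blct / (1 + blct)
  structure(list(r = areas$shape, p = p, mean = p * areas$shape / (1 - p)),
            class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  cat(sprintf("<nb_params> r = %g, p = %g (mean NLVs per cell %g)\n",
              x$r, x$p, x$mean))
  invisible(x)
}

#' Per-vesicle intensity model
#'
#' Parametric model of the integrated fluorescence intensity of a single
#' nanoparticle-loaded vesicle (a surrogate for the number of encapsulated
#' particles). The distribution is dose-invariant: one parameter set is
#' shared across all exposure conditions. Supported families are
#' `"lognormal"` (parameters `meanlog`, `sdlog`) and `"gamma"` (parameters
#' `shape`, `scale`); both are positive, unimodal and right-skewed, matching
#' observed per-vesicle intensity histograms.
#'
#' @param family `"lognormal"` or `"gamma"`.
#' @param ... Family parameters: `meanlog`/`sdlog` or `shape`/`scale`.
#' @return An object of class `intensity_model`.
#' @examples
#' im <- intensity_model("lognormal", meanlog = log(500), sdlog = 0.5)
#' intensity_mean(im)
#' @export
intensity_model <- function(family = c("lognormal", "gamma"), ...) {
  family <- match.arg(family)
  params <- list(...)
  defaults <- switch(family,
    lognormal = list(meanlog = log(500), sdlog = 0.5),
    gamma = list(shape = 4, scale = 150)
  )
  missing <- setdiff(names(defaults), names(params))
  params <- c(params[names(params) %in% names(defaults)], defaults[missing])
  if (family == "lognormal") {
    check_number(params$meanlog, "meanlog", finite = TRUE)
    check_number(params$sdlog, "sdlog", 0, strict_min = TRUE)
  } else {
    check_number(params$shape, "shape", 0, strict_min = TRUE)
    check_number(params$scale, "scale", 0, strict_min = TRUE)
  }
  structure(list(family = family, params = params), class = "intensity_model")
}

#' @rdname intensity_model
#' @param model An `intensity_model`.
#' @param x,q,p,n Evaluation points, quantile probabilities or sample size.
#' @export
intensity_density <- function(model, x) {
  switch(model$family,
    lognormal = dlnorm(x, model$params$meanlog, model$params$sdlog),
    gamma = dgamma(x, shape = model$params$shape, scale = model$params$scale))
}

#' @rdname intensity_model
#' @export
intensity_cdf <- function(model, q) {
  switch(model$family,
    lognormal = plnorm(q, model$params$meanlog, model$params$sdlog),
    gamma = pgamma(q, shape = model$params$shape, scale = model$params$scale))
}

#' @rdname intensity_model
#' @export
intensity_quantile <- function(model, p) {
  switch(model$family,
    lognormal = qlnorm(p, model$params$meanlog, model$params$sdlog),
    gamma = qgamma(p, shape = model$params$shape, scale = model$params$scale))
}

#' @rdname intensity_model
#' @export
intensity_rand <- function(model, n) {
  switch(model$family,
    lognormal = rlnorm(n, model$params$meanlog, model$params$sdlog),
    gamma = rgamma(n, shape = model$params$shape, scale = model$params$scale))
}

#' @rdname intensity_model
#' @export
intensity_mean <- function(model) {
  switch(model$family,
    lognormal = exp(model$params$meanlog + model$params$sdlog^2 / 2),
    gamma = model$params$shape * model$params$scale)
}

#' @rdname intensity_model
#' @export
intensity_var <- function(model) {
  switch(model$family,
    lognormal = {
      s2 <- model$params$sdlog^2
      (exp(s2) - 1) * exp(2 * model$params$meanlog + s2)
    },
    gamma = model$params$shape * model$params$scale^2)
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf("<intensity_model> %s(%s)\n", x$family,
              paste(names(x$params), format(unlist(x$params), digits = 4),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Cell-cycle (DNA content) model
#'
#' Two-mode model of per-cell integrated nuclear stain intensity: G1 cells
#' around `g1_mode`, G2 cells around `g2_mode` (about twice `g1_mode`, DNA
#' doubling), each mode a truncated normal with coefficient of variation
#' `cv`. G2 cells are larger: their area draw is multiplied by
#' `g2_area_factor`.
#'
#' @param g1_mode,g2_mode Modal nuclear intensities of the G1 and G2
#'   subpopulations; `g2_mode/g1_mode` must lie in `[1.8, 2.2]`.
#' @param cv Coefficient of variation of each mode (default 0.07).
#' @param g2_fraction Proportion of cells in G2 (default 0.3).
#' @param g2_area_factor Multiplicative area scaling for G2 cells, `>= 1`
#'   (default 1.6).
#' @return An object of class `cell_cycle_model`.
#' @export
cell_cycle_model <- function(g1_mode = 200, g2_mode = 400, cv = 0.07,
                             g2_fraction = 0.3, g2_area_factor = 1.6) {
  check_number(g1_mode, "g1_mode", 0, strict_min = TRUE)
  check_number(g2_mode, "g2_mode", 0, strict_min = TRUE)
  ratio <- g2_mode / g1_mode
  if (ratio < 1.8 || ratio > 2.2) {
    stop_bad_arg("`g2_mode/g1_mode` must lie in [1.8, 2.2] (DNA doubling); got ",
                 format(ratio))
  }
  check_number(cv, "cv", 0, strict_min = TRUE)
  check_number(g2_fraction, "g2_fraction", 0, strict_min = TRUE)
  if (g2_fraction >= 1) stop_bad_arg("`g2_fraction` must be < 1")
  check_number(g2_area_factor, "g2_area_factor", 1)
  structure(list(g1_mode = g1_mode, g2_mode = g2_mode, cv = cv,
                 g2_fraction = g2_fraction, g2_area_factor = g2_area_factor),
            class = "cell_cycle_model")
}

#' @export
print.cell_cycle_model <- function(x, ...) {
  cat(sprintf(
    "<cell_cycle_model> G1 mode %g, G2 mode %g (cv %g), G2 fraction %g, G2 area x%g\n",
    x$g1_mode, x$g2_mode, x$cv, x$g2_fraction, x$g2_area_factor))
  invisible(x)
}
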