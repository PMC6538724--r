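#' Predict NLV and intensity distributions and compare to observations
#'
#' Builds the negative-binomial NLV prediction for an exposure from a fitted
#' model, evaluates a chi-squared goodness of fit against observed per-cell
#' counts (adjacent bins pooled from the upper tail until every expected
#' count is at least 5) and the sup-CDF distance, and, when an intensity
#' model is available, predicts the total per-cell intensity distribution
#' and reports its Kolmogorov-Smirnov distance to the observed totals.
#'
#' @param fit An `uptake_fit` from [fit_uptake_model()], or a list with
#'   elements `area_model` (a [cell_area_model()]), `lam` and optionally
#'   `intensity_model` when the parameters are known rather than fitted.
#' @param exposure An [exposure_condition()] to predict for.
#' @param cells Observed per-cell table for that condition (columns
#'   `nlv_count` and, for the intensity comparison,
#'   `total_nlv_intensity`).
#' @param intensity_method Evaluation route for the compound intensity
#'   distribution (`"numeric"` default, or `"stochastic"`).
#' @param seed RNG seed for the stochastic route.
#' @return An object of class `uptake_prediction` with the predicted pmf
#'   table (`counts`), the GOF summary tibble (`gof`), and the predicted
#'   intensity distribution (`intensity_dist`, possibly `NULL`).
#' @export
predict_and_compare <- function(fit, exposure, cells,
                                intensity_method = "numeric", seed = NULL) {
  stopifnot(inherits(exposure, "exposure_condition"))
  if (exposure$dtp <= 0) stop_bad_arg("exposure dose-time product must be positive")
  if (!"nlv_count" %in% names(cells)) {
    stop_bad_arg("`cells` must contain an `nlv_count` column")
  }
  if (inherits(fit, "uptake_fit")) {
    lam <- fit$lambda_fit$lam_hat
    area_model <- fit$area_model
    imodel <- fit$intensity_model
  } else if (is.list(fit) && inherits(fit$area_model, "cell_area_model") &&
             is.numeric(fit$lam)) {
    lam <- fit$lam
    area_model <- fit$area_model
    imodel <- fit$intensity_model
  } else {
    stop_bad_arg("`fit` must be an uptake_fit or list(area_model=, lam=)")
  }
  obs <- cells$nlv_count
  check_counts(obs, "nlv_count")
  nb <- nb_params(area_model, uptake_model(lam = max(lam, 0)), exposure)

  kmax <- max(obs, ceiling(nb$mean + 12 * sqrt(nb$mean / (1 - nb$p) + 1)))
  k <- 0:kmax
  pk <- dnbinom(k, size = nb$r, prob = 1 - nb$p)
  pk[length(pk)] <- pk[length(pk)] +
    pnbinom(kmax, size = nb$r, prob = 1 - nb$p, lower.tail = FALSE)
  observed <- tabulate(obs + 1L, nbins = kmax + 1L)
  counts <- tibble::tibble(n = k, prob = pk, expected = length(obs) * pk,
                           observed = observed)

  gof <- chisq_pooled(counts$observed, counts$expected)
  emp <- cumsum(observed) / length(obs)
  gof$sup_cdf <- max(abs(emp - cumsum(pk) / sum(pk)))
  gof$mean_observed <- mean(obs)
  gof$mean_predicted <- nb$mean

  idist <- NULL
  if (!is.null(imodel)) {
    idist <- cell_intensity_distribution(nb, imodel,
                                         method = intensity_method,
                                         seed = seed)
    if ("total_nlv_intensity" %in% names(cells)) {
      tot <- cells$total_nlv_intensity
      # compare on CDFs, including the shared atom at zero
      qs <- sort(unique(tot))
      gof$intensity_sup_cdf <-
        max(abs(ecdf(tot)(qs) - cell_intensity_cdf(idist, qs)))
    }
  }
  structure(list(nb = nb, exposure = exposure, counts = counts, gof = gof,
                 intensity_dist = idist, n_cells = length(obs)),
            class = "uptake_prediction")
}

# chi-squared GOF with adjacent-bin pooling so every expected count >= 5;
# a (near-)degenerate prediction keeps two bins, and observed mass on a
# zero-expectation bin is an unconditional rejection
chisq_pooled <- function(observed, expected, min_expected = 5) {
  stopifnot(length(observed) == length(expected))
  o <- observed; e <- expected
  i <- length(e)
  while (i > 2 && e[i] < min_expected) {
    e[i - 1] <- e[i - 1] + e[i]
    o[i - 1] <- o[i - 1] + o[i]
    o <- o[-i]; e <- e[-i]
    i <- i - 1
  }
  while (length(e) > 2 && e[1] < min_expected) {
    e[2] <- e[2] + e[1]; o[2] <- o[2] + o[1]
    o <- o[-1]; e <- e[-1]
  }
  df <- length(e) - 1L
  if (any(e == 0)) {
    if (any(o[e == 0] > 0)) {
      return(tibble::tibble(chisq = Inf, df = df, p_value = 0))
    }
    o <- o[e > 0]; e <- e[e > 0]
    df <- length(e) - 1L
  }
  stat <- sum((o - e)^2 / e)
  tibble::tibble(chisq = stat, df = df,
                 p_value = if (df >= 1) pchisq(stat, df, lower.tail = FALSE)
                           else NA_real_)
}

#' @export
print.uptake_prediction <- function(x, ...) {
  cat(sprintf("<uptake_prediction> C = %g nM, t = %g h: NB(r = %.3g, p = %.3g), mean %.3g\n",
              x$exposure$concentration, x$exposure$duration,
              x$nb$r, x$nb$p, x$nb$mean))
  cat(sprintf("  chi-squared %.2f on %d df (p = %.3g), sup-CDF %.4f over %d cells\n",
              x$gof$chisq, x$gof$df, x$gof$p_value, x$gof$sup_cdf, x$n_cells))
  invisible(x)
}

#' @export
tidy.uptake_prediction <- function(x, ...) x$counts

#' @export
glance.uptake_prediction <- function(x, ...) x$gof

#' @export
autoplot.uptake_prediction <- function(object, ...) {
  df <- tidyr::pivot_longer(object$counts,
                            c("observed", "expected"),
                            names_to = "which", values_to = "cells")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$cells,
                                   fill = .data$which)) +
    ggplot2::geom_col(data = ~ dplyr::filter(.x, .data$which == "observed"),
                      fill = "grey70") +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$which == "expected"),
                       colour = "black") +
    ggplot2::labs(x = "NLVs per cell", y = "cells",
                  subtitle = sprintf("NB mean %.2f, chi-sq p = %.3g",
                                     object$nb$mean, object$gof$p_value))
}
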