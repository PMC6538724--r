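#' Area-percentile quality-control filter
#'
#' Discards mis-segmented cell objects by dropping rows whose area falls
#' strictly outside the 5th-95th percentile interval of the input (linear
#' interpolation percentiles; ties at the boundary are retained). When a
#' `condition_id` column is present the percentiles are computed within each
#' condition, matching per-experiment quality control.
#'
#' @param cells A data frame of per-cell measurements with an area column.
#' @param area_col Name of the area column (default `"area_um2"`).
#' @param lower,upper Percentile bounds (defaults 0.05 and 0.95).
#' @param per_condition Compute percentiles within `condition_id` groups
#'   when that column exists (default `TRUE`).
#' @return The filtered tibble, with attribute `"qc"` summarising rows
#'   removed.
#' @examples
#' cells <- tibble::tibble(area_um2 = 1:100)
#' nrow(qc_filter(cells)) # 90
#' @export
qc_filter <- function(cells, area_col = "area_um2", lower = 0.05,
                      upper = 0.95, per_condition = TRUE) {
  if (!is.data.frame(cells) || nrow(cells) == 0L) {
    stop_bad_arg("`cells` must be a non-empty data frame")
  }
  if (!area_col %in% names(cells)) {
    stop_bad_arg("no column `", area_col, "` in `cells`")
  }
  grouped <- per_condition && "condition_id" %in% names(cells)
  keep_rows <- function(df) {
    q <- quantile(df[[area_col]], c(lower, upper), type = 7, names = FALSE)
    dplyr::filter(df, .data[[area_col]] >= q[1], .data[[area_col]] <= q[2])
  }
  out <- if (grouped) {
    cells |>
      dplyr::group_by(.data$condition_id) |>
      dplyr::group_modify(~ keep_rows(.x)) |>
      dplyr::ungroup() |>
      dplyr::relocate(dplyr::any_of(names(cells)))
  } else {
    keep_rows(tibble::as_tibble(cells))
  }
  attr(out, "qc") <- tibble::tibble(n_in = nrow(cells), n_kept = nrow(out),
                                    n_removed = nrow(cells) - nrow(out))
  out
}

#' Fit the gamma cell-area model
#'
#' Estimates the gamma shape and scale of a population's cell-area
#' distribution, by maximum likelihood (default) or by the method of
#' moments (`shape = mean^2/var`, `scale = var/mean`). For the gamma family
#' the MLE reproduces the sample mean exactly (`shape * scale = mean`),
#' which is what makes the downstream lambda estimate insensitive to the
#' area QC truncation.
#'
#' @param areas Numeric vector of positive areas, or a data frame holding
#'   them.
#' @param method `"mle"` or `"moments"`.
#' @param area_col Area column when `areas` is a data frame.
#' @return A [cell_area_model()] with attribute `"se"` (standard errors,
#'   MLE only) and `"n"`.
#' @examples
#' x <- rgamma(1000, 2, scale = 500)
#' fit_area_gamma(x)
#' @export
fit_area_gamma <- function(areas, method = c("mle", "moments"),
                           area_col = "area_um2") {
  if (is.data.frame(areas)) areas <- areas[[area_col]]
  method <- match.arg(method)
  if (!is.numeric(areas) || length(areas) < 10L) {
    stop_bad_arg("need at least 10 area values")
  }
  if (anyNA(areas) || any(areas <= 0)) {
    stop_bad_arg("areas must be positive and non-missing")
  }
  m <- mean(areas); v <- var(areas)
  a0 <- m^2 / v; b0 <- v / m
  if (method == "moments") {
    out <- cell_area_model(a0, b0)
    attr(out, "se") <- c(shape = NA_real_, scale = NA_real_)
  } else {
    s <- m # rescale for a well-conditioned optimisation
    fit <- fitdistrplus::fitdist(areas / s, "gamma",
                                 start = list(shape = a0, rate = s / b0))
    est <- fit$estimate
    se <- fit$sd
    out <- cell_area_model(unname(est["shape"]), s / unname(est["rate"]))
    attr(out, "se") <- c(shape = unname(se["shape"]),
                         scale = s * unname(se["rate"]) / est["rate"]^2)
  }
  attr(out, "n") <- length(areas)
  attr(out, "method") <- method
  out
}

#' Per-condition mean NLV counts
#'
#' Summarises a cell table into one row per exposure condition: the
#' dose-time product, the number of cells, and the mean NLV count with its
#' standard error. This is the input to the lambda line fit.
#'
#' @param cells A cell table with `condition_id`, `concentration_nM`,
#'   `duration_h` and `nlv_count` columns.
#' @return A tibble with columns `condition_id`, `dtp`, `n`, `mean_nlv`,
#'   `se`.
#' @export
mean_nlv_by_condition <- function(cells) {
  needed <- c("condition_id", "concentration_nM", "duration_h", "nlv_count")
  missing <- setdiff(needed, names(cells))
  if (length(missing)) {
    stop_bad_arg("cell table is missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  cells |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      dtp = .data$concentration_nM[1] * .data$duration_h[1],
      n = dplyr::n(),
      mean_nlv = mean(.data$nlv_count),
      se = sd(.data$nlv_count) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$dtp)
}

#' Estimate the uptake rate constant lambda
#'
#' Ordinary least squares of per-condition mean NLV count on the dose-time
#' product (a first-order polynomial with free intercept), then
#' `lambda = slope / (shape * scale)` using the fitted area model. The
#' intercept is reported with its confidence interval as a model-adequacy
#' diagnostic: the linear mean law predicts an intercept of zero.
#'
#' @param cond_means A data frame with columns `dtp` and `mean_nlv`
#'   (optionally `se` and `n`), e.g. from [mean_nlv_by_condition()].
#' @param area_model A fitted [cell_area_model()].
#' @param weights `NULL` for unweighted OLS (default) or `"inv_var"` for
#'   inverse-variance weighting by the per-condition squared standard
#'   error.
#' @return A list of class `lambda_fit`: `lam_hat`, `lam_se`, `slope`,
#'   `intercept` (with SEs and the intercept 95% CI), the underlying `lm`
#'   fit, and the input table.
#' @examples
#' cm <- tibble::tibble(dtp = c(1, 2, 4), mean_nlv = c(2, 4, 8))
#' estimate_lambda(cm, cell_area_model(2, 500))$lam_hat # 2/1000
#' @export
estimate_lambda <- function(cond_means, area_model, weights = NULL) {
  stopifnot(inherits(area_model, "cell_area_model"))
  if (!is.data.frame(cond_means) ||
      !all(c("dtp", "mean_nlv") %in% names(cond_means))) {
    stop_bad_arg("`cond_means` needs columns `dtp` and `mean_nlv`")
  }
  if (length(unique(cond_means$dtp)) < 2L) {
    stop_bad_arg("need at least 2 distinct dose-time products to fit a line")
  }
  w <- NULL
  if (identical(weights, "inv_var")) {
    if (!"se" %in% names(cond_means)) {
      stop_bad_arg("inverse-variance weighting needs an `se` column")
    }
    w <- 1 / cond_means$se^2
  } else if (!is.null(weights)) {
    stop_bad_arg("`weights` must be NULL or \"inv_var\"")
  }
  fit <- lm(mean_nlv ~ dtp, data = cond_means, weights = w)
  cf <- summary(fit)$coefficients
  ab <- area_model$shape * area_model$scale
  ci <- suppressWarnings(confint(fit))
  structure(list(
    lam_hat = cf["dtp", "Estimate"] / ab,
    lam_se = cf["dtp", "Std. Error"] / ab,
    slope = cf["dtp", "Estimate"],
    slope_se = cf["dtp", "Std. Error"],
    intercept = cf["(Intercept)", "Estimate"],
    intercept_se = cf["(Intercept)", "Std. Error"],
    intercept_ci = unname(ci["(Intercept)", ]),
    area_model = area_model,
    lm = fit,
    cond_means = tibble::as_tibble(cond_means)
  ), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("<lambda_fit> lambda = %.5g (se %.2g) per nM per h per area unit\n",
              x$lam_hat, x$lam_se))
  cat(sprintf("  slope %.4g (se %.2g); intercept %.4g [%.4g, %.4g]\n",
              x$slope, x$slope_se, x$intercept,
              x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Simultaneous per-vesicle intensity fit
#'
#' Fits one shared intensity distribution to the pooled per-vesicle
#' intensities of all exposure conditions (maximum likelihood), then
#' reports the per-condition one-sample Kolmogorov-Smirnov distance to the
#' shared fit as the dose-invariance diagnostic: under invariance all
#' conditions sit close to the common curve, while a shifted condition
#' stands out.
#'
#' @param nlvs A data frame of per-vesicle rows with an intensity column
#'   and (optionally) `condition_id`, or a numeric vector.
#' @param family `"lognormal"` or `"gamma"`.
#' @param intensity_col Intensity column name.
#' @return An [intensity_model()] with attributes `"se"`, `"n"` and
#'   `"condition_ks"` (tibble of per-condition KS distances).
#' @export
fit_intensity_simultaneous <- function(nlvs, family = c("lognormal", "gamma"),
                                       intensity_col = "intensity") {
  family <- match.arg(family)
  if (is.data.frame(nlvs)) {
    x <- nlvs[[intensity_col]]
    cond <- if ("condition_id" %in% names(nlvs)) nlvs$condition_id
  } else {
    x <- nlvs
    cond <- NULL
  }
  if (!is.numeric(x) || length(x) < 100L) {
    stop_bad_arg("need at least 100 intensities for a pooled fit")
  }
  if (anyNA(x) || any(x <= 0)) stop_bad_arg("intensities must be positive")
  n <- length(x)
  if (family == "lognormal") {
    lx <- log(x)
    ml <- mean(lx)
    sl <- sqrt(mean((lx - ml)^2))
    model <- intensity_model("lognormal", meanlog = ml, sdlog = sl)
    se <- c(meanlog = sl / sqrt(n), sdlog = sl / sqrt(2 * n))
  } else {
    s <- mean(x)
    fit <- fitdistrplus::fitdist(x / s, "gamma")
    est <- fit$estimate
    model <- intensity_model("gamma", shape = unname(est["shape"]),
                             scale = s / unname(est["rate"]))
    se <- c(shape = unname(fit$sd["shape"]),
            scale = s * unname(fit$sd["rate"]) / est["rate"]^2)
  }
  attr(model, "se") <- se
  attr(model, "n") <- n
  if (!is.null(cond)) {
    ks <- tibble::tibble(condition_id = unique(cond))
    ks$n <- vapply(ks$condition_id, function(id) sum(cond == id), integer(1))
    ks$ks_distance <- vapply(ks$condition_id, function(id) {
      xi <- x[cond == id]
      unname(suppressWarnings(
        ks.test(xi, function(q) intensity_cdf(model, q))$statistic))
    }, numeric(1))
    attr(model, "condition_ks") <- ks
  }
  model
}

#' Fit the full uptake model to measurement tables
#'
#' The calibration pipeline: area QC filter, pooled gamma fit to cell
#' areas, per-condition mean NLV counts, lambda from the mean-versus-DTP
#' line, and the simultaneous per-vesicle intensity fit.
#'
#' @param cells Per-cell table (schema of [generate_population()], or
#'   remapped via [read_nlv_tables()]).
#' @param nlvs Per-vesicle table; may be `NULL` to skip the intensity fit.
#' @param family Intensity family for the pooled fit.
#' @param qc Apply [qc_filter()] first (default `TRUE`).
#' @param area_method Passed to [fit_area_gamma()].
#' @param weights Passed to [estimate_lambda()].
#' @return An object of class `uptake_fit` with elements `area_model`,
#'   `lambda_fit`, `intensity_model`, `cond_means`, `qc` and `n_cells`.
#' @examples
#' tabs <- generate_exposure_grid(study_grid(), 300, cell_area_model(2, 1500),
#'                                uptake_model(lam = 0.00107), seed = 1)
#' fit <- fit_uptake_model(tabs$cells, tabs$nlvs)
#' glance(fit)
#' @export
fit_uptake_model <- function(cells, nlvs = NULL, family = "lognormal",
                             qc = TRUE, area_method = "mle", weights = NULL) {
  validate_cell_table(cells)
  kept <- if (qc) qc_filter(cells) else tibble::as_tibble(cells)
  area_model <- fit_area_gamma(kept, method = area_method)
  cond_means <- mean_nlv_by_condition(kept)
  lam <- estimate_lambda(cond_means, area_model, weights = weights)
  imodel <- NULL
  if (!is.null(nlvs) && nrow(nlvs) >= 100) {
    keep_nlvs <- nlvs
    if (all(c("cell_id", "condition_id") %in% names(nlvs)) &&
        "condition_id" %in% names(kept)) {
      keep_nlvs <- dplyr::semi_join(nlvs, kept,
                                    by = c("cell_id", "condition_id"))
    }
    imodel <- fit_intensity_simultaneous(keep_nlvs, family = family)
  }
  structure(list(
    area_model = area_model,
    lambda_fit = lam,
    intensity_model = imodel,
    cond_means = cond_means,
    qc = attr(kept, "qc"),
    n_cells = nrow(kept)
  ), class = "uptake_fit")
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat("<uptake_fit>\n")
  cat(sprintf("  area: gamma(shape %.3g, scale %.4g), %d cells after QC\n",
              x$area_model$shape, x$area_model$scale, x$n_cells))
  cat(sprintf("  lambda: %.5g (se %.2g) per nM per h per area unit\n",
              x$lambda_fit$lam_hat, x$lambda_fit$lam_se))
  if (!is.null(x$intensity_model)) {
    cat(sprintf("  vesicle intensity: %s fit pooled over %d vesicles\n",
                x$intensity_model$family, attr(x$intensity_model, "n")))
  }
  invisible(x)
}

#' @export
tidy.uptake_fit <- function(x, ...) {
  ase <- attr(x$area_model, "se")
  rows <- list(
    tibble::tibble(term = c("area_shape", "area_scale"),
                   estimate = c(x$area_model$shape, x$area_model$scale),
                   std_error = unname(ase[c("shape", "scale")])),
    tibble::tibble(term = c("lambda", "slope", "intercept"),
                   estimate = c(x$lambda_fit$lam_hat, x$lambda_fit$slope,
                                x$lambda_fit$intercept),
                   std_error = c(x$lambda_fit$lam_se, x$lambda_fit$slope_se,
                                 x$lambda_fit$intercept_se))
  )
  if (!is.null(x$intensity_model)) {
    ise <- attr(x$intensity_model, "se")
    rows <- c(rows, list(tibble::tibble(
      term = paste0("intensity_", names(x$intensity_model$params)),
      estimate = unlist(x$intensity_model$params, use.names = FALSE),
      std_error = unname(ise[names(x$intensity_model$params)])
    )))
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.uptake_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda_fit$lam_hat,
    lambda_se = x$lambda_fit$lam_se,
    intercept = x$lambda_fit$intercept,
    r_squared = summary(x$lambda_fit$lm)$r.squared,
    mean_area = area_mean(x$area_model),
    n_cells = x$n_cells,
    n_conditions = nrow(x$cond_means)
  )
}

#' @export
autoplot.uptake_fit <- function(object, ...) {
  cm <- object$cond_means
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$dtp, y = .data$mean_nlv)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_nlv - .data$se,
                                        ymax = .data$mean_nlv + .data$se),
                           width = 0) +
    ggplot2::geom_abline(slope = object$lambda_fit$slope,
                         intercept = object$lambda_fit$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "dose-time product (nM h)", y = "mean NLVs per cell")
}
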