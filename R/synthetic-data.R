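#' Generate CellProfiler-style per-cell and per-vesicle tables
#'
#' Draws a synthetic imaged population with the statistical structure the
#' uptake model assumes: gamma-distributed cell areas (G2 cells scaled up by
#' the cycle model's area factor), per-cell NLV counts Poisson with rate
#' `lam * area * C * t`, per-vesicle intensities i.i.d. from a single
#' dose-invariant intensity model, and bimodal G1/G2 nuclear (DNA content)
#' intensities. Output mimics post-segmentation measurement tables: one row
#' per cell and one row per nanoparticle-loaded vesicle, linked by
#' `cell_id`.
#'
#' @param n_cells Number of cells to draw, `>= 1`.
#' @param areas A [cell_area_model()].
#' @param uptake An [uptake_model()].
#' @param exposure An [exposure_condition()].
#' @param intensity An [intensity_model()] for per-vesicle intensity.
#' @param cycle A [cell_cycle_model()].
#' @param seed Optional RNG seed; a fixed seed gives identical tables.
#' @param noise_cv Optional multiplicative lognormal measurement noise
#'   (coefficient of variation) applied to vesicle intensities; default 0
#'   (off) so analytic identities hold exactly.
#' @param condition_id Identifier recorded in both tables (default derived
#'   from the exposure).
#' @return A list of class `nlv_tables` with elements `cells` (tibble:
#'   `cell_id`, `condition_id`, `concentration_nM`, `duration_h`,
#'   `area_um2`, `nuclear_intensity`, `phase`, `nlv_count`,
#'   `total_nlv_intensity`) and `nlvs` (tibble: `nlv_id`, `cell_id`,
#'   `condition_id`, `intensity`). The generating parameters and seed are
#'   attached as attribute `"params"`.
#' @examples
#' tabs <- generate_population(500, cell_area_model(2, 500),
#'                             uptake_model(lam = 0.002),
#'                             exposure_condition(2, 1), seed = 1)
#' head(tabs$cells)
#' @export
generate_population <- function(n_cells, areas, uptake, exposure,
                                intensity = intensity_model(),
                                cycle = cell_cycle_model(),
                                seed = NULL, noise_cv = 0,
                                condition_id = NULL) {
  check_number(n_cells, "n_cells", 1)
  n_cells <- as.integer(n_cells)
  stopifnot(inherits(areas, "cell_area_model"),
            inherits(uptake, "uptake_model"),
            inherits(exposure, "exposure_condition"),
            inherits(intensity, "intensity_model"),
            inherits(cycle, "cell_cycle_model"))
  check_number(noise_cv, "noise_cv", 0)
  condition_id <- condition_id %||%
    sprintf("C%g_t%g", exposure$concentration, exposure$duration)
  with_seed(seed, {
    g2 <- rbinom(n_cells, 1L, cycle$g2_fraction) == 1L
    area <- rgamma(n_cells, shape = areas$shape, scale = areas$scale)
    area[g2] <- area[g2] * cycle$g2_area_factor
    mode <- ifelse(g2, cycle$g2_mode, cycle$g1_mode)
    nuclear <- rnorm(n_cells, mean = mode, sd = cycle$cv * mode)
    while (any(bad <- nuclear <= 0)) { # truncation at 0; essentially never fires
      nuclear[bad] <- rnorm(sum(bad), mean = mode[bad],
                            sd = cycle$cv * mode[bad])
    }
    counts <- rpois(n_cells, uptake$lam * area * exposure$dtp)
    n_nlv <- sum(counts)
    ivals <- intensity_rand(intensity, n_nlv)
    if (noise_cv > 0) {
      sdl <- sqrt(log(1 + noise_cv^2))
      ivals <- ivals * rlnorm(n_nlv, -sdl^2 / 2, sdl)
    }
    parent <- rep.int(seq_len(n_cells), counts)
    total <- numeric(n_cells)
    if (n_nlv > 0) {
      sums <- rowsum(ivals, parent)
      total[as.integer(rownames(sums))] <- sums[, 1]
    }
    cells <- tibble::tibble(
      cell_id = seq_len(n_cells),
      condition_id = condition_id,
      concentration_nM = exposure$concentration,
      duration_h = exposure$duration,
      area_um2 = area,
      nuclear_intensity = nuclear,
      phase = ifelse(g2, "G2", "G1"),
      nlv_count = counts,
      total_nlv_intensity = total
    )
    nlvs <- tibble::tibble(
      nlv_id = seq_len(n_nlv),
      cell_id = parent,
      condition_id = condition_id,
      intensity = ivals
    )
    structure(
      list(cells = cells, nlvs = nlvs),
      class = "nlv_tables",
      params = list(
        n_cells = n_cells, alpha = areas$shape, beta = areas$scale,
        lam = uptake$lam, concentration_nM = exposure$concentration,
        duration_h = exposure$duration,
        intensity_family = intensity$family,
        intensity_params = intensity$params,
        cycle = unclass(cycle), noise_cv = noise_cv, seed = seed
      )
    )
  })
}

#' @export
print.nlv_tables <- function(x, ...) {
  cat(sprintf("<nlv_tables> %d cells, %d NLVs, %d condition(s)\n",
              nrow(x$cells), nrow(x$nlvs),
              length(unique(x$cells$condition_id))))
  invisible(x)
}

#' The 12-condition study exposure grid
#'
#' Administered doses of 0.5, 2, 4 and 5 nM crossed with exposure durations
#' of 0.5, 1 and 2 h, spanning a 40-fold range of dose-time product (16-fold
#' between the commonly compared 0.25 and 4 nM h corners of the design).
#'
#' @param concentrations Concentrations in nM.
#' @param durations Durations in hours.
#' @return A list of [exposure_condition()] objects.
#' @export
study_grid <- function(concentrations = c(0.5, 2, 4, 5),
                       durations = c(0.5, 1, 2)) {
  conds <- expand.grid(concentration = concentrations, duration = durations,
                       KEEP.OUT.ATTRS = FALSE)
  purrr::pmap(conds, exposure_condition)
}

#' Generate tables across an exposure grid
#'
#' Runs [generate_population()] once per exposure condition with
#' per-condition seeds derived deterministically from the master seed, and
#' binds the results into a single pair of tables distinguished by
#' `condition_id`.
#'
#' @param conditions A list of [exposure_condition()] objects (e.g.
#'   [study_grid()]).
#' @param n_cells Cells per condition (scalar or one per condition).
#' @inheritParams generate_population
#' @return An `nlv_tables` list covering all conditions; `nlv_id` is unique
#'   within a condition.
#' @examples
#' grid <- generate_exposure_grid(study_grid(), n_cells = 200,
#'                                areas = cell_area_model(2, 1500),
#'                                uptake = uptake_model(lam = 0.00107),
#'                                seed = 1)
#' dplyr::count(grid$cells, condition_id)
#' @export
generate_exposure_grid <- function(conditions, n_cells, areas, uptake,
                                   intensity = intensity_model(),
                                   cycle = cell_cycle_model(),
                                   seed = NULL, noise_cv = 0) {
  if (!is.list(conditions) || length(conditions) == 0L) {
    stop_bad_arg("`conditions` must be a non-empty list of exposure_condition")
  }
  ids <- vapply(conditions, function(e) {
    stopifnot(inherits(e, "exposure_condition"))
    sprintf("C%g_t%g", e$concentration, e$duration)
  }, character(1))
  if (anyDuplicated(ids)) {
    stop_bad_arg("duplicate condition identifiers: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n_cells <- rep_len(n_cells, length(conditions))
  parts <- purrr::imap(conditions, function(e, i) {
    generate_population(n_cells[i], areas, uptake, e, intensity, cycle,
                        seed = derive_seed(seed, i), noise_cv = noise_cv,
                        condition_id = ids[i])
  })
  out <- list(
    cells = dplyr::bind_rows(purrr::map(parts, "cells")),
    nlvs = dplyr::bind_rows(purrr::map(parts, "nlvs"))
  )
  structure(out, class = "nlv_tables",
            params = list(master_seed = seed,
                          conditions = purrr::map(parts, attr, "params")))
}

#' Write or read measurement tables
#'
#' `write_nlv_tables()` writes `Cells.csv` and `NLVs.csv` (UTF-8,
#' comma-separated, headered) plus a `generation_params.json` manifest
#' recording the generating parameters and seed. `read_nlv_tables()` reads them back,
#' optionally remapping column names from an arbitrary segmentation export
#' via `column_map` (keys `area_col`, `nuclear_col`, `nlv_count_col`,
#' `intensity_col`).
#'
#' @param tables An `nlv_tables` list.
#' @param dir Output/input directory.
#' @param force Overwrite existing tables (default `FALSE`; refusing to
#'   overwrite keeps runs from silently clobbering artefacts).
#' @return `write_nlv_tables()` invisibly returns the written paths;
#'   `read_nlv_tables()` returns an `nlv_tables` list.
#' @export
write_nlv_tables <- function(tables, dir, force = FALSE) {
  stopifnot(inherits(tables, "nlv_tables"))
  paths <- file.path(dir, c("Cells.csv", "NLVs.csv", "generation_params.json"))
  if (!force && any(file.exists(paths[1:2]))) {
    stop_bad_arg("output tables already exist in `", dir,
                 "`; use force = TRUE to overwrite")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tables$cells, paths[1])
  readr::write_csv(tables$nlvs, paths[2])
  jsonlite::write_json(attr(tables, "params") %||% list(), paths[3],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(paths)
}

#' @rdname write_nlv_tables
#' @param column_map Optional named list renaming external columns onto the
#'   package schema.
#' @export
read_nlv_tables <- function(dir, column_map = NULL) {
  cells <- readr::read_csv(file.path(dir, "Cells.csv"),
                           show_col_types = FALSE)
  nlvs <- readr::read_csv(file.path(dir, "NLVs.csv"), show_col_types = FALSE)
  if (!is.null(column_map)) {
    ren <- c(area_um2 = column_map$area_col,
             nuclear_intensity = column_map$nuclear_col,
             nlv_count = column_map$nlv_count_col)
    ren <- ren[!vapply(ren, is.null, logical(1))]
    cells <- dplyr::rename(cells, dplyr::all_of(unlist(ren)))
    if (!is.null(column_map$intensity_col)) {
      nlvs <- dplyr::rename(nlvs,
                            intensity = dplyr::all_of(column_map$intensity_col))
    }
  }
  validate_cell_table(cells)
  structure(list(cells = cells, nlvs = nlvs), class = "nlv_tables")
}

validate_cell_table <- function(cells,
                                required = c("cell_id", "area_um2",
                                             "nlv_count")) {
  missing <- setdiff(required, names(cells))
  if (length(missing)) {
    stop_bad_arg("cell table is missing required column(s): ",
                 paste(missing, collapse = ", "),
                 " (supply a `column_map` to rename external exports)")
  }
  invisible(cells)
}
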