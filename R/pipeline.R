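#' Default pipeline configuration
#'
#' The resolved configuration is a plain named list, serialisable to
#' YAML/JSON. Top-level keys: `stages` (subset of `"generate"`, `"fit"`,
#' `"predict"`, `"cellcycle"`, run in that dependency order), `seed`,
#' `n_cells` (per condition), the generating/fitting parameters (`alpha`,
#' `beta`, `lam`, `concentrations_nM`, `durations_h`, `intensity_family`,
#' `intensity_params`, `cycle`), `input_dir` (tables to analyse when the
#' `generate` stage is not run) and `column_map` (renaming for external
#' CellProfiler-style exports).
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    stages = c("generate", "fit", "predict", "cellcycle"),
    seed = 1L,
    n_cells = 1000L,
    alpha = 2,
    beta = 1500,
    lam = 0.00107,
    concentrations_nM = c(0.5, 2, 4, 5),
    durations_h = c(0.5, 1, 2),
    intensity_family = "lognormal",
    intensity_params = list(meanlog = log(500), sdlog = 0.5),
    cycle = list(g1_mode = 200, g2_mode = 400, cv = 0.07,
                 g2_fraction = 0.3, g2_area_factor = 1.6),
    noise_cv = 0,
    input_dir = NULL,
    column_map = NULL,
    gate_method = "mixture"
  )
}

read_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_bad_arg("config file not found: ", config)
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      return(jsonlite::read_json(config, simplifyVector = TRUE))
    }
    return(yaml::read_yaml(config))
  }
  if (is.list(config)) return(config)
  stop_bad_arg("`config` must be a file path or a named list")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on one output
#' directory: `generate` draws the synthetic exposure grid and writes
#' `Cells.csv`/`NLVs.csv`; `fit` runs the calibration pipeline (QC, gamma
#' area fit, lambda line fit, pooled intensity fit) and writes
#' `fit_result.json`; `predict` writes per-condition predicted-vs-observed
#' count tables and goodness-of-fit summaries; `cellcycle` gates G1/G2 and
#' writes raw and per-area Kolmogorov-Smirnov comparisons. A
#' `manifest.json` records every artefact with an MD5 content hash, the
#' resolved configuration, and stage timings; identical config and seed
#' give byte-identical artefacts.
#'
#' @param config A named list or path to a YAML/JSON file; entries override
#'   [default_config()].
#' @param out_dir Output directory for all artefacts.
#' @param seed Master seed override (takes precedence over the config
#'   file).
#' @param force Overwrite existing artefacts (default `FALSE`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest as a list.
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "nlv-run")
#' run_pipeline(list(n_cells = 200), out_dir = out, seed = 1, force = TRUE)
#' }
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL, force = FALSE,
                         quiet = FALSE) {
  cfg <- utils::modifyList(default_config(), read_config(config))
  if (!is.null(seed)) cfg$seed <- seed
  if (identical(cfg$stages, "reproduce")) {
    cfg$stages <- c("generate", "fit", "predict", "cellcycle")
  }
  stages <- match.arg(cfg$stages,
                      c("generate", "fit", "predict", "cellcycle"),
                      several.ok = TRUE)
  stages <- intersect(c("generate", "fit", "predict", "cellcycle"), stages)
  if (missing(out_dir) || is.null(out_dir)) stop_bad_arg("`out_dir` is required")
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    stop_bad_arg("`", out_dir, "` already holds pipeline output; ",
                 "use force = TRUE to overwrite")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  timings <- list()
  artefacts <- character(0)
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  areas <- cell_area_model(cfg$alpha, cfg$beta)
  uptake <- uptake_model(lam = cfg$lam)
  imodel <- do.call(intensity_model,
                    c(list(family = cfg$intensity_family), cfg$intensity_params))
  cycle <- do.call(cell_cycle_model, cfg$cycle)
  conds <- study_grid(cfg$concentrations_nM, cfg$durations_h)

  tables <- NULL
  if ("generate" %in% stages) {
    say("stage generate: ", length(conds), " conditions x ", cfg$n_cells,
        " cells")
    tables <- clock("generate",
      generate_exposure_grid(conds, cfg$n_cells, areas, uptake, imodel,
                             cycle, seed = cfg$seed, noise_cv = cfg$noise_cv))
    write_nlv_tables(tables, out_dir, force = TRUE)
    artefacts <- c(artefacts, "Cells.csv", "NLVs.csv",
                   "generation_params.json")
  } else {
    if (is.null(cfg$input_dir)) {
      stop_bad_arg("stage `", setdiff(stages, "generate")[1],
                   "` needs tables: run the generate stage or set `input_dir`")
    }
    say("reading tables from ", cfg$input_dir)
    tables <- read_nlv_tables(cfg$input_dir, column_map = cfg$column_map)
  }

  fit <- NULL
  if (any(c("fit", "predict") %in% stages)) {
    say("stage fit: calibrating on ", nrow(tables$cells), " cells")
    fit <- clock("fit", fit_uptake_model(tables$cells, tables$nlvs,
                                         family = cfg$intensity_family))
    fit_json <- list(
      parameters = tidy(fit),
      summary = glance(fit),
      per_condition_means = fit$cond_means,
      intensity_condition_ks =
        if (!is.null(fit$intensity_model)) attr(fit$intensity_model, "condition_ks")
    )
    jsonlite::write_json(fit_json, file.path(out_dir, "fit_result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", null = "null")
    artefacts <- c(artefacts, "fit_result.json")
  }

  if ("predict" %in% stages) {
    say("stage predict: per-condition goodness of fit")
    pred <- clock("predict", {
      # compare on the same QC'd population the calibration used
      kept <- qc_filter(tables$cells)
      ids <- unique(kept$condition_id)
      purrr::map(ids, function(id) {
        sub <- dplyr::filter(kept, .data$condition_id == id)
        expo <- exposure_condition(sub$concentration_nM[1], sub$duration_h[1])
        p <- predict_and_compare(fit, expo, sub)
        list(id = id,
             counts = dplyr::mutate(p$counts, condition_id = id,
                                    .before = 1),
             gof = dplyr::mutate(p$gof, condition_id = id, .before = 1))
      })
    })
    readr::write_csv(dplyr::bind_rows(purrr::map(pred, "counts")),
                     file.path(out_dir, "predicted_counts.csv"))
    readr::write_csv(dplyr::bind_rows(purrr::map(pred, "gof")),
                     file.path(out_dir, "prediction_gof.csv"))
    artefacts <- c(artefacts, "predicted_counts.csv", "prediction_gof.csv")
  }

  if ("cellcycle" %in% stages) {
    say("stage cellcycle: G1/G2 gating and KS comparisons")
    cc <- clock("cellcycle", {
      gates <- if (identical(cfg$gate_method, "model")) {
        gates_from_model(cycle)
      } else {
        derive_gates(tables$cells$nuclear_intensity, method = "mixture")
      }
      raw <- compare_g1_g2(tables$cells, gates, "none")
      norm <- compare_g1_g2(tables$cells, gates, "per_area")
      list(gates = gates, raw = raw, norm = norm)
    })
    readr::write_csv(cc$norm$gated, file.path(out_dir, "cellcycle_gated.csv"))
    jsonlite::write_json(
      list(gates = unclass(cc$gates),
           raw = cc$raw$ks, per_area = cc$norm$ks,
           summary_raw = cc$raw$summary, summary_per_area = cc$norm$summary),
      file.path(out_dir, "cellcycle.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
    artefacts <- c(artefacts, "cellcycle_gated.csv", "cellcycle.json")
  }

  jsonlite::write_json(
    list(resolved_config = cfg[!vapply(cfg, is.null, logical(1))],
         stages = stages),
    file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artefacts <- unique(c(artefacts, "config.json"))
  files <- setdiff(artefacts, "manifest.json")
  manifest <- list(
    artefacts = lapply(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }),
    timings_s = timings,
    seed = cfg$seed
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("wrote ", length(files) + 1, " artefacts to ", out_dir)
  invisible(manifest)
}
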