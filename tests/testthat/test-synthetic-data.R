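test_that("zero uptake rate yields all-zero counts and an empty vesicle table", {
  tabs <- generate_population(100, default_area(), uptake_model(lam = 0),
                              exposure_condition(2, 1), seed = 1)
  expect_true(all(tabs$cells$nlv_count == 0))
  expect_equal(nrow(tabs$nlvs), 0)
  expect_true(all(tabs$cells$total_nlv_intensity == 0))
})

test_that("cell and vesicle tables reconcile exactly", {
  tabs <- generate_population(2000, default_area(), uptake_model(lam = 0.002),
                              exposure_condition(2, 1), seed = 2)
  per_cell <- dplyr::summarise(dplyr::group_by(tabs$nlvs, cell_id),
                               n = dplyr::n(), tot = sum(intensity))
  merged <- dplyr::left_join(tabs$cells, per_cell, by = "cell_id")
  merged$n[is.na(merged$n)] <- 0L
  merged$tot[is.na(merged$tot)] <- 0
  expect_identical(merged$nlv_count, merged$n)
  expect_equal(merged$total_nlv_intensity, merged$tot, tolerance = 1e-12)
  # every vesicle has a parent cell
  expect_true(all(tabs$nlvs$cell_id %in% tabs$cells$cell_id))
  expect_true(all(tabs$nlvs$intensity > 0))
})

test_that("identical seed and parameters give identical tables", {
  args <- list(500, default_area(), uptake_model(lam = 0.002),
               exposure_condition(4, 1))
  t1 <- do.call(generate_population, c(args, seed = 33))
  t2 <- do.call(generate_population, c(args, seed = 33))
  expect_identical(t1$cells, t2$cells)
  expect_identical(t1$nlvs, t2$nlvs)
})

test_that("areas are marginally gamma when the G2 area coupling is off", {
  tabs <- generate_population(1e4, default_area(), uptake_model(lam = 0.002),
                              exposure_condition(2, 1), cycle = flat_cycle(),
                              seed = 4)
  ks <- suppressWarnings(
    ks.test(tabs$cells$area_um2, pgamma, shape = 2, scale = 500))
  expect_gt(ks$p.value, 0.01)
})

test_that("generated counts follow the analytic negative binomial", {
  tabs <- generate_population(1e4, default_area(), uptake_model(lam = 0.002),
                              exposure_condition(2, 1), cycle = flat_cycle(),
                              seed = 5)
  counts <- tabs$cells$nlv_count
  k <- 0:max(counts)
  pk <- nlv_pmf_population(k, default_area(), uptake_model(lam = 0.002),
                           exposure_condition(2, 1))
  pk[length(pk)] <- pk[length(pk)] + (1 - sum(pk))
  obs <- tabulate(counts + 1L, nbins = length(k))
  gof <- nlvuptake:::chisq_pooled(obs, length(counts) * pk)
  expect_gt(gof$p_value, 0.01)
})

test_that("per-vesicle intensity is invariant across the dose-time product", {
  mk <- function(conc, t, seed) {
    generate_population(6000, default_area(), uptake_model(lam = 0.002),
                        exposure_condition(conc, t), seed = seed)$nlvs$intensity
  }
  i_low <- mk(2, 1, 6) # dtp 2, ~ 2.4e4 vesicles
  i_high <- mk(5, 1, 7) # dtp 5
  expect_gt(length(i_low), 1e4)
  expect_gt(length(i_high), 1e4)
  expect_lt(ks_two_sample(i_low, i_high)$statistic, 0.02)
})

test_that("the exposure grid spans the design and recovers the mean law", {
  tabs <- generate_exposure_grid(study_grid(), 1000, grid_area(),
                                 uptake_model(lam = 0.00107),
                                 cycle = flat_cycle(), seed = 8)
  cm <- mean_nlv_by_condition(tabs$cells)
  expect_equal(nrow(cm), 12)
  expect_equal(max(cm$dtp) / min(cm$dtp), 40) # 0.25 .. 10 nM h
  fit <- lm(mean_nlv ~ dtp, data = cm)
  slope <- coef(fit)[["dtp"]]
  # analytic slope standard error from the known NB per-condition variances
  m_i <- 0.00107 * 3000 * cm$dtp
  var_mean <- (m_i + m_i^2 / 2) / cm$n
  xc <- cm$dtp - mean(cm$dtp)
  se_analytic <- sqrt(sum(xc^2 * var_mean)) / sum(xc^2)
  expect_lt(abs(slope - 0.00107 * 3000), 3 * se_analytic)
})

test_that("grid generation is seeded per condition and rejects duplicates", {
  conds <- study_grid(c(2, 4), 1)
  t1 <- generate_exposure_grid(conds, 200, default_area(),
                               uptake_model(lam = 0.002), seed = 9)
  t2 <- generate_exposure_grid(conds, 200, default_area(),
                               uptake_model(lam = 0.002), seed = 9)
  expect_identical(t1$cells, t2$cells)
  expect_setequal(unique(t1$cells$condition_id), c("C2_t1", "C4_t1"))
  expect_error(
    generate_exposure_grid(c(conds, conds[1]), 100, default_area(),
                           uptake_model(lam = 0.002), seed = 1),
    "duplicate")
})

test_that("tables round-trip through CSV with a manifest", {
  dir <- local_tempdir()
  tabs <- generate_population(300, default_area(), uptake_model(lam = 0.002),
                              exposure_condition(2, 1), seed = 10)
  paths <- write_nlv_tables(tabs, dir)
  expect_true(all(file.exists(paths)))
  expect_error(write_nlv_tables(tabs, dir), "force")
  back <- read_nlv_tables(dir)
  expect_equal(as.data.frame(back$cells), as.data.frame(tabs$cells),
               tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "generation_params.json"))
  expect_equal(manifest$seed, 10)
  expect_equal(manifest$lam, 0.002)
})

test_that("column mapping adapts external table schemas", {
  dir <- local_tempdir()
  tabs <- generate_population(150, default_area(), uptake_model(lam = 0.002),
                              exposure_condition(2, 1), seed = 11)
  ext <- tabs
  ext$cells <- dplyr::rename(ext$cells, AreaShape_Area = area_um2,
                             Children_NLV_Count = nlv_count)
  ext$nlvs <- dplyr::rename(ext$nlvs, Intensity_IntegratedIntensity = intensity)
  write_nlv_tables(ext, dir)
  back <- read_nlv_tables(dir, column_map = list(
    area_col = "AreaShape_Area", nlv_count_col = "Children_NLV_Count",
    intensity_col = "Intensity_IntegratedIntensity"))
  expect_true(all(c("area_um2", "nlv_count") %in% names(back$cells)))
  expect_true("intensity" %in% names(back$nlvs))
  expect_error(read_nlv_tables(dir), "column_map")
})
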