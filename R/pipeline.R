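#' Pipeline configuration
#'
#' One structured configuration drives the whole analysis: either a
#' [scenario_spec()] (synthetic world) or paths to a Newick tree, a
#' long-format occurrence CSV plus a cell table, a layers CSV and a
#' protection CSV. Every stochastic stage has a named seed derived from
#' `seed`. The configuration can be written to / read from JSON.
#'
#' @param scenario a [scenario_spec()], or `NULL` when file inputs are given.
#' @param tree_file,occurrence_file,cells_file,layers_file,protection_file
#'   input paths used when `scenario` is `NULL`.
#' @param n_iter randomization iterations for the CANAPE null.
#' @param alpha two-tailed significance level.
#' @param strict_both_pe mixed-category variant flag, see [canape_classify()].
#' @param min_richness cell filter threshold.
#' @param predictors layer names entering the driver models.
#' @param threat_layers layer names compared between hotspot classes.
#' @param k_scan neighbour counts scanned for the SAR-error weights.
#' @param n_perm permutations for the group comparisons.
#' @param seed master seed.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_spec(),
                            tree_file = NULL, occurrence_file = NULL,
                            cells_file = NULL, layers_file = NULL,
                            protection_file = NULL,
                            n_iter = 999, alpha = 0.05,
                            strict_both_pe = FALSE,
                            min_richness = 5,
                            predictors = c("MAT", "AP", "LGM_MAT_anom",
                                           "LGM_AP_anom", "Miocene_MAT_anom",
                                           "Miocene_AP_anom", "elev_range"),
                            threat_layers = c("HMI", "future_MAT_anom",
                                              "future_AP_anom"),
                            k_scan = c(2, 4, 6, 8),
                            n_perm = 10000,
                            seed = 1,
                            out_dir = NULL) {
  if (is.null(scenario)) {
    files <- c(tree_file, occurrence_file, cells_file)
    if (any(vapply(files, is.null, logical(1))))
      stopf("without a scenario, tree_file, occurrence_file and cells_file are required")
    for (f in c(files, layers_file, protection_file))
      if (!is.null(f) && !file.exists(f)) stopf("input file not found: %s", f)
  } else {
    stopifnot(inherits(scenario, "scenario_spec"))
  }
  if (n_iter < 1) stopf("`n_iter` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("`alpha` must be in (0, 1)")
  structure(list(scenario = scenario,
                 tree_file = tree_file, occurrence_file = occurrence_file,
                 cells_file = cells_file, layers_file = layers_file,
                 protection_file = protection_file,
                 n_iter = n_iter, alpha = alpha,
                 strict_both_pe = strict_both_pe,
                 min_richness = min_richness,
                 predictors = predictors, threat_layers = threat_layers,
                 k_scan = k_scan, n_perm = n_perm,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input assembly (simulation or file loading), the
#' richness filter and tree/grid alignment, the endemism metrics, the CANAPE
#' randomization and classification, driver-model fitting (OLS and SAR error
#' with k-scan, VIF and Moran diagnostics), hotspot-versus-non-hotspot
#' permutation comparisons, and protection-coverage accounting. Any stage
#' failure aborts with the stage name and cause; stages already written to
#' `out_dir` are retained.
#'
#' Per-stage outputs (when `out_dir` is set): `endemism.csv`,
#' `classification.csv`, `category_percentages.csv`, `driver_fits.json`,
#' `group_tests.json`, `coverage.csv`, and a `report.json` bundling the
#' summary tables with the seeds and input digests used.
#'
#' @param config a [pipeline_config()].
#' @return the report as a list, invisibly when written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digests <- list()

  # --- inputs ----------------------------------------------------------
  inputs <- run_stage("inputs", {
    if (!is.null(config$scenario)) {
      bundle <- simulate_scenario(config$scenario, seed = config$seed)
      if (!is.null(out_dir)) {
        sdir <- file.path(out_dir, "scenario")
        write_scenario(bundle, sdir)
        digests <- lapply(list.files(sdir, full.names = TRUE), tools::md5sum)
      }
      bundle
    } else {
      tree <- read_newick(config$tree_file)
      cells <- utils::read.csv(config$cells_file, stringsAsFactors = FALSE)
      grid <- read_occurrences(config$occurrence_file, cells)
      layers <- NULL
      if (!is.null(config$layers_file)) {
        lay_df <- utils::read.csv(config$layers_file, stringsAsFactors = FALSE)
        layers <- lapply(lay_df[-1L], function(v)
          stats::setNames(v, lay_df[[1L]]))
      }
      protection <- NULL
      if (!is.null(config$protection_file)) {
        pr_df <- utils::read.csv(config$protection_file, stringsAsFactors = FALSE)
        protection <- list()
        for (nm in setdiff(names(pr_df), c("cell_id", "priority_rank")))
          protection[[nm]] <- protection_scheme(
            stats::setNames(pr_df[[nm]] > 0, pr_df$cell_id), nm)
        if ("priority_rank" %in% names(pr_df))
          protection$priority_rank <- stats::setNames(pr_df$priority_rank,
                                                      pr_df$cell_id)
      }
      for (f in c(config$tree_file, config$occurrence_file,
                  config$cells_file, config$layers_file,
                  config$protection_file))
        digests[[basename(f)]] <- tools::md5sum(f)
      list(tree = tree, grid = grid, layers = layers,
           protection = protection, seeds = c(pipeline = config$seed))
    }
  })

  # --- grid filter + alignment ----------------------------------------
  prep <- run_stage("grid", {
    grid <- filter_min_richness(inputs$grid, config$min_richness)
    align_tree_grid(inputs$tree, grid)
  })

  # --- endemism metrics ------------------------------------------------
  metrics <- run_stage("endemism", endemism_metrics(prep$tree, prep$grid))
  if (!is.null(out_dir))
    write_endemism(metrics, file.path(out_dir, "endemism.csv"))

  # --- CANAPE ----------------------------------------------------------
  rand_seed <- config$seed + 1L
  rand <- run_stage("canape", randomization_test(
    prep$tree, prep$grid, n_iter = config$n_iter, seed = rand_seed))
  classification <- canape_classify(rand, alpha = config$alpha,
                                    strict_both_pe = config$strict_both_pe,
                                    all_cells = inputs$grid$cells$id)
  cat_tab <- category_percentages(classification)
  if (!is.null(out_dir)) {
    write_classification(classification, file.path(out_dir, "classification.csv"))
    utils::write.csv(cat_tab, file.path(out_dir, "category_percentages.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  # --- drivers ---------------------------------------------------------
  drivers <- NULL
  if (!is.null(inputs$layers)) {
    drivers <- run_stage("drivers", {
      pe <- stats::setNames(metrics$PE_original, metrics$cell)
      use <- intersect(config$predictors, names(inputs$layers))
      tab <- build_driver_table(pe, inputs$layers[use], prep$grid$cells)
      X <- tab[, use, drop = FALSE]
      vifs <- vif(X)
      ols <- fit_ols(tab$response, X)
      sar <- fit_sar_error(tab$response, X,
                           coords = tab[, c("x", "y")],
                           k_scan = config$k_scan)
      w_best <- knn_weights(tab[, c("x", "y")], sar$k)
      list(table = tab, vif = vifs, ols = ols, sar = sar,
           selection = model_selection(list(OLS = ols, SAR_error = sar)),
           moran_ols = moran_test(ols$residuals, w_best),
           moran_sar = moran_test(sar$residuals, w_best))
    })
    if (!is.null(out_dir))
      jsonlite::write_json(list(
        vif = as.list(drivers$vif),
        ols = list(coefficients = drivers$ols$coefficients,
                   adj_r_squared = drivers$ols$adj_r_squared,
                   AIC = drivers$ols$AIC, BIC = drivers$ols$BIC),
        sar = list(coefficients = drivers$sar$coefficients,
                   lambda = drivers$sar$lambda,
                   nagelkerke_r2 = drivers$sar$nagelkerke_r2,
                   AIC = drivers$sar$AIC, BIC = drivers$sar$BIC,
                   k = drivers$sar$k),
        selection = drivers$selection,
        moran = list(ols = drivers$moran_ols[c("I", "p_value")],
                     sar = drivers$moran_sar[c("I", "p_value")])),
        file.path(out_dir, "driver_fits.json"),
        auto_unbox = TRUE, digits = NA)
  }

  # --- group comparisons ----------------------------------------------
  tests <- NULL
  if (!is.null(inputs$layers)) {
    tests <- run_stage("group_tests", {
      hot <- group_hotspots(classification)
      analysed <- classification$cell[classification$category != "excluded"]
      test_layers <- intersect(c(config$predictors, config$threat_layers),
                               names(inputs$layers))
      two <- lapply(test_layers, function(nm) {
        v <- inputs$layers[[nm]][analysed]
        fisher_pitman_two_sample(v[hot[analysed]], v[!hot[analysed]],
                                 n_perm = config$n_perm,
                                 seed = config$seed + 2L)
      })
      names(two) <- test_layers
      ksamp <- NULL
      cats <- droplevels(factor(classification$category[
        match(analysed, classification$cell)]))
      if (nlevels(cats) >= 3L) {
        ksamp <- lapply(intersect(config$threat_layers, names(inputs$layers)),
                        function(nm) {
          v <- inputs$layers[[nm]][analysed]
          list(k_sample = fisher_pitman_k_sample(v, cats,
                                                 n_perm = config$n_perm,
                                                 seed = config$seed + 3L),
               posthoc = posthoc_pairwise(v, cats,
                                          n_perm = min(config$n_perm, 5000L),
                                          seed = config$seed + 4L))
        })
        names(ksamp) <- intersect(config$threat_layers, names(inputs$layers))
      }
      list(two_sample = two, k_sample = ksamp)
    })
    if (!is.null(out_dir))
      jsonlite::write_json(list(
        two_sample = lapply(tests$two_sample, function(t)
          t[c("statistic", "p_value", "method")]),
        k_sample = lapply(tests$k_sample %||% list(), function(t)
          list(statistic = t$k_sample$statistic,
               p_value = t$k_sample$p_value,
               letters = as.list(t$posthoc$letters)))),
        file.path(out_dir, "group_tests.json"),
        auto_unbox = TRUE, digits = NA)
  }

  # --- protection ------------------------------------------------------
  coverage <- NULL
  if (!is.null(inputs$protection)) {
    coverage <- run_stage("protection", {
      schemes <- inputs$protection[setdiff(names(inputs$protection),
                                           "priority_rank")]
      do.call(rbind, lapply(schemes, function(s)
        coverage_by_class(classification, classification, s)))
    })
    if (!is.null(out_dir))
      utils::write.csv(coverage, file.path(out_dir, "coverage.csv"),
                       row.names = FALSE, quote = FALSE)
  }

  report <- list(
    seeds = as.list(inputs$seeds),
    n_iter = config$n_iter, alpha = config$alpha,
    n_cells_analysed = sum(classification$category != "excluded"),
    n_species = nrow(prep$grid$presence),
    category_percentages = cat_tab,
    driver_summary = if (!is.null(drivers)) list(
      vif = as.list(drivers$vif),
      sar_lambda = drivers$sar$lambda,
      sar_nagelkerke_r2 = drivers$sar$nagelkerke_r2,
      selection = drivers$selection) else NULL,
    group_tests = if (!is.null(tests)) lapply(tests$two_sample, function(t)
      list(statistic = t$statistic, p_value = t$p_value)) else NULL,
    coverage = coverage,
    input_digests = digests
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(c(report, list(
      classification = classification, metrics = metrics,
      randomization = rand, drivers = drivers, tests = tests))))
  }
  c(report, list(classification = classification, metrics = metrics,
                 randomization = rand, drivers = drivers, tests = tests))
}
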