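## Reading/writing the fixed CSV schemas and the end-to-end pipeline.
## Schemas: stomach records `pred_id,item_id,count`; predators
## `pred_id,species,standard_length_mm`; prey traits
## `item_id,taxon,trophic_group,body_size_mm`.

#' Read and validate the three input tables
#'
#' Hard-errors with row numbers on missing columns, duplicated ids,
#' non-numeric or non-positive sizes, negative counts, unknown trophic
#' labels, and broken referential integrity.
#'
#' @param stomach_path,predator_path,prey_path CSV paths.
#' @return List `records`, `predators` (`predator_table`), `pool`
#'   (`prey_pool`).
#' @export
read_diet_tables <- function(stomach_path, predator_path, prey_path) {
  for (pth in c(stomach_path, predator_path, prey_path)) {
    if (!file.exists(pth)) stop("file not found: ", pth, call. = FALSE)
  }
  records <- read.csv(stomach_path, stringsAsFactors = FALSE)
  predators <- read.csv(predator_path, stringsAsFactors = FALSE)
  prey <- read.csv(prey_path, stringsAsFactors = FALSE)

  need_cols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  need_cols(records, c("pred_id", "item_id", "count"), "stomach table")
  need_cols(predators, c("pred_id", "species", "standard_length_mm"),
            "predator table")
  need_cols(prey, c("item_id", "taxon", "trophic_group", "body_size_mm"),
            "prey trait table")

  if (anyDuplicated(predators$pred_id)) {
    stop("duplicate pred_id at predator-table row(s) ",
         paste(which(duplicated(predators$pred_id)), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(predators$standard_length_mm) |
                 predators$standard_length_mm <= 0)
  if (length(bad)) {
    stop("non-positive/non-numeric standard_length_mm at predator-table ",
         "row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(records$count))) |
                 records$count < 0 | records$count != round(records$count))
  if (length(bad)) {
    stop("invalid count at stomach-table row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!records$pred_id %in% predators$pred_id)
  if (length(bad)) {
    stop("unknown pred_id at stomach-table row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!records$item_id %in% prey$item_id)
  if (length(bad)) {
    stop("unknown item_id at stomach-table row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pool <- data.frame(item_id = prey$item_id, taxon_label = prey$taxon,
                     trophic_group = prey$trophic_group,
                     body_size_mm = prey$body_size_mm,
                     stringsAsFactors = FALSE)
  pool <- validate_prey_pool(pool)
  class(predators) <- c("predator_table", "data.frame")
  list(records = records, predators = predators, pool = pool)
}

#' Write a simulation to the standard CSV schemas plus a truth JSON
#'
#' @param sim A `diet_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "diet_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    stomach = file.path(dir, "stomach_records.csv"),
    predators = file.path(dir, "predators.csv"),
    prey = file.path(dir, "prey_traits.csv"),
    truth = file.path(dir, "truth.json")
  )
  write.table(sim$records, paths[["stomach"]], sep = ",", row.names = FALSE,
              quote = FALSE)
  write.table(sim$predators, paths[["predators"]], sep = ",",
              row.names = FALSE, quote = FALSE)
  prey <- data.frame(item_id = sim$pool$item_id,
                     taxon = sim$pool$taxon_label,
                     trophic_group = as.character(sim$pool$trophic_group),
                     body_size_mm = sim$pool$body_size_mm)
  write.table(prey, paths[["prey"]], sep = ",", row.names = FALSE,
              quote = FALSE)
  truth <- sim$truth$params
  truth <- truth[!vapply(truth, is.function, logical(1L))]
  class(truth) <- NULL
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Pipeline configuration
#'
#' @param stomach_path,predator_path,prey_path Input CSVs; alternatively
#'   set `preset` to simulate.
#' @param preset A scenario name `"H1"`..`"H7"` to simulate instead of
#'   reading files.
#' @param class_size Individuals per size class (default 31).
#' @param log10_size Log10-transform prey size in the regression covariate.
#' @param alpha Significance level (default 0.05).
#' @param full_model Full `cats_model_spec`.
#' @param ladder `"standard"` (the nested ladder of
#'   [enumerate_nested_models()]) or `"minimal"` (the full model plus the
#'   two reductions the verdict needs: without the class random effect and
#'   without the quadratic predator-size block).
#' @param percentiles Prey-size percentiles for the curves, strictly
#'   increasing in (0, 1).
#' @param seed Seed for simulation.
#' @param out_dir Optional output directory for the TSV/JSON artifacts.
#' @param control [mechanism_control()] thresholds.
#' @param n_individuals,n_items Simulated design sizes (preset mode).
#' @return A validated `run_config` list.
#' @export
pipeline_config <- function(stomach_path = NULL, predator_path = NULL,
                            prey_path = NULL, preset = NULL,
                            class_size = 31L, log10_size = TRUE,
                            alpha = 0.05, full_model = full_cats_model(),
                            ladder = c("standard", "minimal"),
                            percentiles = c(0.05, 0.5, 0.95),
                            seed = 1L, out_dir = NULL,
                            control = mechanism_control(),
                            n_individuals = 619L, n_items = 60L) {
  ladder <- match.arg(ladder)
  alpha <- assert_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  class_size <- assert_count(class_size, "class_size")
  if (any(percentiles <= 0) || any(percentiles >= 1) ||
      is.unsorted(percentiles, strictly = TRUE)) {
    stop("`percentiles` must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  if (is.null(preset) &&
      (is.null(stomach_path) || is.null(predator_path) || is.null(prey_path))) {
    stop("either the three input paths or a `preset` must be given",
         call. = FALSE)
  }
  out <- list(stomach_path = stomach_path, predator_path = predator_path,
              prey_path = prey_path, preset = preset,
              class_size = class_size, log10_size = log10_size,
              alpha = alpha, full_model = full_model, ladder = ladder,
              percentiles = percentiles, seed = assert_count(seed, "seed", 0L),
              out_dir = out_dir, control = control,
              n_individuals = assert_count(n_individuals, "n_individuals"),
              n_items = assert_count(n_items, "n_items"))
  class(out) <- "run_config"
  out
}

#' Run the full inference pipeline
#'
#' Binning, diet matrix, offset, DWM trends, CATS fits, model comparison,
#' selection curves and the mechanism verdict, in order; optionally writes
#' the coefficient, comparison, DWM and curve TSVs plus a verdict JSON and a
#' log to `out_dir`. The same config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `cats_report` list with every intermediate stage and the
#'   verdict.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(config$preset)) {
    sim <- stage("simulate",
                 simulate_preset(config$preset, seed = config$seed,
                                 n_individuals = config$n_individuals,
                                 n_items = config$n_items,
                                 class_size = config$class_size))
    records <- sim$records; predators <- sim$predators; pool <- sim$pool
  } else {
    inp <- stage("read", read_diet_tables(config$stomach_path,
                                          config$predator_path,
                                          config$prey_path))
    records <- inp$records; predators <- inp$predators; pool <- inp$pool
    sim <- NULL
  }
  classes <- stage("bin", assign_size_classes(predators, config$class_size))
  dmat <- stage("matrix", build_diet_matrix(records, classes, pool))
  offset <- stage("offset", compute_offset(dmat))
  dwm <- stage("dwm", compute_dwm(dmat))
  trends <- stage("dwm", dwm_trends(dmat))
  corr <- stage("correlation", prey_count_size_correlation(dmat))

  specs <- if (config$ladder == "standard") {
    enumerate_nested_models(config$full_model)
  } else {
    full <- config$full_model
    no_class <- cats_model_spec(full$fixed,
                                setdiff(full$random, "class_id"),
                                full$use_offset)
    no_quad <- cats_model_spec(full$fixed[!grepl("PredBS2", full$fixed)],
                               full$random, full$use_offset)
    specs <- list(full, no_class, no_quad)
    names(specs) <- vapply(specs, spec_signature, character(1L))
    specs
  }
  comparison <- stage("fit", compare_models(dmat, specs,
                                            log10_size = config$log10_size))
  full_fit <- comparison$fits[[1L]]
  null_spec <- cats_model_spec(character(), config$full_model$random,
                               config$full_model$use_offset)
  null_fit <- stage("fit", fit_cats(dmat, null_spec,
                                    log10_size = config$log10_size))
  r2 <- stage("fit", pseudo_r2(full_fit, null_fit))
  curves <- stage("curves", selection_curves(full_fit, pool,
                                             config$percentiles))
  verdict <- stage("verdict",
                   mechanism_support(comparison, full_fit, curves, corr,
                                     alpha = config$alpha,
                                     control = config$control))
  report <- list(config = config, simulation = sim, classes = classes,
                 diet_matrix = dmat, offset = offset, dwm = dwm,
                 dwm_trends = trends, correlation = corr,
                 comparison = comparison, full_fit = full_fit,
                 null_fit = null_fit, pseudo_r2 = r2, curves = curves,
                 verdict = verdict)
  class(report) <- "cats_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.cats_report <- function(x, ...) {
  cat("CATS prey-selection report\n")
  cat(" ", nrow(x$classes$classes), "size classes,",
      ncol(x$diet_matrix$counts), "prey items, total count",
      sum(x$diet_matrix$counts), "\n")
  cat(sprintf("  count-size correlation r = %.3f (p = %.3g)\n",
              x$correlation$r, x$correlation$p))
  cat(sprintf("  full model AIC %.2f, weight %.3f; pseudo-R2 %.3f (dev) / %.3f (corr)\n",
              x$full_fit$aic, x$comparison$table$weight[1L],
              x$pseudo_r2$deviance_r2, x$pseudo_r2$corr_r2))
  print(x$verdict)
  invisible(x)
}

#' Write the pipeline artifacts
#'
#' Coefficient, model-comparison, DWM and selection-curve TSVs (header row,
#' tab separated), a verdict JSON and a short log file.
#'
#' @param report A `cats_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    pth <- file.path(dir, name)
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 10,
                                                   format = "g"))
    write.table(df, pth, sep = "\t", row.names = FALSE, quote = FALSE)
    pth
  }
  paths <- c(
    coefficients = wtsv(coef_table(report$full_fit), "coefficients.tsv"),
    comparison = wtsv(report$comparison$table, "model_comparison.tsv"),
    dwm = wtsv(report$dwm, "dwm.tsv"),
    dwm_trends = wtsv(report$dwm_trends, "dwm_trends.tsv"),
    curves = wtsv(report$curves, "selection_curves.tsv"),
    verdict = file.path(dir, "verdict.json"),
    log = file.path(dir, "run.log")
  )
  v <- report$verdict
  jsonlite::write_json(
    list(hypothesis = v$hypothesis,
         m1 = list(supported = v$m1$supported, delta_aic = v$m1$delta_aic,
                   r = v$m1$r, p = v$m1$p),
         m2 = list(supported = v$m2$supported),
         m3 = list(supported = v$m3$supported, inversion = v$m3$inversion,
                   ordering = v$m3$ordering),
         carnivore_large_avoidance = v$carnivore_large_avoidance,
         alpha = v$alpha,
         pseudo_r2 = report$pseudo_r2,
         full_model_weight = report$comparison$table$weight[1L]),
    paths[["verdict"]], auto_unbox = TRUE, digits = NA)
  writeLines(c(
    paste("catselect pipeline run, seed", report$config$seed),
    paste("classes:", nrow(report$classes$classes),
          "items:", ncol(report$diet_matrix$counts)),
    paste("ladder:", report$config$ladder,
          "models:", nrow(report$comparison$table)),
    paste("hypothesis:", v$hypothesis)
  ), paths[["log"]])
  invisible(paths)
}
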