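#' Pipeline configuration
#'
#' One object carrying every stage's parameters, round-trippable through
#' YAML. All randomness flows from the single `seed` through fixed per-stage
#' offsets.
#'
#' @param population A [population_spec()] for the synthetic cohort (its
#'   `seed` is overridden by `seed`).
#' @param fit A [fit_params()].
#' @param template_resolution Template resolution level (default 0).
#' @param k_upper,k_lobule First-stage PC counts for CI synthesis.
#' @param ci_amplitude_upper,ci_amplitude_lobule First-stage CI amplitudes
#'   (raw score units; defaults 100 and 60).
#' @param cci_pcs_upper,cci_pcs_lobule Second-stage PC counts kept for the
#'   criterion images (defaults 5 and 6).
#' @param cci_amplitude_upper,cci_amplitude_lobule Second-stage amplitudes
#'   (defaults 100 and 30).
#' @param ev_threshold_upper,ev_threshold_lobule EV-magnitude selection
#'   thresholds reported alongside the scree criterion.
#' @param threshold_quantile Percentile for [calibrate_threshold()].
#' @param allow_scaling Passed to [generalized_procrustes()].
#' @param seed Root seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(population = population_spec(),
                            fit = fit_params(),
                            template_resolution = 0,
                            k_upper = 5, k_lobule = 6,
                            ci_amplitude_upper = 100, ci_amplitude_lobule = 60,
                            cci_pcs_upper = 5, cci_pcs_lobule = 6,
                            cci_amplitude_upper = 100,
                            cci_amplitude_lobule = 30,
                            ev_threshold_upper = 500,
                            ev_threshold_lobule = 100,
                            threshold_quantile = 90,
                            allow_scaling = TRUE,
                            seed = 1) {
  population$seed <- as.integer(seed)
  structure(
    list(population = population, fit = fit,
         template_resolution = template_resolution,
         k_upper = k_upper, k_lobule = k_lobule,
         ci_amplitude_upper = ci_amplitude_upper,
         ci_amplitude_lobule = ci_amplitude_lobule,
         cci_pcs_upper = cci_pcs_upper, cci_pcs_lobule = cci_pcs_lobule,
         cci_amplitude_upper = cci_amplitude_upper,
         cci_amplitude_lobule = cci_amplitude_lobule,
         ev_threshold_upper = ev_threshold_upper,
         ev_threshold_lobule = ev_threshold_lobule,
         threshold_quantile = threshold_quantile,
         allow_scaling = allow_scaling,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- unclass(config)
  plain$population <- unclass(plain$population)
  plain$population$side_plan <- as.list(plain$population$side_plan)
  plain$fit <- unclass(plain$fit)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pop <- do.call(population_spec, c(
    raw$population[setdiff(names(raw$population), "side_plan")],
    list(side_plan = unlist(raw$population$side_plan))
  ))
  fit <- do.call(fit_params, raw$fit[setdiff(names(raw$fit), "n_relax_iters")])
  fit$n_relax_iters <- as.integer(raw$fit$n_relax_iters)
  args <- raw[setdiff(names(raw), c("population", "fit"))]
  do.call(pipeline_config, c(list(population = pop, fit = fit), args))
}

log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full ear-classification pipeline
#'
#' Simulate (or accept) a cohort, fit the template to every mesh, align,
#' split regions, run the two-stage PCA per region, derive the criterion
#' images, calibrate the classification threshold and classify the cohort.
#' Writes tidy CSV tables plus a JSON run manifest to `out_dir` and returns
#' all in-memory artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param cohort Optional pre-built cohort (list of subjects with `mesh` and
#'   `meta`); by default simulated from `config$population`.
#' @return A `pipeline_run` list: `template`, `cohort_manifest`, `homologous`,
#'   per-region `shape_model`s, `ci`s, `cci`s, `classification`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage("template", "resolution ", config$template_resolution)
  template <- make_template(config$template_resolution, seed = config$seed)

  if (is.null(cohort)) {
    log_stage("simulate", config$population$n_subjects, " subjects")
    cohort <- sample_population(config$population, template)
  }
  manifest <- cohort_manifest(cohort)

  log_stage("fit", length(cohort), " meshes")
  homologous <- lapply(cohort, function(s) {
    mesh <- s$mesh
    if (s$meta$side == "right") mesh <- mirror_mesh(mesh, "yz")
    tryCatch(
      fit_template(template, mesh, params = config$fit, meta = s$meta),
      error = function(e) stop("stage fit, subject ", s$meta$subject_id, " (",
                               s$meta$side, "): ", conditionMessage(e),
                               call. = FALSE)
    )
  })

  log_stage("align", "generalized Procrustes per region")
  regions <- ear_regions()
  splits <- lapply(homologous, split_regions)
  per_region <- lapply(regions, function(reg) {
    subs <- lapply(splits, function(s) s[[reg]])
    gpa <- generalized_procrustes(subs, allow_scaling = config$allow_scaling)
    model <- fit_shape_pca(gpa)
    list(gpa = gpa, model = model, aligned = gpa$models)
  })
  names(per_region) <- regions

  cfg_of <- function(reg, what) {
    key <- paste0(what, "_", if (reg == "upper_auricle") "upper" else "lobule")
    config[[key]]
  }
  log_stage("cci", "two-stage PCA and criterion images")
  built <- lapply(regions, function(reg) {
    model <- per_region[[reg]]$model
    k <- min(cfg_of(reg, "k"), model$n_displayed)
    cis <- make_composite_images(model, k, cfg_of(reg, "ci_amplitude"))
    ci_model <- second_stage_pca(cis)
    n_pcs <- min(cfg_of(reg, "cci_pcs"), ci_model$n_displayed)
    ccis <- derive_ccis(ci_model, n_pcs, cfg_of(reg, "cci_amplitude"),
                        region = reg)
    ccis <- calibrate_threshold(per_region[[reg]]$aligned, ccis,
                                q = config$threshold_quantile)
    list(cis = cis, ci_model = ci_model, ccis = ccis)
  })
  names(built) <- regions

  log_stage("classify", length(homologous), " models")
  classification <- classify_aligned(per_region, built, homologous)

  run <- structure(
    list(template = template, cohort_manifest = manifest,
         homologous = homologous, per_region = per_region, built = built,
         classification = classification, config = config),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Classify the GPA-aligned region sub-models (the frame the CCIs live in).
classify_aligned <- function(per_region, built, homologous) {
  metas <- lapply(homologous, function(m) m$meta)
  rows <- list()
  for (reg in ear_regions()) {
    aligned <- per_region[[reg]]$aligned
    ccis <- built[[reg]]$ccis
    for (i in seq_along(aligned)) {
      m <- aligned[[i]]
      m$meta <- metas[[i]]
      res <- classify_one(m, ccis)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = m$meta$subject_id, side = m$meta$side, region = reg,
        assigned = res$assigned, min_dbv = min(res$dbv_by_cci),
        n_under_threshold = length(res$under_threshold_labels),
        under_threshold_labels =
          paste(res$under_threshold_labels, collapse = ",")
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  summaries <- lapply(ear_regions(), function(reg) {
    summarise_region_results(dplyr::filter(results, .data$region == reg),
                             cci_labels(built[[reg]]$ccis), reg)
  })
  names(summaries) <- ear_regions()
  structure(list(results = results, summary = summaries),
            class = "cohort_classification")
}

summarise_region_results <- function(r, labels, reg) {
  n_total <- nrow(r)
  n_under <- sum(r$assigned != OUT_OF_CLASSIFICATION)
  n_multi <- sum(r$n_under_threshold >= 2L)
  freq <- table(factor(r$assigned[r$assigned != OUT_OF_CLASSIFICATION],
                       levels = labels))
  both <- dplyr::count(dplyr::distinct(r, .data$subject_id, .data$side),
                       .data$subject_id)
  bilateral <- both$subject_id[both$n == 2L]
  asym <- 0L
  if (length(bilateral)) {
    wide <- tidyr::pivot_wider(
      dplyr::filter(r, .data$subject_id %in% bilateral),
      id_cols = "subject_id", names_from = "side", values_from = "assigned"
    )
    asym <- sum(wide$left != wide$right |
                  wide$left == OUT_OF_CLASSIFICATION |
                  wide$right == OUT_OF_CLASSIFICATION)
  }
  list(region = reg, n_total = n_total, n_under_threshold = n_under,
       n_over_threshold = n_total - n_under, n_multi_match = n_multi,
       assignment_counts = as.integer(freq),
       assignment_labels = names(freq),
       n_asymmetric = asym, n_bilateral_subjects = length(bilateral))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$cohort_manifest, file.path(out_dir, "cohort.csv"))
  fitres <- tibble::tibble(
    subject_id = vapply(run$homologous, function(m) m$meta$subject_id,
                        character(1)),
    side = vapply(run$homologous, function(m) m$meta$side, character(1)),
    fit_residual = vapply(run$homologous, function(m) m$fit_residual,
                          numeric(1))
  )
  readr::write_csv(fitres, file.path(out_dir, "fit_report.csv"))
  for (reg in ear_regions()) {
    tab <- tidy(run$per_region[[reg]]$model,
                ages = run$cohort_manifest$age, rounded = TRUE)
    readr::write_csv(tab, file.path(out_dir, paste0("pca_", reg, ".csv")))
    d <- dbv_per_pc(run$per_region[[reg]]$model)
    readr::write_csv(d, file.path(out_dir, paste0("dbv_", reg, ".csv")))
  }
  readr::write_csv(run$classification$results,
                   file.path(out_dir, "classification.csv"))
  readr::write_csv(tidy(run$classification),
                   file.path(out_dir, "classification_summary.csv"))
  cfg <- run$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("auriclass")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    n_meshes = nrow(run$cohort_manifest),
    n_ccis = lapply(run$built, function(b) length(b$ccis$ccis)),
    thresholds = lapply(run$built, function(b) b$ccis$threshold)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Human-readable report of a pipeline run
#'
#' Formats the PC tables (CR/CCR at 0.1%, R at 0.01), the per-PC DBV slopes,
#' and the four-row classification block per region, from the persisted or
#' in-memory artifacts of [run_pipeline()]. Every number is recomputable from
#' the stage outputs; the report only formats.
#'
#' @param run A `pipeline_run`, or a directory written by [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
make_report <- function(run) {
  if (is.character(run)) {
    need <- c("pca_upper_auricle.csv", "pca_lobule.csv",
              "classification_summary.csv")
    missing <- need[!file.exists(file.path(run, need))]
    if (length(missing)) {
      stop("incomplete run: missing ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    pca <- lapply(ear_regions(), function(reg)
      readr::read_csv(file.path(run, paste0("pca_", reg, ".csv")),
                      show_col_types = FALSE))
    names(pca) <- ear_regions()
    summ <- readr::read_csv(file.path(run, "classification_summary.csv"),
                            show_col_types = FALSE)
  } else {
    pca <- lapply(ear_regions(), function(reg)
      tidy(run$per_region[[reg]]$model, ages = run$cohort_manifest$age,
           rounded = TRUE))
    names(pca) <- ear_regions()
    summ <- tidy(run$classification)
  }
  lines <- character(0)
  for (reg in ear_regions()) {
    tab <- pca[[reg]]
    lines <- c(lines, paste0("== PCA (", reg, ") =="),
               sprintf("%-4s %10s %8s %8s%s", "PC", "EV", "CR(%)", "CCR(%)",
                       if (!is.null(tab$r)) "        R" else ""))
    for (i in seq_len(nrow(tab))) {
      lines <- c(lines, sprintf(
        "%-4d %10.1f %8.1f %8.1f%s", tab$pc[i], tab$ev[i], tab$cr[i],
        tab$ccr[i],
        if (!is.null(tab$r)) sprintf(" %8.2f", tab$r[i]) else ""))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "== Classification ==")
  for (reg in ear_regions()) {
    s <- dplyr::filter(summ, .data$region == reg)
    lines <- c(lines, paste0("-- ", reg, " --"))
    for (i in seq_len(nrow(s))) {
      lines <- c(lines, sprintf("%-28s %4d / %4d (%.1f%%)", s$statistic[i],
                                s$n[i], s$denominator[i], s$percent[i]))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
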