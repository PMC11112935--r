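# End-to-end orchestration: simulate or ingest a cohort, run the WTA and
# ROI protocols per patient, then the association and survival layers, and
# write the report bundle.

#' Configuration of an end-to-end run
#'
#' Exactly one of `simulate` (a [sim_config()]) or `input_dir` (a cohort
#' directory as written by [write_cohort()]) must be given.
#'
#' @param simulate [sim_config()] for simulate mode, or `NULL`.
#' @param input_dir cohort directory for ingest mode, or `NULL`.
#' @param roi [roi_params()].
#' @param grouping_metrics patient-summary columns used for median-split
#'   groupings in the association and survival layers.
#' @param multivariate_metric metric entering the multivariate Cox model.
#' @param output_dir directory for the report bundle (`NULL`: in-memory
#'   only).
#' @param seed run seed; in simulate mode it overrides the simulator seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, input_dir = NULL,
                       roi = roi_params(),
                       grouping_metrics = c("gzmb_ccr8_ratio",
                                            "hot_mean_ccr8_treg",
                                            "hot_mean_pct_gzmb"),
                       multivariate_metric = "gzmb_ccr8_ratio",
                       output_dir = NULL, seed = NULL) {
  if (is.null(simulate) == is.null(input_dir)) {
    stop("exactly one of `simulate` or `input_dir` must be supplied",
         call. = FALSE)
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  structure(list(simulate = simulate, input_dir = input_dir, roi = roi,
                 grouping_metrics = grouping_metrics,
                 multivariate_metric = multivariate_metric,
                 output_dir = output_dir, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulate mode generates the cohort from the configured
#' [sim_config()]; ingest mode reads cell tables, masks and the clinical
#' table from `input_dir`. Either way every patient then passes through
#' [analyze_patient()] (tumor restriction, WTA metrics, density maps,
#' Hot/Cold-Spot selection, field metrics, summary), and the cohort
#' through [clinico_association_table()] per grouping metric and
#' [survival_report()]. Identical config and seed give identical bundles.
#'
#' @param config a [run_config()].
#' @return list of class `tilspot_run` with `summaries`, `fields`,
#'   `associations` (one table per grouping metric), `survival`
#'   ([survival_report()]), `clinical` and `manifest`. Written to
#'   `config$output_dir` as CSV/JSON when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!is.null(config$seed)) sim$seed <- config$seed
    if (is.null(sim$seed)) {
      stop("simulate mode needs a seed for reproducibility", call. = FALSE)
    }
    cohort <- withCallingHandlers(
      suppressMessages(simulate_cohort(sim, roi = config$roi)),
      warning = note)
    slides <- cohort$slides
    clinical <- cohort$clinical
  } else {
    cohort <- read_cohort(config$input_dir)
    slides <- cohort$slides
    clinical <- cohort$clinical
  }
  if (length(slides) == 0) stop("empty cohort", call. = FALSE)

  summaries <- list()
  fields <- list()
  for (pid in names(slides)) {
    sl <- slides[[pid]]
    an <- withCallingHandlers(
      suppressMessages(
        analyze_patient(sl$panel_a, sl$panel_b, sl$mask, config$roi)),
      warning = note)
    summaries[[pid]] <- an$summary
    fields[[pid]] <- an$fields
  }
  summaries <- do.call(rbind, summaries)
  fields <- do.call(rbind, fields)
  rownames(summaries) <- rownames(fields) <- NULL

  associations <- list()
  for (m in config$grouping_metrics) {
    grp <- withCallingHandlers(
      median_split(summaries[[m]], ids = summaries$patient_id),
      warning = note)
    associations[[m]] <- withCallingHandlers(
      clinico_association_table(clinical, grp), warning = note)
  }

  surv <- withCallingHandlers(
    survival_report(summaries, clinical, metrics = config$grouping_metrics,
                    multivariate_metric = config$multivariate_metric),
    warning = note)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tilspot")),
    mode = if (!is.null(config$simulate)) "simulate" else "ingest",
    seed = config$seed %||%
      (if (!is.null(config$simulate)) config$simulate$seed),
    n_patients = nrow(summaries),
    roi = unclass(config$roi),
    grouping_metrics = config$grouping_metrics,
    sim_config = if (!is.null(config$simulate))
      unclass(config$simulate)[setdiff(names(config$simulate), "seed")],
    warnings = warnings_log)

  bundle <- structure(
    list(summaries = summaries, fields = fields,
         associations = associations, survival = surv,
         clinical = clinical, manifest = manifest),
    class = "tilspot_run")
  if (!is.null(config$output_dir)) write_run_outputs(bundle,
                                                     config$output_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tilspot_run <- function(x, ...) {
  cat(sprintf("<tilspot_run> %d patients (%s mode)\n",
              x$manifest$n_patients, x$manifest$mode))
  print(x$survival)
  invisible(x)
}

#' Write a run bundle to disk
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$summaries,
                   file.path(dir, "patient_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$fields, file.path(dir, "field_metrics.csv"),
                   row.names = FALSE)
  assoc <- do.call(rbind, lapply(names(bundle$associations), function(m) {
    cbind(grouping = m, bundle$associations[[m]])
  }))
  utils::write.csv(assoc, file.path(dir, "associations.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$survival$by_metric,
                   file.path(dir, "survival_by_metric.csv"),
                   row.names = FALSE)
  km <- do.call(rbind, lapply(names(bundle$survival$km), function(m) {
    hi <- bundle$survival$km[[m]]$high
    lo <- bundle$survival$km[[m]]$low
    rbind(cbind(metric = m, group = "high", hi),
          cbind(metric = m, group = "low", lo))
  }))
  utils::write.csv(km, file.path(dir, "km_curves.csv"), row.names = FALSE)
  if (!is.null(bundle$survival$multivariate)) {
    utils::write.csv(as.data.frame(bundle$survival$multivariate),
                     file.path(dir, "cox_multivariate.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Write / read a cohort directory
#'
#' Persists a simulated (or externally assembled) cohort in the package's
#' interchange formats: per patient `cells_<id>_A.csv` and
#' `cells_<id>_B.csv` ([write_cell_table()]), `mask_<id>.geojson`
#' ([write_tumor_mask()]), plus one `clinical.csv`. [read_cohort()] is the
#' exact inverse.
#'
#' @param cohort list with `slides` (named per-patient list of `panel_a`,
#'   `panel_b`, `mask`) and `clinical`, e.g. a [simulate_cohort()] result.
#' @param dir target directory.
#' @return `dir` invisibly (write) / the cohort list (read).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$slides)) {
    sl <- cohort$slides[[pid]]
    write_cell_table(sl$panel_a, file.path(dir,
                                           sprintf("cells_%s_A.csv", pid)))
    write_cell_table(sl$panel_b, file.path(dir,
                                           sprintf("cells_%s_B.csv", pid)))
    write_tumor_mask(sl$mask, file.path(dir,
                                        sprintf("mask_%s.geojson", pid)))
  }
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  clinical <- read_clinical(file.path(dir, "clinical.csv"))
  ids <- clinical$patient_id
  slides <- lapply(ids, function(pid) {
    pa <- read_cell_table(file.path(dir, sprintf("cells_%s_A.csv", pid)),
                          PANEL_A)
    pb <- read_cell_table(file.path(dir, sprintf("cells_%s_B.csv", pid)),
                          PANEL_B)
    mask <- read_tumor_mask(file.path(dir, sprintf("mask_%s.geojson", pid)))
    attr(pa, "bbox") <- attr(pb, "bbox") <- mask_bbox(mask)
    list(panel_a = pa, panel_b = pb, mask = mask)
  })
  names(slides) <- ids
  list(slides = slides, clinical = clinical)
}
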