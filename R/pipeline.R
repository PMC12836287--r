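# End-to-end orchestration: simulate -> build atlas -> predict -> block ->
# evaluate -> leave-one-out, with persisted intermediates and a manifest.

#' Pipeline run configuration
#'
#' @param out_dir run directory.
#' @param n_cases cohort size.
#' @param phantom a `phantom_spec`.
#' @param registration a `registration_config`.
#' @param block a `block_params`.
#' @param weighting_p SSIM weighting exponent.
#' @param test_index index of the cohort case treated as the "new patient"
#'   for prediction and block generation (excluded from the atlas).
#' @param write_dicom also export the test case + block as DICOM-RT.
#' @param run_loo run the leave-one-out validation stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, n_cases = 10L,
                       phantom = phantom_spec(dose_style = "helical"),
                       registration = registration_config(),
                       block = block_params(), weighting_p = 1,
                       test_index = NULL, write_dicom = FALSE,
                       run_loo = TRUE) {
  structure(list(out_dir = out_dir, n_cases = as.integer(n_cases),
                 phantom = phantom, registration = registration,
                 block = block, weighting_p = weighting_p,
                 test_index = if (is.null(test_index)) NULL
                              else as.integer(test_index),
                 write_dicom = isTRUE(write_dicom),
                 run_loo = isTRUE(run_loo)),
            class = "run_config")
}

pipeline_log <- function(stage, id, fmt, ...) {
  message(sprintf("[%s] (%s) %s", stage, id, sprintf(fmt, ...)))
}

# run one pipeline stage; errors are re-thrown with a stage tag so a halted
# run names the stage that failed (partial outputs are retained)
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full dose-mimicking pipeline
#'
#' Stages, in order: cohort simulation, atlas construction, dose prediction
#' for the held-out test case, complete-block generation and export, plan
#' metric evaluation, and (optionally) leave-one-out validation. All
#' intermediates are persisted under `config$out_dir`; a `manifest.json`
#' records the configuration, its hash, and the artifact paths. A rerun with
#' the same config reproduces the metric tables bit-identically.
#'
#' @param config a `run_config`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out, "config.json")
  cfg_ser <- list(n_cases = config$n_cases,
                  phantom = unclass(config$phantom["grid" != names(config$phantom)]),
                  grid = list(origin = config$phantom$grid$origin,
                              spacing = config$phantom$grid$spacing,
                              shape = config$phantom$grid$shape),
                  registration = unclass(config$registration),
                  block = unclass(config$block),
                  weighting_p = config$weighting_p)
  jsonlite::write_json(cfg_ser, cfg_path, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  pipeline_log("simulate", cfg_hash, "generating %d-case cohort (seed %d)",
               config$n_cases, config$phantom$seed)
  cohort <- run_stage("simulate", make_phantom_cohort(config$n_cases, config$phantom))
  cohort_dir <- file.path(out, "cohort")
  for (cs in cohort$cases) write_case_dir(cs, file.path(cohort_dir, cs$id))

  ti <- if (is.null(config$test_index)) config$n_cases else config$test_index
  test <- cohort$cases[[ti]]
  atlas_cases <- cohort$cases[-ti]
  pipeline_log("build-atlas", test$id, "atlas of %d members, reference '%s'",
               length(atlas_cases), atlas_cases[[1]]$id)
  atlas <- run_stage("build-atlas",
                     build_atlas(atlas_cases, atlas_cases[[1]]$id,
                                 config$registration))

  pipeline_log("predict", test$id, "predicting dose (p = %g)",
               config$weighting_p)
  pred <- run_stage("predict",
                    suppressWarnings(predict_dose(atlas, test,
                                                  p = config$weighting_p)))
  write_mha(pred$predicted_dose, file.path(out, "predicted_dose.mha"))

  pipeline_log("make-block", test$id, "threshold %.2f Gy",
               config$block$threshold_gy)
  iso <- extract_isodose(pred$predicted_dose, config$block$threshold_gy)
  block <- make_complete_block(test$structures$masks$Body, iso, config$block)
  write_mha(block, file.path(out, "complete_block.mha"))
  rtstruct_path <- file.path(out, "block_rtstruct.dcm")
  export_block(block, test, rtstruct_path)
  if (config$write_dicom)
    write_dicom_case(test, file.path(out, "dicom", test$id))

  pipeline_log("evaluate", test$id, "plan metrics and block constraints")
  metrics <- plan_metrics(test, dose = test$dose)
  metrics_path <- file.path(out, "metrics.csv")
  write.csv(cbind(config_hash = cfg_hash, metrics), metrics_path,
            row.names = FALSE)
  blk_report <- check_block_dose(block, pred$predicted_dose)
  goals <- evaluate_clinical_goals(test)
  write.csv(cbind(config_hash = cfg_hash, goals),
            file.path(out, "clinical_goals.csv"), row.names = FALSE)

  loo_path <- NULL
  if (config$run_loo) {
    pipeline_log("validate-loo", "cohort", "leave-one-out over %d cases",
                 config$n_cases)
    loo <- run_stage("validate-loo",
                     suppressWarnings(leave_one_out(
                       cohort$cases, config$registration,
                       config$block$threshold_gy, config$weighting_p)))
    loo_path <- file.path(out, "loo.csv")
    write.csv(cbind(config_hash = cfg_hash, loo$per_case), loo_path,
              row.names = FALSE)
  }

  manifest <- list(
    config_hash = cfg_hash,
    package_version = as.character(utils::packageVersion("dosemimic")),
    test_case = test$id,
    weights = stats::setNames(as.list(pred$weights$weight),
                              pred$member_ids),
    block = blk_report,
    artifacts = list(config = cfg_path, cohort = cohort_dir,
                     predicted_dose = file.path(out, "predicted_dose.mha"),
                     complete_block = file.path(out, "complete_block.mha"),
                     block_rtstruct = rtstruct_path,
                     metrics = metrics_path, loo = loo_path))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
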