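#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults match the
#' analysis settings throughout the package: 8 gray levels, unit pair
#' distance, stepwise thresholds 0.05 in / 0.15 out, 12 training
#' subjects, 100 cross-validation repeats.
#'
#' @param image_config an [image_gen_config()] to synthesize a cohort,
#'   or NULL when `manifest_path` is given.
#' @param manifest_path CSV manifest of existing NIfTI masks (columns
#'   `subject_id`, `roi_id`, `mask_path`, `label`) — mutually exclusive
#'   with `image_config`.
#' @param volume_paths named character vector (subject id -> mean-volume
#'   NIfTI path); required with `manifest_path`.
#' @param n_levels,distance texture settings.
#' @param p_enter,p_remove stepwise thresholds.
#' @param n_train,n_repeats evaluation settings.
#' @param seed RNG seed for splits (and the generator, if used).
#' @param out_dir output directory, or NULL to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(image_config = image_gen_config(),
                       manifest_path = NULL, volume_paths = NULL,
                       n_levels = 8L, distance = 1L,
                       p_enter = 0.05, p_remove = 0.15,
                       n_train = 12L, n_repeats = 100L,
                       seed = 1L, out_dir = NULL) {
  if (is.null(image_config) && is.null(manifest_path))
    stop("either `image_config` or `manifest_path` must be given", call. = FALSE)
  if (!is.null(manifest_path) && is.null(volume_paths))
    stop("`volume_paths` is required with `manifest_path`", call. = FALSE)
  structure(list(image_config = image_config, manifest_path = manifest_path,
                 volume_paths = volume_paths, n_levels = as.integer(n_levels),
                 distance = as.integer(distance), p_enter = p_enter,
                 p_remove = p_remove, n_train = as.integer(n_train),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

load_cohort <- function(config) {
  if (!is.null(config$manifest_path)) {
    manifest <- read_roi_manifest(config$manifest_path)
    volumes <- lapply(config$volume_paths, read_volume)
    rois <- lapply(seq_len(nrow(manifest)), function(i) {
      row <- manifest[i, ]
      if (!file.exists(row$mask_path))
        stop("[load] mask file missing for ROI ", row$roi_id, ": ",
             row$mask_path, call. = FALSE)
      roi_mask(RNifti::readNifti(row$mask_path) != 0,
               subject_id = row$subject_id, roi_id = row$roi_id,
               label = row$label)
    })
    list(volumes = volumes, rois = rois,
         manifest = manifest[c("subject_id", "roi_id", "label")])
  } else {
    ic <- config$image_config
    ic$seed <- config$seed
    generate_volume_dataset(ic)
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full texture-analysis pipeline
#'
#' Extract (ROI texture features) -> univariate statistics ->
#' correlations of the significant features -> forward stepwise logistic
#' model on the full table -> patient-grouped cross-validated
#' evaluation. All stage outputs are returned, and written under
#' `config$out_dir` (CSV/JSON plus a manifest recording configuration,
#' seed and package version) when it is set. Given the same config and
#' seed the run is bit-reproducible.
#'
#' @param config a [run_config()].
#' @return List with `feature_table`, `univariate`, `correlations`,
#'   `model`, `evaluation`, `label_summary`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- stage("load", load_cohort(config))
  feature_table <- stage("extract",
    extract_feature_table(cohort$volumes, cohort$rois,
                          n_levels = config$n_levels,
                          distance = config$distance))
  label_summary <- summarize_labels(feature_table$label)
  uni <- stage("stats", univariate_table(feature_table))
  sig <- uni$feature[order(uni$p_value)][seq_len(min(4L, nrow(uni)))]
  correlations <- stage("stats", feature_correlations(feature_table, sig))
  model <- stage("fit", suppressWarnings(
    stepwise_select(feature_table, p_enter = config$p_enter,
                    p_remove = config$p_remove)))
  plans <- make_splits(unique(feature_table$subject_id),
                       n_train = config$n_train,
                       n_repeats = config$n_repeats, seed = config$seed)
  evaluation <- stage("evaluate", suppressWarnings(
    run_cv(feature_table, plans, p_enter = config$p_enter,
           p_remove = config$p_remove)))

  result <- list(feature_table = feature_table, univariate = uni,
                 correlations = correlations, model = model,
                 evaluation = evaluation, label_summary = label_summary,
                 config = config)
  if (!is.null(config$out_dir)) write_run_artifacts(result, config$out_dir)
  result
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(result$feature_table, file.path(out_dir, "feature_table.csv"))
  utils::write.csv(result$univariate, file.path(out_dir, "univariate.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$correlations),
                   file.path(out_dir, "correlations.csv"))
  write_stepwise_model(result$model, file.path(out_dir, "model.json"))
  write_eval_result(result$evaluation,
                    json_path = file.path(out_dir, "evaluation.json"),
                    csv_path = file.path(out_dir, "evaluation_repeats.csv"))
  cfg <- result$config
  cfg$image_config <- unclass(cfg$image_config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fmritex")),
    config = unclass(cfg), label_summary = result$label_summary)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
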