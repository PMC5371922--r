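#' Full-pipeline configuration
#'
#' Bundles every stage's parameters into one serializable object. Either
#' `input_dir` (WAVs plus a `labels.csv` sidecar) or `simulate` (a list with
#' `n_normal`, `n_pathological`) must be supplied to [run_pipeline()].
#'
#' @param input_dir Directory of input WAV recordings, or `NULL` to simulate.
#' @param output_dir Directory for per-stage artifacts.
#' @param simulate `NULL`, or list(n_normal, n_pathological) to generate a
#'   synthetic dataset.
#' @param synth A [synth_config] used when simulating.
#' @param analysis_rate_hz Internal analysis rate; recordings at other rates
#'   are resampled on ingestion.
#' @param filter A [filter_spec].
#' @param wavelet A [gabor_wavelet_spec].
#' @param peak_threshold Wavelet peak threshold (normalized units).
#' @param min_separation_s Minimum peak spacing, seconds.
#' @param selection_threshold DTW coverage threshold.
#' @param constraint A [dtw_constraint].
#' @param segment_length,overlap_fraction Bispectrum estimator parameters.
#' @param k,regularization Cross-validation folds and SVM cost.
#' @param seed Master seed (simulation and fold shuffling).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = tempfile("pcgkit"),
                            simulate = NULL, synth = synth_config(),
                            analysis_rate_hz = 4000,
                            filter = filter_spec(),
                            wavelet = gabor_wavelet_spec(),
                            peak_threshold = 0.1, min_separation_s = 0.06,
                            selection_threshold = 0.005,
                            constraint = dtw_constraint("sakoe_chiba"),
                            segment_length = 256, overlap_fraction = 0.5,
                            k = 8, regularization = 1, seed = 42L) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 simulate = simulate, synth = synth,
                 analysis_rate_hz = analysis_rate_hz, filter = filter,
                 wavelet = wavelet, peak_threshold = peak_threshold,
                 min_separation_s = min_separation_s,
                 selection_threshold = selection_threshold,
                 constraint = constraint, segment_length = segment_length,
                 overlap_fraction = overlap_fraction, k = k,
                 regularization = regularization, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (nm %in% c("synth", "filter", "wavelet", "constraint")) {
      ctor <- switch(nm, synth = synth_config, filter = filter_spec,
                     wavelet = gabor_wavelet_spec, constraint = dtw_constraint)
      cfg[[nm]] <- do.call(ctor, raw[[nm]])
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- lapply(config, function(v) if (is.list(v)) unclass(v) else v)
  yaml::write_yaml(plain, path)
  invisible(path)
}

# Analyse one recording through denoise -> segment -> select -> features.
analyse_recording <- function(rec, config) {
  if (rec$sample_rate_hz != config$analysis_rate_hz) {
    rec <- resample_recording(rec, config$analysis_rate_hz)
  }
  rec <- bandpass_filter(rec, config$filter)
  rec <- normalize_amplitude(rec)
  env <- gabor_wavelet_transform(rec, config$wavelet)
  peaks <- detect_peaks(env, rec$sample_rate_hz, config$peak_threshold,
                        config$min_separation_s)
  events <- label_events(peaks)
  cycles <- extract_cycles(rec, events)
  if (length(cycles) == 0) stop_param("no complete cardiac cycle extracted")
  selection <- select_representatives(cycles, config$selection_threshold,
                                      config$constraint)
  features <- extract_features(selection, cycles, config$segment_length,
                               config$overlap_fraction)
  list(events = events, cycles = cycles, selection = selection,
       features = features)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Run the whole diagnosis pipeline
#'
#' Executes simulate/ingest, denoise, segmentation, cycle selection, feature
#' extraction and cross-validated classification in order, persisting every
#' intermediate under `output_dir` (events CSVs, selection JSONs,
#' `features.csv`, `report.json`, `roc.csv`, and a `manifest.json` recording
#' the configuration, seed and per-stage record counts). A recording that
#' fails any stage is skipped and listed in the manifest; it never aborts the
#' batch. Two runs with the same configuration produce identical outputs.
#'
#' @param config A [pipeline_config].
#' @return List with `report` (a `pcg_eval`), `features` (data frame) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "events"), showWarnings = FALSE)
  dir.create(file.path(out, "selection"), showWarnings = FALSE)

  recordings <- list()
  if (!is.null(config$simulate)) {
    ds <- generate_dataset(config$simulate$n_normal,
                           config$simulate$n_pathological,
                           base_config = config$synth, seed = config$seed)
    recordings <- lapply(ds, `[[`, "recording")
  } else {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir)) {
      stop_param("no inputs: `input_dir` missing and simulation not requested")
    }
    wavs <- list.files(config$input_dir, pattern = "\\.wav$",
                       full.names = TRUE)
    if (length(wavs) == 0) {
      stop_param("no inputs: no .wav files in ", config$input_dir)
    }
    labels <- read_labels(file.path(config$input_dir, "labels.csv"))
    lab <- labels$label[match(basename(wavs), labels$file)]
    recordings <- Map(function(p, l) {
      r <- read_wav(p)
      r$label <- l
      r
    }, wavs, as.list(lab))
  }

  feats <- list(); ids <- character(0); labs <- character(0)
  failed <- list()
  for (rec in recordings) {
    res <- tryCatch(analyse_recording(rec, config), error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1L]] <- list(id = rec$subject_id,
                                            error = conditionMessage(res))
      next
    }
    id <- rec$subject_id
    write.csv(res$events, file.path(out, "events", paste0(id, ".csv")),
              row.names = FALSE, quote = FALSE)
    write_json_artifact(
      res$selection[c("representative_indices", "assignment",
                      "assigned_distance", "coverage_threshold",
                      "max_assigned_distance")],
      file.path(out, "selection", paste0(id, ".json")))
    feats[[length(feats) + 1L]] <- res$features
    ids <- c(ids, id)
    labs <- c(labs, if (is.null(rec$label)) NA_character_ else rec$label)
  }
  if (length(feats) == 0) stop_param("every recording failed analysis")

  fdf <- as.data.frame(do.call(rbind, feats))
  fdf <- cbind(subject_id = ids, fdf, label = labs)
  write.csv(fdf, file.path(out, "features.csv"), row.names = FALSE,
            quote = FALSE)

  report <- NULL
  if (all(!is.na(labs)) && length(unique(labs)) == 2) {
    y <- ifelse(labs == "normal", 1, -1)
    x <- as.matrix(fdf[, !(names(fdf) %in% c("subject_id", "label"))])
    report <- kfold_cross_validate(x, y, k = config$k, seed = config$seed,
                                   regularization = config$regularization)
    write_json_artifact(list(confusion = report$confusion,
                             accuracy_percent = report$accuracy_percent,
                             per_class_percent = report$per_class_percent,
                             auc = report$auc,
                             fold_assignments = report$fold_assignments),
                        file.path(out, "report.json"))
    write.csv(report$roc_points, file.path(out, "roc.csv"),
              row.names = FALSE, quote = FALSE)
  }

  manifest <- list(seed = config$seed,
                   n_input = length(recordings),
                   n_analysed = length(ids),
                   n_failed = length(failed),
                   failed = failed,
                   config = lapply(unclass(config)[
                     setdiff(names(config), c("input_dir", "output_dir"))],
                     function(v) if (is.list(v)) unclass(v) else v))
  write_json_artifact(manifest, file.path(out, "manifest.json"))
  list(report = report, features = fdf, manifest = manifest)
}
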