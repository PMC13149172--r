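#' Analyze a single trace end to end
#'
#' Conditioning, beat detection, per-beat measurement, EAD detection,
#' rhythm classification, and the per-recording summary, in one call.
#'
#' @param trace a raw [fluor_trace()].
#' @param recording_id identifier for the summary row.
#' @param preprocess named list of [preprocess_trace()] arguments.
#' @param detect named list of [detect_beats()] arguments.
#' @param thresholds classifier threshold overrides
#'   (see [rhythm_thresholds()]).
#' @param reference_freq optional reference frequency for the relative
#'   tachycardia rule.
#' @return list: `trace` (conditioned), `beats`, `metrics`, `ead_counts`,
#'   `assessment`, `summary` (the summary row carries the label string and
#'   arrhythmic flag).
#' @export
analyze_trace <- function(trace, recording_id = "recording",
                          preprocess = list(), detect = list(),
                          thresholds = list(), reference_freq = NULL) {
  tr <- do.call(preprocess_trace, c(list(trace = trace), preprocess))
  beats <- do.call(detect_beats, c(list(trace = tr), detect))
  metrics <- measure_beats(tr, beats)
  window <- length(trace$values) / trace$frame_rate
  eads <- detect_ead(tr, metrics,
                     delta = utils::modifyList(rhythm_thresholds(),
                                               thresholds)$ead_delta)
  assess <- classify_rhythm(metrics$activation_time, window,
                            ead_counts = eads, thresholds = thresholds,
                            reference_freq = reference_freq)
  summ <- summarize_syncytium(metrics, window, recording_id,
                              trace$modality)
  summ$labels <- paste(assess$labels, collapse = "+")
  summ$arrhythmic <- assess$arrhythmic
  list(trace = tr, beats = beats, metrics = metrics, ead_counts = eads,
       assessment = assess, summary = summ)
}

#' Analyze a recording (movie) end to end
#'
#' Global-ROI trace analysis plus, when the field is large enough and a
#' propagated beat is available, activation mapping and conduction
#' velocity.
#'
#' @param movie a [fluor_movie()].
#' @param min_pixels_cv minimum number of pixels before conduction
#'   velocity is attempted (default 256).
#' @inheritParams analyze_trace
#' @param cv named list of extra arguments for [recording_cv()].
#' @return as [analyze_trace()], plus `cv` (a `conduction_estimate` or
#'   `NULL`); the summary row gains `cv_median` / `cv_mean` columns.
#' @export
analyze_recording <- function(movie, preprocess = list(), detect = list(),
                              thresholds = list(), reference_freq = NULL,
                              min_pixels_cv = 256, cv = list()) {
  stopifnot(inherits(movie, "fluor_movie"))
  res <- analyze_trace(extract_trace(movie, "global"),
                       recording_id = movie$recording_id,
                       preprocess = preprocess, detect = detect,
                       thresholds = thresholds,
                       reference_freq = reference_freq)
  d <- dim(movie$frames)
  est <- NULL
  if (d[2] * d[3] >= min_pixels_cv && nrow(res$beats)) {
    est <- tryCatch(
      do.call(recording_cv, c(list(movie = movie, beats = res$beats), cv)),
      error = function(e) {
        message("conduction velocity skipped for ", movie$recording_id,
                ": ", conditionMessage(e))
        NULL
      })
  }
  res$cv <- est
  res$summary$cv_median <- if (!is.null(est)) est$median_cv else NA_real_
  res$summary$cv_mean <- if (!is.null(est)) est$mean_cv else NA_real_
  res
}

#' Simulate a cohort to disk
#'
#' Runs [generate_cohort()] and writes each recording (TIFF or HDF5 via
#' [write_movie()]), the combined ground-truth beat table
#' (`truth_beats.csv`), the per-recording label table (`truth_table.csv`),
#' and a manifest (`manifest.json`: seed, group sizes, package version),
#' so a simulation is fully reproducible from its output directory.
#'
#' @param groups cohort specification, as in [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param format `"tiff"` or `"hdf5"`.
#' @return the [generate_cohort()] result, invisibly.
#' @export
run_simulate <- function(groups, out_dir, seed = 1L, format = "tiff") {
  coh <- generate_cohort(groups, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "hdf5") ".h5" else ".tif"
  for (rec in coh$recordings)
    write_movie(rec$movie,
                file.path(out_dir, paste0(rec$movie$recording_id, ext)),
                format = format)
  utils::write.csv(coh$beats, file.path(out_dir, "truth_beats.csv"),
                   row.names = FALSE)
  utils::write.csv(coh$table, file.path(out_dir, "truth_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, format = format,
         groups = lapply(groups, function(g) list(n = g$n)),
         n_recordings = length(coh$recordings),
         package = as.character(utils::packageVersion("cardiomap"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(coh)
}

#' Analyze a directory of recordings
#'
#' Reads every movie in `in_dir` (TIFF with sidecar, or HDF5), analyzes
#' each, and writes per-recording beat tables
#' (`<id>_beats.csv`), assessments (`<id>_assessment.json`), the cohort
#' summary table (`summary.csv`) and a manifest. Outputs are deterministic
#' given inputs and parameters. An unreadable recording is skipped with a
#' logged error; the run fails only if every recording fails.
#'
#' @param in_dir directory of recordings (or a list of [fluor_movie()]
#'   objects).
#' @param out_dir output directory.
#' @param frame_rate,pixel_pitch,modality metadata overrides passed to
#'   [read_movie()] (usually unnecessary when sidecars exist).
#' @inheritParams analyze_recording
#' @return data frame of per-recording summaries, invisibly.
#' @export
run_analyze <- function(in_dir, out_dir, frame_rate = NULL,
                        pixel_pitch = NULL, modality = NULL,
                        preprocess = list(), detect = list(),
                        thresholds = list(), reference_freq = NULL,
                        min_pixels_cv = 256, cv = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(in_dir)) {
    paths <- list.files(in_dir, pattern = "\\.(tif|tiff|h5|hdf5)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (!length(paths)) stop("no recordings found in ", in_dir)
    loaders <- lapply(paths, function(p) function()
      read_movie(p, frame_rate = frame_rate, pixel_pitch = pixel_pitch,
                 modality = modality))
  } else {
    loaders <- lapply(in_dir, function(m) function() m)
    paths <- vapply(in_dir, function(m) m$recording_id, character(1))
  }
  summaries <- list()
  failed <- character(0)
  for (i in seq_along(loaders)) {
    res <- tryCatch({
      movie <- loaders[[i]]()
      analyze_recording(movie, preprocess = preprocess, detect = detect,
                        thresholds = thresholds,
                        reference_freq = reference_freq,
                        min_pixels_cv = min_pixels_cv, cv = cv)
    }, error = function(e) {
      message("skipping ", paths[i], ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      failed <- c(failed, paths[i])
      next
    }
    id <- res$summary$recording_id
    utils::write.csv(res$metrics,
                     file.path(out_dir, paste0(id, "_beats.csv")),
                     row.names = FALSE)
    a <- res$assessment
    jsonlite::write_json(
      list(recording_id = id, labels = a$labels, arrhythmic = a$arrhythmic,
           evidence = a$evidence, thresholds = a$thresholds),
      file.path(out_dir, paste0(id, "_assessment.json")),
      auto_unbox = TRUE, digits = NA)
    summaries[[length(summaries) + 1L]] <- res$summary
  }
  if (!length(summaries))
    stop("all recordings failed to analyze (",
         paste(failed, collapse = ", "), ")")
  tab <- do.call(rbind, summaries)
  utils::write.csv(tab, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_analyzed = nrow(tab), n_skipped = length(failed),
         skipped = failed,
         package = as.character(utils::packageVersion("cardiomap"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

#' Compare a cohort metric across groups
#'
#' Thin wrapper over [compare_groups()] for tidy `(recording_id, group,
#' value)` tables (CSV path or data frame), writing an optional JSON
#' report.
#'
#' @param table data frame or CSV path with columns `group` and `value`
#'   (or `metric` columns selected via `metric`).
#' @param metric when the table is a cohort summary, the column to
#'   compare.
#' @param alpha significance level.
#' @param out optional JSON report path.
#' @return a `group_comparison`.
#' @export
run_compare <- function(table, metric = "value", alpha = 0.05, out = NULL) {
  if (is.character(table)) table <- utils::read.csv(table)
  stopifnot("group" %in% names(table), metric %in% names(table))
  cmp <- compare_groups(table[[metric]], table$group, alpha = alpha)
  if (!is.null(out)) {
    jsonlite::write_json(
      list(metric = metric, branch = cmp$branch,
           summary = cmp$summary, normality_p = as.list(cmp$normality_p),
           variance_p = cmp$variance_p, omnibus = cmp$omnibus,
           pairwise = cmp$pairwise, alpha = cmp$alpha,
           alpha_adjusted = cmp$alpha_adjusted, notes = cmp$notes),
      out, auto_unbox = TRUE, digits = NA)
  }
  cmp
}
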