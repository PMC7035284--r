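#' End-to-end pipeline: simulate/load, extract, fit, score, profile
#'
#' Runs the whole assessment pipeline and writes its artifacts under
#' `out_dir`: the cohort feature table (`features.csv`), the norm model
#' (`norms.json`), the five scale models (`scale_<category>.json`), the
#' scores table (`scores.csv`), per-child profiles (`profiles.json`) and a
#' run manifest (`manifest.json`) capturing the full configuration.
#' Deterministic given the configuration and seed: a rerun writes
#' byte-identical scores.
#'
#' Input is either a directory of recording files (`input_dir`) with an
#' optional `labels.csv`, or — when `input_dir` is `NULL` — a cohort
#' simulated from `n_school`/`n_atypical`.
#'
#' @param out_dir Output directory (created if missing).
#' @param input_dir Optional directory of recording CSV/JSON files.
#' @param n_school,n_atypical Simulated group sizes when `input_dir` is
#'   `NULL`.
#' @param seed Seed for simulation and clustering.
#' @param duration_s Simulated recording length (see
#'   [simulate_recording()]).
#' @param alpha,beta Score parameters (see [fit_norms()]).
#' @param fractions Severity threshold fractions (see
#'   [threshold_from_quantiles()]).
#' @param restarts K-means restarts.
#' @param write_recordings Also write the simulated recordings as CSV files
#'   under `out_dir/recordings/` (off by default; they are large).
#' @param config Extraction constants, [handscale_config()].
#' @return Invisibly, a list with the in-memory artifacts (`cohort`,
#'   `norms`, `scales`, `scores`, `profiles`, paths).
#' @export
run_pipeline <- function(out_dir, input_dir = NULL,
                         n_school = 100, n_atypical = 20, seed = 1,
                         duration_s = 115, alpha = log(2), beta = 2,
                         fractions = c(vs = 0.02, s = 0.086, m = 0.15,
                                       l = 0.25),
                         restarts = 50, write_recordings = FALSE,
                         config = handscale_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(input_dir)) {
    if (!dir.exists(input_dir)) {
      abort(paste0("input directory not found: ", input_dir),
            class = "handscale_io_error")
    }
    paths <- list.files(input_dir, pattern = "\\.(csv|json)$",
                        full.names = TRUE)
    paths <- paths[!grepl("(labels\\.csv|\\.meta\\.json)$", paths)]
    if (!length(paths)) {
      abort(paste0("no recording files in: ", input_dir),
            class = "handscale_io_error")
    }
    recordings <- lapply(paths, read_recording)
    labels_path <- file.path(input_dir, "labels.csv")
    labels <- if (file.exists(labels_path)) {
      tibble::as_tibble(utils::read.csv(labels_path,
                                        stringsAsFactors = FALSE))
    } else NULL
    message("loaded ", length(recordings), " recording(s) from ", input_dir)
  } else {
    sim <- simulate_cohort(n_school, n_atypical, seed = seed,
                           duration_s = duration_s)
    recordings <- sim$recordings
    labels <- sim$labels
    message("simulated cohort: ", n_school, " school + ", n_atypical,
            " atypical writer(s)")
    if (write_recordings) {
      rec_dir <- file.path(out_dir, "recordings")
      dir.create(rec_dir, showWarnings = FALSE)
      for (rec in recordings) {
        write_recording(rec, file.path(
          rec_dir, paste0(rec_meta(rec)$child_id, ".csv")))
      }
      utils::write.csv(labels, file.path(rec_dir, "labels.csv"),
                       row.names = FALSE)
    }
  }

  ex <- extract_cohort(recordings, labels = labels, config = config)
  message("extracted ", sum(grepl("^f_", names(ex$cohort))),
          " features for ", nrow(ex$cohort), " children")
  write_cohort(ex$cohort, file.path(out_dir, "features.csv"))

  norms <- fit_norms(ex$cohort, reference_spectra = ex$reference_spectra,
                     alpha = alpha, beta = beta)
  write_norm_model(norms, file.path(out_dir, "norms.json"))
  message("fitted ", nrow(norms$curves), " norm curves")

  scales <- fit_scales(ex$cohort, norms, restarts = restarts, seed = seed,
                       fractions = fractions)
  for (ct in names(scales)) {
    write_scale_model(scales[[ct]],
                      file.path(out_dir, paste0("scale_", ct, ".json")))
  }
  message("fitted 5 scale models (total + 4 categories)")

  scores <- score_cohort(ex$cohort, scales$total, norms)
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)

  profiles <- lapply(seq_len(nrow(ex$cohort)), function(i) {
    row <- ex$cohort[i, ]
    feats <- cohort_row_features(row)
    profile(feats, row$age, row$gender, scales, norms,
            child_id = row$child_id)
  })
  jsonlite::write_json(
    lapply(profiles, function(p) list(
      child_id = p$child_id, global_score = p$global_score,
      category_scores = p$category_scores, severity = p$severity)),
    file.path(out_dir, "profiles.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("handscale")),
    seed = seed, n_children = nrow(ex$cohort),
    n_school = if (is.null(input_dir)) n_school else NA,
    n_atypical = if (is.null(input_dir)) n_atypical else NA,
    input_dir = input_dir %||% NA, duration_s = duration_s,
    alpha = alpha, beta = beta, fractions = as.list(fractions),
    restarts = restarts, config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message("scores written for ", nrow(scores), " children -> ",
          file.path(out_dir, "scores.csv"))
  invisible(list(cohort = ex$cohort, reference_spectra = ex$reference_spectra,
                 norms = norms, scales = scales, scores = scores,
                 profiles = profiles, out_dir = out_dir))
}

# one cohort row -> long feature tibble
cohort_row_features <- function(row) {
  fcols <- grep("^f_\\d+$", names(row), value = TRUE)
  tibble::tibble(
    feature_id = as.integer(sub("^f_", "", fcols)),
    value = as.numeric(unlist(row[fcols])))
}
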