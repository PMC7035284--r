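#' Read a pen recording from disk
#'
#' Two dialects are supported. The CSV dialect has a header
#' `stroke_id,t,x,y,pressure,azimuth,altitude` (optionally `line_id`), one
#' row per sample, with writer metadata either in `# key=value` comment
#' lines at the top of the file or in a JSON sidecar `<path>.meta.json`.
#' The JSON dialect is a single document
#' `{"meta": {...}, "strokes": [[{t,x,y,pressure,azimuth,altitude}, ...], ...]}`.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A validated [recording()].
#' @export
read_recording <- function(path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("recording file not found: ", path), class = "handscale_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (dialect == "json") read_recording_json(path) else read_recording_csv(path)
}

read_recording_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- parse_meta_comments(lines[is_meta])
  if (!length(meta)) {
    sidecar <- paste0(path, ".meta.json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
    }
  }
  body_lines <- which(!is_meta & nzchar(trimws(lines)))
  if (!length(body_lines)) {
    abort("empty recording: no data rows.", class = "handscale_validation_error")
  }
  header <- strsplit(trimws(lines[body_lines[1]]), ",")[[1]]
  need <- c("stroke_id", "t", "x", "y", "pressure", "azimuth", "altitude")
  if (!all(need %in% header)) {
    abort(paste0("parse error at line ", body_lines[1],
                 ": header must contain ", paste(need, collapse = ",")),
          class = "handscale_parse_error")
  }
  rows <- body_lines[-1]
  if (!length(rows)) {
    abort("empty recording: header but no samples.",
          class = "handscale_validation_error")
  }
  parts <- strsplit(lines[rows], ",")
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    bad <- rows[which(nf != length(header))[1]]
    abort(paste0("parse error at line ", bad, ": expected ",
                 length(header), " fields, found ", nf[which(nf != length(header))[1]]),
          class = "handscale_parse_error")
  }
  m <- matrix(unlist(parts), ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  df <- tibble::as_tibble(m)
  for (cl in intersect(c(need, "line_id"), header)) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !(df[[cl]] %in% c("NA", "")))
    if (length(bad)) {
      abort(paste0("parse error at line ", rows[bad[1]],
                   ": non-numeric value in column ", cl),
            class = "handscale_parse_error")
    }
    df[[cl]] <- v
  }
  if (is.null(meta$age) || is.null(meta$gender)) {
    abort("recording metadata must provide at least age and gender.",
          class = "handscale_validation_error")
  }
  rate <- as.numeric(meta$sampling_rate_hz %||% 60)
  # dialects that supply only sample indices: t = index / rate
  if (!"t" %in% header && "index" %in% header) df$t <- df$index / rate
  recording(df,
            age = as.numeric(meta$age), gender = as.character(meta$gender),
            laterality = as.character(meta$laterality %||% "unknown"),
            sampling_rate_hz = rate,
            child_id = as.character(meta$child_id %||% NA_character_))
}

parse_meta_comments <- function(comment_lines) {
  kv <- sub("^\\s*#\\s*", "", comment_lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  if (!length(kv)) return(list())
  keys <- trimws(sub("=.*$", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  setNames(as.list(vals), keys)
}

read_recording_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  meta <- doc$meta
  strokes <- doc$strokes
  if (is.data.frame(strokes)) strokes <- list(strokes)
  samples <- dplyr::bind_rows(
    purrr::imap(strokes, function(s, i) {
      s <- tibble::as_tibble(s)
      s$stroke_id <- as.integer(i)
      s
    })
  )
  recording(samples,
            age = as.numeric(meta$age), gender = as.character(meta$gender),
            laterality = as.character(meta$laterality %||% "unknown"),
            sampling_rate_hz = as.numeric(meta$sampling_rate_hz %||% 60),
            child_id = as.character(meta$child_id %||% NA_character_))
}

#' Write a pen recording to disk
#'
#' Inverse of [read_recording()]: numeric values are printed with full
#' precision so that `read_recording(write_recording(rec))` reproduces the
#' recording field by field.
#'
#' @param rec A validated `recording`.
#' @param path Output file path.
#' @param dialect `"csv"` (with `# key=value` metadata comments) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "recording"))
  validate_recording(rec)
  m <- rec_meta(rec)
  if (dialect == "json") {
    idx <- stroke_index(rec)
    strokes <- lapply(seq_len(nrow(idx)), function(i) {
      s <- rec[idx$start[i]:idx$end[i],
               c("t", "x", "y", "pressure", "azimuth", "altitude")]
      as.data.frame(s)
    })
    # I(17) significant digits: doubles round-trip exactly through text
    jsonlite::write_json(list(meta = m, strokes = strokes), path,
                         auto_unbox = TRUE, digits = I(17), na = "null")
    return(invisible(path))
  }
  num <- function(v) sprintf("%.17g", v)
  header <- "stroke_id,t,x,y,pressure,azimuth,altitude,line_id"
  body <- paste(rec$stroke_id, num(rec$t), num(rec$x), num(rec$y),
                num(rec$pressure), num(rec$azimuth), num(rec$altitude),
                ifelse(is.na(rec$line_id), "NA", rec$line_id),
                sep = ",")
  meta_lines <- c(
    if (!is.na(m$child_id)) paste0("# child_id=", m$child_id),
    paste0("# age=", num(m$age)),
    paste0("# gender=", m$gender),
    paste0("# laterality=", m$laterality),
    paste0("# sampling_rate_hz=", num(m$sampling_rate_hz))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(meta_lines, header, body), con)
  invisible(path)
}

#' Read or write a cohort feature table
#'
#' The cohort table is a wide tibble with one row per child: `child_id`,
#' `age`, `gender`, `label` (one of `school`, `dysgraphic`, `unknown`) and
#' one `f_<id>` column per catalogued feature (ids 1-36, 38-63). Missing
#' (quality-flagged) feature values are stored as `NA`.
#'
#' @param path CSV file path.
#' @return `read_cohort`: the cohort tibble.
#' @export
read_cohort <- function(path) {
  df <- tibble::as_tibble(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE))
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_cohort <- function(cohort) {
  need <- c("child_id", "age", "gender", "label")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    abort(paste0("cohort table is missing columns: ", paste(miss, collapse = ", ")),
          class = "handscale_validation_error")
  }
  if (anyDuplicated(cohort$child_id)) {
    abort("cohort child_id values must be unique.",
          class = "handscale_validation_error")
  }
  fcols <- grep("^f_\\d+$", names(cohort), value = TRUE)
  if (!length(fcols)) {
    abort("cohort table has no feature columns (f_<id>).",
          class = "handscale_validation_error")
  }
  tibble::as_tibble(cohort)
}

# feature columns of a cohort table, as integer ids
cohort_feature_ids <- function(cohort) {
  sort(as.integer(sub("^f_", "", grep("^f_\\d+$", names(cohort), value = TRUE))))
}
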