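#' Build a pen recording from a sample table
#'
#' A recording is one child's writing session: an ordered sequence of strokes
#' (maximal pen-down intervals), each stroke an ordered sequence of pen
#' samples. It is represented as a tibble with one row per on-surface sample
#' and columns `stroke_id`, `t` (seconds since recording start), `x`, `y`
#' (device points; `y` grows downward), `pressure` (device units, >= 0),
#' `azimuth` and `altitude` (pen tilt angles, degrees in \[0, 180\]), plus an
#' optional `line_id` giving the line of text a stroke belongs to. Writer
#' metadata (age, gender, laterality, nominal sampling rate, child id) is
#' carried in attributes and retrieved with [rec_meta()].
#'
#' In-air motion is not recorded; pen lifts appear only as time gaps between
#' consecutive strokes. Strokes with fewer than 2 samples are dropped with a
#' warning.
#'
#' @param samples Data frame with columns `stroke_id,t,x,y,pressure,azimuth,
#'   altitude` (and optionally `line_id`), one row per pen sample.
#' @param age Writer age in years (continuous, positive).
#' @param gender `"F"` or `"M"`.
#' @param laterality `"left"`, `"right"` or `"unknown"`.
#' @param sampling_rate_hz Nominal capture frequency, default 60.
#' @param child_id Optional identifier string.
#' @return A validated `recording` tibble.
#' @examples
#' rec <- recording(
#'   tibble::tibble(
#'     stroke_id = 1L, t = c(0, 1/60, 2/60), x = c(0, 1, 2), y = c(0, 0, 0),
#'     pressure = 1, azimuth = 60, altitude = 40
#'   ),
#'   age = 8, gender = "F"
#' )
#' n_strokes(rec)
#' @export
recording <- function(samples, age, gender,
                      laterality = c("unknown", "left", "right"),
                      sampling_rate_hz = 60,
                      child_id = NA_character_) {
  laterality <- match.arg(laterality)
  gender <- as.character(gender)
  if (!gender %in% c("F", "M")) {
    abort("`gender` must be \"F\" or \"M\".", class = "handscale_validation_error")
  }
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age <= 0) {
    abort("`age` must be a single positive number of years.",
          class = "handscale_validation_error")
  }
  cols <- c("stroke_id", "t", "x", "y", "pressure", "azimuth", "altitude")
  missing_cols <- setdiff(cols, names(samples))
  if (length(missing_cols)) {
    abort(paste0("`samples` is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "handscale_validation_error")
  }
  samples <- tibble::as_tibble(samples)
  if (!"line_id" %in% names(samples)) samples$line_id <- NA_integer_
  samples <- samples[, c(cols, "line_id")]
  samples$stroke_id <- as.integer(samples$stroke_id)
  samples$line_id <- as.integer(samples$line_id)

  rec <- tibble::new_tibble(
    samples,
    age = age, gender = gender, laterality = laterality,
    sampling_rate_hz = sampling_rate_hz, child_id = as.character(child_id),
    class = "recording"
  )
  validate_recording(rec)
}

#' Validate a recording
#'
#' Checks the recording invariants: at least one stroke of >= 2 samples,
#' strictly increasing time within each stroke, non-overlapping stroke time
#' ranges ordered by start time, tilt angles within \[0, 180\] degrees,
#' non-negative pressure, and positive total on-surface time. Strokes with
#' fewer than 2 samples are dropped with a warning rather than an error.
#'
#' @param rec A `recording`.
#' @return The (possibly pruned) recording, invisibly valid.
#' @export
validate_recording <- function(rec) {
  if (nrow(rec) == 0L) {
    abort("empty recording: no pen samples.", class = "handscale_validation_error")
  }
  n_by_stroke <- table(rec$stroke_id)
  short <- names(n_by_stroke)[n_by_stroke < 2L]
  if (length(short)) {
    warn(paste0("dropping ", length(short),
                " degenerate stroke(s) with < 2 samples: ",
                paste(short, collapse = ", ")))
    keep <- !rec$stroke_id %in% as.integer(short)
    rec <- rec[keep, , drop = FALSE]
    if (nrow(rec) == 0L) {
      abort("empty recording after dropping degenerate strokes.",
            class = "handscale_validation_error")
    }
  }
  bad_angle <- rec$azimuth < 0 | rec$azimuth > 180 |
    rec$altitude < 0 | rec$altitude > 180
  if (any(bad_angle, na.rm = TRUE) || anyNA(bad_angle)) {
    abort(paste0("tilt angles must lie in [0, 180] degrees; first bad sample row: ",
                 which(bad_angle | is.na(bad_angle))[1]),
          class = "handscale_validation_error")
  }
  if (any(!is.finite(rec$pressure)) || any(rec$pressure < 0)) {
    abort("pressure must be finite and >= 0.", class = "handscale_validation_error")
  }
  # per-stroke monotone time, stroke order and non-overlap
  idx <- stroke_index(rec)
  for (i in seq_len(nrow(idx))) {
    tt <- rec$t[idx$start[i]:idx$end[i]]
    if (any(diff(tt) <= 0)) {
      abort(paste0("timestamps must be strictly increasing within stroke ",
                   idx$stroke_id[i]),
            class = "handscale_validation_error")
    }
  }
  if (nrow(idx) > 1L) {
    starts <- rec$t[idx$start]
    ends <- rec$t[idx$end]
    if (any(diff(starts) <= 0) || any(starts[-1] <= ends[-length(ends)])) {
      abort("strokes must be ordered by start time with non-overlapping time ranges.",
            class = "handscale_validation_error")
    }
  }
  total_on <- sum(rec$t[stroke_index(rec)$end] - rec$t[stroke_index(rec)$start])
  if (!(total_on > 0)) {
    abort("total on-surface time must be > 0.", class = "handscale_validation_error")
  }
  rec
}

#' @export
print.recording <- function(x, ...) {
  m <- rec_meta(x)
  cat(sprintf(
    "<recording> %d samples, %d stroke(s); age %.2f y, gender %s, %s-handed, %g Hz\n",
    nrow(x), n_strokes(x), m$age, m$gender, m$laterality, m$sampling_rate_hz))
  NextMethod()
}

#' Recording metadata
#'
#' @param rec A `recording`.
#' @return A list with `child_id`, `age`, `gender`, `laterality`,
#'   `sampling_rate_hz`.
#' @export
rec_meta <- function(rec) {
  list(
    child_id = attr(rec, "child_id"),
    age = attr(rec, "age"),
    gender = attr(rec, "gender"),
    laterality = attr(rec, "laterality"),
    sampling_rate_hz = attr(rec, "sampling_rate_hz")
  )
}

#' @rdname rec_meta
#' @export
n_strokes <- function(rec) length(unique(rec$stroke_id))

# First/last row index of each stroke, in time order.
stroke_index <- function(rec) {
  r <- rle(rec$stroke_id)
  end <- cumsum(r$lengths)
  tibble::tibble(stroke_id = r$values,
                 start = c(1L, head(end, -1L) + 1L),
                 end = end)
}

#' Concatenate on-surface samples across strokes
#'
#' Returns all on-surface samples in time order together with an index of
#' where each stroke starts and ends, as the attribute `"stroke_index"`
#' (a tibble with columns `stroke_id`, `start`, `end` of row positions).
#' The total row count always equals the sum of the stroke sizes.
#'
#' @param rec A `recording`.
#' @return A tibble of samples with attribute `stroke_index`.
#' @export
concat_samples <- function(rec) {
  out <- tibble::as_tibble(as.data.frame(rec))
  attr(out, "stroke_index") <- stroke_index(rec)
  out
}

#' Assign strokes to lines of text
#'
#' Groups strokes into lines by 1-D single linkage on their median `y`:
#' sorted by median `y`, a new line starts whenever the gap between
#' consecutive medians exceeds `gap_factor` times the median stroke height.
#' Line ids increase with median `y` (top line first, since `y` grows
#' downward). If every stroke already carries a `line_id`, the recording is
#' returned unchanged: explicit labels win. The operation is idempotent and
#' invariant to stroke order up to label renumbering; a single line is a
#' legal outcome.
#'
#' @param rec A `recording`.
#' @param gap_factor Multiplier of the median stroke height used as the
#'   line-gap threshold; default 1.5.
#' @return The recording with `line_id` filled for every stroke.
#' @export
segment_lines <- function(rec, gap_factor = 1.5) {
  if (!anyNA(rec$line_id)) return(rec)
  idx <- stroke_index(rec)
  med_y <- vapply(seq_len(nrow(idx)), function(i)
    median(rec$y[idx$start[i]:idx$end[i]]), numeric(1))
  height <- vapply(seq_len(nrow(idx)), function(i) {
    yy <- rec$y[idx$start[i]:idx$end[i]]
    diff(range(yy))
  }, numeric(1))
  thr <- gap_factor * median(height)
  ord <- order(med_y)
  gaps <- diff(med_y[ord])
  new_line <- c(FALSE, gaps > thr)
  line_of_sorted <- cumsum(new_line) + 1L
  line_by_stroke <- integer(nrow(idx))
  line_by_stroke[ord] <- line_of_sorted
  rec$line_id <- line_by_stroke[match(rec$stroke_id, idx$stroke_id)]
  rec
}
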