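#' Extract the handwriting feature catalogue from a recording
#'
#' Computes the full 62-feature catalogue (or the subset for the given
#' categories): static features 1-12, kinematic 13-23, pressure 24-36 and
#' tilt 38-63. Frequency-comparison features (entropy / correlation /
#' distance of a writer's spectrum against the cohort average) require
#' `ref_spectra`, a named list of reference spectra with elements `tremor`,
#' `speed`, `pressure_rate`, `azimuth_rate`, `altitude_rate` (as stored in a
#' fitted [fit_norms()] model); without it those features are returned `NA`
#' with flag `"no_reference"`. Features whose preconditions are unmet (too
#' few samples for a bin or a spectrum) are `NA` with flag
#' `"insufficient_data"` rather than an error.
#'
#' The writer's own spectra (for building cohort references) are attached as
#' the `"spectra"` attribute of the result.
#'
#' @param rec A [recording()].
#' @param ref_spectra Named list of reference spectra, or `NULL`.
#' @param categories Optional subset of
#'   `c("static", "kinematic", "pressure", "tilt")`.
#' @param config Pipeline constants; see [handscale_config()].
#' @return A tibble with columns `feature_id`, `name`, `category`, `value`,
#'   `flag`, one row per catalogued feature, ordered by id.
#' @export
extract_features <- function(rec, ref_spectra = NULL, categories = NULL,
                             config = handscale_config()) {
  stopifnot(inherits(rec, "recording"))
  rec <- segment_lines(rec)
  fam <- list(
    static = function() static_features(rec, ref_spectra, config),
    kinematic = function() kinematic_features(rec, ref_spectra, config),
    pressure = function() pressure_features(rec, ref_spectra, config),
    tilt = function() tilt_features(rec, ref_spectra, config)
  )
  wanted <- categories %||% names(fam)
  parts <- lapply(fam[wanted], function(f) f())
  out <- dplyr::bind_rows(lapply(parts, `[[`, "values"))
  spectra <- purrr::flatten(lapply(parts, `[[`, "spectra"))
  out <- dplyr::arrange(
    dplyr::left_join(out, feature_catalogue(), by = "feature_id"),
    feature_id)
  out <- out[, c("feature_id", "name", "category", "value", "flag")]
  attr(out, "spectra") <- spectra
  out
}

#' Fixed pipeline constants
#'
#' The numeric constants of the extraction and scaling pipeline, exposed in
#' one place: the 300-point static bins, 600-point spectral bins, 10-sample
#' rate bins, 20-pixel density grid, the tremor window, the smoothing window
#' parameters for the velocity-peaks feature, and the line-gap factor.
#'
#' @param static_bin Points per static (barycenter / bounding box) bin.
#' @param spectral_bin Points per Fourier bin.
#' @param rate_bin Samples per averaged rate bin.
#' @param grid_px Density grid cell size, device points.
#' @param tremor_window Points per tremor direction window.
#' @param smooth_M,smooth_p,smooth_sigma Generalized-Gaussian window length,
#'   shape and width for the velocity-peaks feature.
#' @param line_gap_factor Multiplier of median stroke height for line
#'   segmentation.
#' @param max_gap_s Longest gap (s) a spectral bin may span.
#' @return A named list.
#' @export
handscale_config <- function(static_bin = 300, spectral_bin = 600,
                             rate_bin = 10, grid_px = 20, tremor_window = 10,
                             smooth_M = 3, smooth_p = 0.5, smooth_sigma = 2,
                             line_gap_factor = 1.5, max_gap_s = 1) {
  as.list(environment())
}

# ---- shared helpers ---------------------------------------------------------

flag_row <- function(id, value, flag = "ok") {
  tibble::tibble(feature_id = as.integer(id), value = as.numeric(value),
                 flag = flag)
}

na_rows <- function(ids, flag) {
  tibble::tibble(feature_id = as.integer(ids), value = NA_real_, flag = flag)
}

# values at stroke-interior positions of diff(): drop differences that
# straddle a stroke boundary
within_stroke_diff <- function(v, rec) {
  d <- diff(v)
  idx <- stroke_index(rec)
  boundary <- idx$end[-nrow(idx)]     # diff positions crossing strokes
  if (length(boundary)) d <- d[-boundary]
  d
}

# slope of least-squares line y ~ x; 0-variance x gives NA
ls_slope <- function(y, x) {
  if (length(y) < 2L || sd(x) == 0) return(NA_real_)
  unname(coef(lm(y ~ x))[2])
}

# strict sign inversions of consecutive first differences; zero diffs skipped
count_inversions <- function(diffs) {
  s <- sign(diffs)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}

# generalized-Gaussian smoothing window (length M, shape p, width sigma),
# normalized to unit sum, applied with reflect padding
gen_gauss_smooth <- function(v, M = 3, p = 0.5, sigma = 2) {
  half <- (M - 1) / 2
  k <- seq(-half, half)
  w <- exp(-0.5 * abs(k / sigma)^(2 * p))
  w <- w / sum(w)
  n <- length(v)
  if (n <= M) return(v)
  pad <- half
  padded <- c(v[(pad + 1):2], v, v[(n - 1):(n - pad)])
  as.numeric(stats::filter(padded, w, sides = 2))[(pad + 1):(pad + n)]
}

count_extrema <- function(v) {
  count_inversions(diff(v))
}

# rate-of-change series over averaged bins of `bin` consecutive samples:
# rate_j = |mean_{j+1} - mean_j| / (mid-time_{j+1} - mid-time_j)
rate_series <- function(values, times, bin = 10) {
  nb <- floor(length(values) / bin)
  if (nb < 2L) return(list(rate = numeric(0), t = numeric(0)))
  grp <- rep(seq_len(nb), each = bin)
  v <- values[seq_len(nb * bin)]
  tt <- times[seq_len(nb * bin)]
  bm <- as.numeric(tapply(v, grp, mean))
  bt <- as.numeric(tapply(tt, grp, mean))
  dt <- diff(bt)
  keep <- dt > 0
  list(rate = (abs(diff(bm)) / dt)[keep],
       t = ((bt[-1] + bt[-length(bt)]) / 2)[keep])
}

# total elapsed time from first to last sample of the recording
total_duration <- function(rec) rec$t[nrow(rec)] - rec$t[1]

# spectral 5-feature block for a series; returns rows + the spectrum (or NULL).
# rate_hz is the series' NOMINAL rate so every writer shares one frequency
# grid (a requirement for cohort-average reference spectra).
spectral_rows <- function(ids, series, times, ref, config, rate_hz) {
  if (length(series) < config$spectral_bin) {
    return(list(values = na_rows(ids, "insufficient_data"), spectrum = NULL))
  }
  spec <- tryCatch(
    mean_spectrum(series, times, bin_size = config$spectral_bin,
                  sampling_rate_hz = rate_hz,
                  max_gap_s = config$max_gap_s),
    handscale_insufficient_data = function(e) NULL)
  if (is.null(spec)) {
    return(list(values = na_rows(ids, "insufficient_data"), spectrum = NULL))
  }
  s <- spectral_summary(spec, ref)
  vals <- dplyr::bind_rows(
    flag_row(ids[1], s[["bandwidth"]]),
    flag_row(ids[2], s[["median"]]),
    if (is.null(ref)) na_rows(ids[3:5], "no_reference") else dplyr::bind_rows(
      flag_row(ids[3], s[["entropy"]]),
      flag_row(ids[4], s[["correlation"]]),
      flag_row(ids[5], s[["distance"]]))
  )
  list(values = vals, spectrum = spec)
}

# mean/max/sd + rate stats + slope + inversions + spectral block for one
# scalar channel (pressure, azimuth or altitude)
channel_dynamics <- function(values, rec, ref, config,
                             ids_scalar, ids_rate, id_slope, id_invs,
                             ids_spectral) {
  dur <- total_duration(rec)
  rows <- dplyr::bind_rows(
    flag_row(ids_scalar[1], mean(values)),
    flag_row(ids_scalar[2], max(values)),
    flag_row(ids_scalar[3], sd(values))
  )
  rs <- rate_series(values, rec$t, config$rate_bin)
  if (length(rs$rate) >= 1L) {
    rows <- dplyr::bind_rows(rows,
      flag_row(ids_rate[1], mean(rs$rate)),
      flag_row(ids_rate[2], max(rs$rate)),
      flag_row(ids_rate[3], if (length(rs$rate) > 1) sd(rs$rate) else 0))
    sl <- ls_slope(rs$rate, rs$t)
    rows <- dplyr::bind_rows(rows,
      if (is.na(sl)) na_rows(id_slope, "insufficient_data")
      else flag_row(id_slope, sl))
  } else {
    rows <- dplyr::bind_rows(rows, na_rows(c(ids_rate, id_slope),
                                           "insufficient_data"))
  }
  invs <- count_inversions(within_stroke_diff(values, rec))
  rows <- dplyr::bind_rows(rows, flag_row(id_invs, invs / dur))
  rate_hz <- rec_meta(rec)$sampling_rate_hz / config$rate_bin
  sp <- spectral_rows(ids_spectral, rs$rate, rs$t, ref, config, rate_hz)
  list(values = dplyr::bind_rows(rows, sp$values), spectrum = sp$spectrum)
}

# ---- static features (1-12) -------------------------------------------------

#' @rdname extract_features
#' @export
static_features <- function(rec, ref_spectra = NULL,
                            config = handscale_config()) {
  rec <- segment_lines(rec)
  out <- list()

  # (1)-(2): 300-point bins within a line of text
  bins <- line_bins(rec, config$static_bin)
  if (length(bins$dy_pairs)) {
    out$f1 <- flag_row(1, mean(bins$dy_pairs))
  } else {
    out$f1 <- na_rows(1, "insufficient_data")
  }
  if (length(bins$areas)) {
    out$f2 <- flag_row(2, mean(bins$areas))
  } else {
    out$f2 <- na_rows(2, "insufficient_data")
  }

  # (3) mean pen-lift displacement between consecutive strokes
  idx <- stroke_index(rec)
  if (nrow(idx) > 1L) {
    lx <- rec$x[idx$end[-nrow(idx)]]; ly <- rec$y[idx$end[-nrow(idx)]]
    fx <- rec$x[idx$start[-1]]; fy <- rec$y[idx$start[-1]]
    out$f3 <- flag_row(3, mean(sqrt((fx - lx)^2 + (fy - ly)^2)))
  } else {
    out$f3 <- flag_row(3, 0)
  }

  # (4) density over a grid of `grid_px`-sized cells
  cell <- config$grid_px
  ix <- floor((rec$x - min(rec$x)) / cell)
  iy <- floor((rec$y - min(rec$y)) / cell)
  counts <- table(paste(ix, iy))
  out$f4 <- flag_row(4, mean(as.numeric(counts)))

  # (5) circular mean of step directions; (6) mean absolute turning angle
  dx <- within_stroke_diff(rec$x, rec)
  dy <- within_stroke_diff(rec$y, rec)
  nz <- dx != 0 | dy != 0
  if (any(nz)) {
    th <- atan2(dy[nz], dx[nz])
    out$f5 <- flag_row(5, atan2(mean(sin(th)), mean(cos(th))))
  } else {
    out$f5 <- na_rows(5, "insufficient_data")
  }
  out$f6 <- turning_angle_row(rec)

  # (7) convex hull area of all on-surface points
  out$f7 <- flag_row(7, hull_area(rec$x, rec$y))

  # (8)-(12) spectral summary of the tremor residual signal
  res <- suppressWarnings(
    tremor_signal(rec[, c("x", "y")], window = config$tremor_window))
  res_t <- rec$t[seq_along(res)]
  sp <- spectral_rows(8:12, res, res_t, ref_spectra$tremor, config,
                      rec_meta(rec)$sampling_rate_hz)
  out$f8_12 <- sp$values

  list(values = dplyr::bind_rows(out), spectra = list(tremor = sp$spectrum))
}

line_bins <- function(rec, bin) {
  dys <- numeric(0); areas <- numeric(0)
  for (lid in unique(rec$line_id)) {
    pts <- rec[rec$line_id %in% lid, ]
    nb <- floor(nrow(pts) / bin)
    if (nb < 1L) next
    grp <- rep(seq_len(nb), each = bin)
    xs <- pts$x[seq_len(nb * bin)]; ys <- pts$y[seq_len(nb * bin)]
    by_ <- as.numeric(tapply(ys, grp, mean))
    if (nb >= 2L) dys <- c(dys, abs(diff(by_)))
    w <- as.numeric(tapply(xs, grp, function(v) diff(range(v))))
    h <- as.numeric(tapply(ys, grp, function(v) diff(range(v))))
    areas <- c(areas, w * h)
  }
  list(dy_pairs = dys, areas = areas)
}

turning_angle_row <- function(rec) {
  if (nrow(rec) < 3L) return(na_rows(6, "insufficient_data"))
  idx <- stroke_index(rec)
  angles <- numeric(0)
  for (i in seq_len(nrow(idx))) {
    r <- idx$start[i]:idx$end[i]
    if (length(r) < 3L) next
    ux <- diff(rec$x[r]); uy <- diff(rec$y[r])
    n <- length(ux)
    cx <- ux[-n] * uy[-1] - uy[-n] * ux[-1]
    dt <- ux[-n] * ux[-1] + uy[-n] * uy[-1]
    keep <- (ux[-n] != 0 | uy[-n] != 0) & (ux[-1] != 0 | uy[-1] != 0)
    angles <- c(angles, abs(atan2(cx[keep], dt[keep])))
  }
  if (!length(angles)) return(na_rows(6, "insufficient_data"))
  flag_row(6, mean(angles))
}

hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# ---- kinematic features (13-23) ---------------------------------------------

#' @rdname extract_features
#' @export
kinematic_features <- function(rec, ref_spectra = NULL,
                               config = handscale_config()) {
  vel <- velocity_series(rec)
  out <- list()
  if (length(vel$v) >= 2L) {
    out$stats <- dplyr::bind_rows(
      flag_row(13, mean(vel$v)),
      flag_row(14, max(vel$v)),
      flag_row(15, sd(vel$v)))
    sl <- ls_slope(vel$v, vel$t)
    out$slope <- if (is.na(sl)) na_rows(16, "insufficient_data")
                 else flag_row(16, sl)
    sm <- gen_gauss_smooth(vel$v, config$smooth_M, config$smooth_p,
                           config$smooth_sigma)
    out$peaks <- flag_row(17, count_extrema(sm) / total_duration(rec))
  } else {
    out$stats <- na_rows(13:17, "insufficient_data")
  }
  sp <- spectral_rows(18:22, vel$v, vel$t, ref_spectra$speed, config,
                      rec_meta(rec)$sampling_rate_hz)
  out$spectral <- sp$values

  idx <- stroke_index(rec)
  if (nrow(idx) > 1L) {
    gaps <- rec$t[idx$start[-1]] - rec$t[idx$end[-nrow(idx)]]
    out$air <- flag_row(23, sum(gaps) / total_duration(rec))
  } else {
    out$air <- flag_row(23, 0)
  }
  list(values = dplyr::bind_rows(out), spectra = list(speed = sp$spectrum))
}

# within-stroke pen speed: step length / step duration, at step mid-times
velocity_series <- function(rec) {
  dx <- within_stroke_diff(rec$x, rec)
  dy <- within_stroke_diff(rec$y, rec)
  dt <- within_stroke_diff(rec$t, rec)
  tm <- (rec$t[-1] + rec$t[-nrow(rec)]) / 2
  idx <- stroke_index(rec)
  boundary <- idx$end[-nrow(idx)]
  if (length(boundary)) tm <- tm[-boundary]
  list(v = sqrt(dx^2 + dy^2) / dt, t = tm)
}

# ---- pressure features (24-36) ----------------------------------------------

#' @rdname extract_features
#' @export
pressure_features <- function(rec, ref_spectra = NULL,
                              config = handscale_config()) {
  cd <- channel_dynamics(rec$pressure, rec, ref_spectra$pressure_rate, config,
                         ids_scalar = 24:26, ids_rate = 27:29,
                         id_slope = 30, id_invs = 31, ids_spectral = 32:36)
  list(values = cd$values, spectra = list(pressure_rate = cd$spectrum))
}

# ---- tilt features (38-63) --------------------------------------------------

#' @rdname extract_features
#' @export
tilt_features <- function(rec, ref_spectra = NULL,
                          config = handscale_config()) {
  az <- channel_dynamics(rec$azimuth, rec, ref_spectra$azimuth_rate, config,
                         ids_scalar = 38:40, ids_rate = 44:46,
                         id_slope = 50, id_invs = 52, ids_spectral = 54:58)
  al <- channel_dynamics(rec$altitude, rec, ref_spectra$altitude_rate, config,
                         ids_scalar = 41:43, ids_rate = 47:49,
                         id_slope = 51, id_invs = 53, ids_spectral = 59:63)
  list(values = dplyr::bind_rows(az$values, al$values),
       spectra = list(azimuth_rate = az$spectrum,
                      altitude_rate = al$spectrum))
}

# ---- cohort extraction ------------------------------------------------------

#' Extract features for a whole cohort
#'
#' Two-pass extraction: every recording's features and per-writer spectra
#' are computed first; reference spectra are then taken (or supplied), and
#' the spectrum-comparison features (entropy / correlation / distance per
#' signal kind) are filled in against them. When `ref_spectra` is supplied
#' (e.g. from a previously fitted norm model) it is used as-is, so new
#' children are compared against the original cohort's averages.
#'
#' @param recordings List of [recording()] objects.
#' @param labels Optional tibble `child_id, age, gender, label`; when absent
#'   it is assembled from each recording's metadata with label `"unknown"`.
#' @param ref_spectra Optional named list of reference spectra.
#' @param config See [handscale_config()].
#' @return A list with `cohort` (wide feature table, one `f_<id>` column per
#'   feature), `reference_spectra`, and `flags` (long tibble of per-child
#'   quality flags).
#' @export
extract_cohort <- function(recordings, labels = NULL, ref_spectra = NULL,
                           config = handscale_config()) {
  per_child <- lapply(recordings, function(rec) {
    fv <- extract_features(rec, ref_spectra = NULL, config = config)
    list(fv = fv, spectra = attr(fv, "spectra"), meta = rec_meta(rec))
  })
  kinds <- c("tremor", "speed", "pressure_rate", "azimuth_rate",
             "altitude_rate")
  if (is.null(ref_spectra)) {
    ref_spectra <- lapply(setNames(kinds, kinds), function(k) {
      sp <- purrr::compact(lapply(per_child, function(pc) pc$spectra[[k]]))
      if (length(sp)) reference_spectrum(sp) else NULL
    })
  }
  compare_ids <- list(tremor = 10:12, speed = 20:22, pressure_rate = 34:36,
                      azimuth_rate = 56:58, altitude_rate = 61:63)
  rows <- purrr::imap(per_child, function(pc, i) {
    fv <- pc$fv
    for (k in kinds) {
      spec <- pc$spectra[[k]]; ref <- ref_spectra[[k]]
      ids <- compare_ids[[k]]
      if (!is.null(spec) && !is.null(ref)) {
        cmp <- spectrum_compare(spec, ref)
        fv$value[match(ids, fv$feature_id)] <-
          c(cmp$entropy, cmp$correlation, cmp$distance)
        fv$flag[match(ids, fv$feature_id)] <- "ok"
      }
    }
    cid <- pc$meta$child_id
    if (is.na(cid)) cid <- sprintf("child_%03d", i)
    tibble::tibble(child_id = cid, age = pc$meta$age,
                   gender = pc$meta$gender, fv)
  })
  long <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(long, feature_id = paste0("f_", feature_id)),
    id_cols = c("child_id", "age", "gender"),
    names_from = "feature_id", values_from = "value")
  if (!is.null(labels)) {
    wide <- dplyr::left_join(wide,
      labels[, c("child_id", "label")], by = "child_id")
  } else {
    wide$label <- "unknown"
  }
  wide <- wide[, c("child_id", "age", "gender", "label",
                   paste0("f_", feature_catalogue()$feature_id))]
  list(cohort = wide, reference_spectra = ref_spectra,
       flags = long[, c("child_id", "feature_id", "flag")])
}
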