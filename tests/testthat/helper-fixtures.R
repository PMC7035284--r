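# Fixture builders shared across the test files. Everything is generated in
# code; no stored data.

# one-stroke recording from explicit coordinate/channel vectors
stroke_rec <- function(x, y, t = NULL, pressure = 1, azimuth = 60,
                       altitude = 40, age = 8, gender = "F", rate = 60) {
  n <- length(x)
  if (is.null(t)) t <- seq_len(n) / rate
  recording(tibble::tibble(
    stroke_id = 1L, t = t, x = x, y = rep_len(y, n),
    pressure = rep_len(pressure, n), azimuth = rep_len(azimuth, n),
    altitude = rep_len(altitude, n)),
    age = age, gender = gender, sampling_rate_hz = rate)
}

# multi-stroke recording from a list of per-stroke sample tibbles
strokes_rec <- function(strokes, age = 8, gender = "F", rate = 60) {
  samples <- dplyr::bind_rows(purrr::imap(strokes, function(s, i) {
    s$stroke_id <- as.integer(i)
    s
  }))
  recording(samples, age = age, gender = gender, sampling_rate_hz = rate)
}

# a plain stroke tibble: n samples starting at t0, advancing in x
stroke_tbl <- function(n, t0 = 0, x0 = 0, y = 100, dt = 1 / 60, vx = 60,
                       pressure = 1, azimuth = 60, altitude = 40) {
  tt <- t0 + dt * seq_len(n)
  tibble::tibble(t = tt, x = x0 + vx * dt * seq_len(n), y = rep_len(y, n),
                 pressure = rep_len(pressure, n),
                 azimuth = rep_len(azimuth, n),
                 altitude = rep_len(altitude, n))
}

# random valid recording for round-trip property tests
random_recording <- function(seed, n_strokes = 3) {
  withr::with_seed(seed, {
    t0 <- 0
    strokes <- lapply(seq_len(n_strokes), function(i) {
      n <- sample(5:30, 1)
      s <- tibble::tibble(
        t = t0 + cumsum(runif(n, 0.01, 0.05)),
        x = cumsum(rnorm(n)), y = 100 + cumsum(rnorm(n)),
        pressure = runif(n, 0, 2), azimuth = runif(n, 0, 180),
        altitude = runif(n, 0, 180))
      t0 <<- max(s$t) + runif(1, 0.05, 0.3)
      s
    })
    strokes_rec(strokes, age = runif(1, 5, 12),
                gender = sample(c("F", "M"), 1))
  })
}

# random normalized spectrum on k lines
random_spectrum <- function(seed, k = 32, rate = 60, bin = 2 * k) {
  withr::with_seed(seed, {
    new_spectrum((1:k) * rate / bin, runif(k))
  })
}

# identity norm model: f_mean = 0, f_std = 1 for the given features, so
# standardized deviations equal the raw feature values
identity_norms <- function(feature_ids, age_range = c(5, 12),
                           alpha = log(2), beta = 2) {
  curves <- dplyr::bind_rows(lapply(c("F", "M"), function(g) {
    tibble::tibble(
      feature_id = as.integer(feature_ids), gender = g,
      b0 = 0, b1 = 0, b2 = 0, b3 = 0,
      s0 = 1, s1 = 0, s2 = 0, s3 = 0,
      age_min = age_range[1], age_max = age_range[2],
      n_fit = 100L, std_floor = 1e-9)
  }))
  structure(list(curves = curves, reference_spectra = NULL,
                 alpha = alpha, beta = beta, schema = "handscale-norms-1"),
            class = "norm_model")
}

# hand-built scale model with one-hot axes on the first three features,
# no centering/scaling, typical centroid at the origin
onehot_scale <- function(feature_ids, category = "total", d_ref = 1,
                         thresholds = c(vs = 0.1, s = 0.2, m = 0.3,
                                        l = 0.4)) {
  p <- length(feature_ids)
  stopifnot(p >= 3)
  axes <- diag(p)[, 1:3]
  cols <- paste0("f_", feature_ids)
  structure(
    list(category = category, feature_ids = as.integer(feature_ids),
         center = setNames(rep(0, p), cols),
         spread = setNames(rep(1, p), cols),
         axes = axes, explained_variance_fractions = c(0.5, 0.3, 0.2),
         centroid_typical = c(0, 0, 0), centroid_atypical = c(5, 0, 0),
         d_ref = d_ref, thresholds = thresholds, seed = 1,
         assignments = NULL, schema = "handscale-scale-1"),
    class = "scale_model")
}

# Gaussian two-population cohort feature table: `shift` (in SD units) is
# added to the listed features for the dysgraphic group
gaussian_cohort <- function(n_school, n_dys, feature_ids, shift_ids = NULL,
                            shift = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- n_school + n_dys
    out <- tibble::tibble(
      child_id = sprintf("g%04d", seq_len(n)),
      age = runif(n, 5, 12),
      gender = rep_len(c("F", "M"), n),
      label = rep(c("school", "dysgraphic"), c(n_school, n_dys)))
    for (fid in feature_ids) {
      v <- rnorm(n)
      if (fid %in% shift_ids) {
        v[out$label == "dysgraphic"] <-
          v[out$label == "dysgraphic"] + shift
      }
      out[[paste0("f_", fid)]] <- v
    }
    out
  })
}
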