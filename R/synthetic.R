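#' Deficit severity knobs for the synthetic writer
#'
#' Severity 0 is a typical writer; each knob monotonically worsens the
#' corresponding feature family. `kinematic` adds velocity jitter,
#' high-frequency path tremor and longer pen lifts; `pressure` inflates
#' pressure variability and inversion rate; `tilt` adds pen-orientation
#' wobble; `static` adds line waviness and letter-size irregularity.
#'
#' @param kinematic,pressure,tilt,static Non-negative severities.
#' @return Named list of severities.
#' @export
deficit_profile <- function(kinematic = 0, pressure = 0, tilt = 0,
                            static = 0) {
  stopifnot(kinematic >= 0, pressure >= 0, tilt >= 0, static >= 0)
  list(kinematic = kinematic, pressure = pressure, tilt = tilt,
       static = static)
}

#' Simulate a handwriting recording
#'
#' Generates a multi-line, multi-stroke pen trace with the statistical
#' structure the pipeline assumes: smooth letter-like sinusoidal
#' oscillations advancing in x, sampled at 60 Hz, several strokes per line
#' and several lines per page. It produces plausible *statistics*, not
#' legible handwriting. Age trends are planted as smooth (cubic) functions
#' of age: baseline speed increases with age while speed variability,
#' pressure variability and tremor amplitude decrease; deficit knobs move
#' the corresponding feature families monotonically (see
#' [deficit_profile()]). Everything is reproducible from `seed`.
#'
#' @param age Years, in the supported 5-12 range (values outside are
#'   accepted but extrapolate the trends).
#' @param gender `"F"` or `"M"` (small planted mean offsets in pressure and
#'   tilt).
#' @param deficit A [deficit_profile()].
#' @param seed Integer RNG seed.
#' @param duration_s Target on-surface writing time; the default 115 s
#'   yields about 6,900 on-surface samples, enough for every catalogued
#'   feature (the pressure/tilt rate spectra need >= 601 averaged bins,
#'   i.e. >= 6,010 samples).
#' @param sampling_rate_hz Capture rate, default 60.
#' @param child_id Optional identifier.
#' @return A [recording()].
#' @examples
#' rec <- simulate_recording(age = 8, gender = "F", seed = 42,
#'                           duration_s = 20)
#' n_strokes(rec)
#' @export
simulate_recording <- function(age, gender = "F",
                               deficit = deficit_profile(), seed = 1,
                               duration_s = 115, sampling_rate_hz = 60,
                               child_id = NA_character_) {
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    dt <- 1 / sampling_rate_hz
    kin <- deficit$kinematic; prs <- deficit$pressure
    tlt <- deficit$tilt; sta <- deficit$static

    # planted age trends (smooth cubics over 5-12 y)
    v_age <- 10 + 3 * age + 0.08 * age^2 - 0.002 * age^3   # pts/s, increasing
    cv_age <- max(0.28 - 0.02 * (age - 5), 0.08)           # speed variability
    p_base <- 0.8 + 0.05 * age - 0.001 * age^2 +
      0.06 * (gender == "M")                               # pressure level
    p_sd_age <- max(0.09 - 0.006 * (age - 5), 0.02)
    trem_age <- max(0.35 - 0.03 * (age - 5), 0.08)         # path tremor, pts
    amp <- 14 - 0.4 * (age - 5)                            # letter size, pts
    letter_hz <- 2.5 + 0.25 * age    # strokes/s rises with automation

    line_height <- 60
    strokes_per_line <- 5L
    t_now <- 0; x_pen <- 50
    stroke_list <- list(); sid <- 0L; line <- 0L
    total_on <- 0
    while (total_on < duration_s) {
      if (sid %% strokes_per_line == 0L) {
        line <- line + 1L
        x_pen <- 50
      }
      sid <- sid + 1L
      dur <- runif(1, 2.6, 3.6)
      n <- max(round(dur * sampling_rate_hz), 12L)
      tt <- t_now + dt * seq_len(n)

      # speed: slow AR(1) drift + white jitter, inflated by kinematic deficit
      drift <- as.numeric(stats::filter(rnorm(n, 0, cv_age * sqrt(1 - 0.97^2)),
                                        0.97, method = "recursive"))
      jitter <- rnorm(n, 0, 0.06 + 0.15 * kin)
      vx <- pmax(v_age * (1 + drift + jitter), 1)
      x <- x_pen + cumsum(vx) * dt

      # letter-like oscillation + waviness + high-frequency tremor
      a_str <- amp * (1 + rnorm(1, 0, 0.06 + 0.18 * sta))
      y0 <- 100 + line_height * line +
        (2 + 7 * sta) * sin(2 * pi * 0.12 * tt + line)
      trem_amp <- trem_age * (1 + 2.2 * kin)
      y <- y0 + a_str * sin(2 * pi * letter_hz * tt + runif(1, 0, 2 * pi)) +
        trem_amp * sin(2 * pi * 11 * tt + runif(1, 0, 2 * pi)) +
        rnorm(n, 0, trem_amp * 0.5)
      x <- x + trem_amp * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) +
        rnorm(n, 0, trem_amp * 0.4)

      # pressure: AR(1) around the age level; deficit raises SD + inversions
      p_sd <- p_sd_age * (1 + 1.6 * prs)
      p_ar <- as.numeric(stats::filter(rnorm(n, 0, p_sd * sqrt(1 - 0.9^2)),
                                       0.9, method = "recursive"))
      p_flip <- (0.004 + 0.04 * prs) * rep_len(c(-1, 1), n)
      pressure <- pmax(p_base * (1 + p_ar) + p_flip, 0)

      # tilt: slow drift + wobble scaled by the tilt deficit
      wob <- 1.2 * (1 + 2.2 * tlt)
      azimuth <- 55 + 8 * (gender == "M") +
        6 * sin(2 * pi * 0.05 * tt) +
        as.numeric(stats::filter(rnorm(n, 0, wob * sqrt(1 - 0.92^2)),
                                 0.92, method = "recursive"))
      altitude <- 42 + 5 * sin(2 * pi * 0.04 * tt + 1) +
        as.numeric(stats::filter(rnorm(n, 0, 0.8 * wob * sqrt(1 - 0.92^2)),
                                 0.92, method = "recursive"))
      azimuth <- pmin(pmax(azimuth, 0), 180)
      altitude <- pmin(pmax(altitude, 0), 180)

      stroke_list[[sid]] <- tibble::tibble(
        stroke_id = sid, t = tt, x = x, y = y, pressure = pressure,
        azimuth = azimuth, altitude = altitude)
      total_on <- total_on + dur
      # pen lifts lengthen with the kinematic deficit but stay below the
      # 1 s page-change limit that spectral binning refuses to span
      gap <- min(runif(1, 0.15, 0.4) * (1 + 0.8 * kin), 0.95)
      t_now <- tt[n] + gap
      x_pen <- x[n] + runif(1, 10, 20)
    }
    recording(dplyr::bind_rows(stroke_list), age = age, gender = gender,
              sampling_rate_hz = sampling_rate_hz, child_id = child_id)
  })
}

#' Simulate a two-population cohort of writers
#'
#' `n_school` typical writers (all deficits 0) with ages uniform over
#' `age_range` and the generator's planted age trends, plus `n_atypical`
#' writers sharing the same age/gender distribution but carrying the given
#' deficit profile (each child's severities jittered by a factor uniform on
#' \[0.7, 1.3\] so the atypical population is heterogeneous). Per-writer RNG
#' streams are derived from the single cohort seed, so the cohort is fully
#' reproducible and writers are mutually independent.
#'
#' @param n_school,n_atypical Group sizes. The study design this emulates
#'   used 390 school-recruited and 58 dysgraphic children.
#' @param age_range Years, default `c(5, 12)`.
#' @param gender_mix Fraction of girls, default 0.5.
#' @param deficit Deficit profile of the atypical group; the default
#'   concentrates the deficit in the kinematic and pressure families.
#' @param seed Cohort seed.
#' @param duration_s Per-recording writing time (see
#'   [simulate_recording()]).
#' @return A list with `recordings` (list of [recording()]) and `labels`
#'   (tibble `child_id, age, gender, label`).
#' @export
simulate_cohort <- function(n_school, n_atypical, age_range = c(5, 12),
                            gender_mix = 0.5,
                            deficit = deficit_profile(kinematic = 2.5,
                                                      pressure = 2,
                                                      tilt = 0.8,
                                                      static = 0.8),
                            seed = 1, duration_s = 115) {
  stopifnot(n_school >= 0, n_atypical >= 0, n_school + n_atypical > 0)
  n <- n_school + n_atypical
  plan <- withr::with_seed(as.integer(seed) %% 2147483647L, tibble::tibble(
    child_id = sprintf("child_%04d", seq_len(n)),
    age = runif(n, age_range[1], age_range[2]),
    gender = ifelse(runif(n) < gender_mix, "F", "M"),
    label = rep(c("school", "dysgraphic"), c(n_school, n_atypical)),
    severity_jitter = runif(n, 0.7, 1.3),
    writer_seed = sample.int(2147483646L, n)
  ))
  recordings <- lapply(seq_len(n), function(i) {
    dfc <- if (plan$label[i] == "dysgraphic") {
      j <- plan$severity_jitter[i]
      deficit_profile(deficit$kinematic * j, deficit$pressure * j,
                      deficit$tilt * j, deficit$static * j)
    } else {
      deficit_profile()
    }
    simulate_recording(plan$age[i], plan$gender[i], dfc,
                       seed = plan$writer_seed[i], duration_s = duration_s,
                       child_id = plan$child_id[i])
  })
  list(recordings = recordings,
       labels = plan[, c("child_id", "age", "gender", "label")])
}

#' Simulate a feature-table cohort with a planted cubic age trend
#'
#' Direct generator of a cohort *feature table* (no pen traces) for norm
#' fitting: one feature with mean `mu(age)` given by cubic coefficients and
#' constant SD, sampled for both genders. Used for parameter-recovery
#' checks of [fit_norms()].
#'
#' @param n Children (split evenly between genders).
#' @param coeffs Length-4 cubic coefficients of the mean curve
#'   (intercept, age, age^2, age^3).
#' @param sd Residual SD.
#' @param age_range Years.
#' @param feature_id Id to store the values under; default 13.
#' @param seed RNG seed.
#' @return A cohort tibble with a single feature column.
#' @export
simulate_norm_cohort <- function(n = 400, coeffs = c(2, 0.5, 0, -0.01),
                                 sd = 1, age_range = c(5, 12),
                                 feature_id = 13, seed = 1) {
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    age <- runif(n, age_range[1], age_range[2])
    gender <- rep_len(c("F", "M"), n)
    value <- poly_eval(coeffs, age) + rnorm(n, 0, sd)
    out <- tibble::tibble(child_id = sprintf("sim_%04d", seq_len(n)),
                          age = age, gender = gender, label = "school")
    out[[paste0("f_", feature_id)]] <- value
    out
  })
}
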