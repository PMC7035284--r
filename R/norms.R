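#' Fit age- and gender-conditional norm curves
#'
#' For every feature column and each gender separately, fits a third-degree
#' polynomial `f_mean(age)` to the feature value by least squares, and a
#' third-degree polynomial `f_std(age)` to the standard deviation of the
#' residuals pooled in 1-year age bins (weighted by bin size). Evaluated
#' standard deviations are clipped below at a positive floor
#' (`std_floor_frac` times the cohort SD of the feature) so Z-scores never
#' divide by zero. A rank-deficient fit (fewer distinct ages or bins than
#' coefficients) falls back to the highest degree the data support, with a
#' warning.
#'
#' The fitted model also stores the cohort-average reference spectra used by
#' the spectrum-comparison features, and the score parameters `alpha` and
#' `beta` of the bounded score map `score = exp(-alpha * z^beta)`.
#'
#' @param cohort Cohort feature table (`child_id, age, gender, label,
#'   f_<id>...`); see [read_cohort()]. `NA` feature values are ignored per
#'   fit.
#' @param reference_spectra Optional named list of cohort reference spectra
#'   (from [extract_cohort()]).
#' @param alpha,beta Positive score parameters; defaults `log(2)` and 2 give
#'   score 0.5 at one SD and 0.0625 at two SDs from the age norm.
#' @param min_children Minimum children required per gender (default 20).
#' @param std_floor_frac Fraction of the cohort feature SD used as the
#'   lower clip for `f_std`; default 0.1.
#' @return A `norm_model` object.
#' @export
fit_norms <- function(cohort, reference_spectra = NULL,
                      alpha = log(2), beta = 2,
                      min_children = 20, std_floor_frac = 0.1) {
  cohort <- validate_cohort(cohort)
  stopifnot(alpha > 0, beta > 0)
  genders <- sort(unique(cohort$gender))
  if (!all(c("F", "M") %in% genders)) {
    abort(paste0("fit_norms() needs both genders in the cohort; found only: ",
                 paste(genders, collapse = ", ")),
          class = "handscale_validation_error")
  }
  for (g in c("F", "M")) {
    sub <- cohort[cohort$gender == g, ]
    if (nrow(sub) < min_children) {
      abort(paste0("too few children for gender ", g, ": ", nrow(sub),
                   " < ", min_children), class = "handscale_validation_error")
    }
    if (length(unique(floor(sub$age))) < 3L) {
      abort(paste0("gender ", g, " spans fewer than 3 distinct ages."),
            class = "handscale_validation_error")
    }
  }
  fids <- cohort_feature_ids(cohort)
  curves <- dplyr::bind_rows(lapply(c("F", "M"), function(g) {
    sub <- cohort[cohort$gender == g, ]
    dplyr::bind_rows(lapply(fids, function(fid) {
      fit_one_curve(sub$age, sub[[paste0("f_", fid)]], fid, g,
                    std_floor_frac)
    }))
  }))
  structure(
    list(curves = curves, reference_spectra = reference_spectra,
         alpha = alpha, beta = beta,
         schema = "handscale-norms-1"),
    class = "norm_model")
}

# cubic (or lower, if rank-deficient) fits for one feature x gender cell
fit_one_curve <- function(age, value, fid, gender, std_floor_frac) {
  ok <- is.finite(age) & is.finite(value)
  age <- age[ok]; value <- value[ok]
  if (length(age) < 4L) {
    abort(paste0("too few finite values for feature ", fid, ", gender ",
                 gender), class = "handscale_validation_error")
  }
  deg_mean <- min(3L, length(unique(age)) - 1L)
  if (deg_mean < 3L) {
    warn(paste0("feature ", fid, " gender ", gender,
                ": falling back to degree ", deg_mean, " mean fit."))
  }
  mean_coeffs <- poly_fit(age, value, deg_mean)
  resid <- value - poly_eval(mean_coeffs, age)

  bin <- floor(age)
  sds <- tapply(resid, bin, sd)
  ns <- tapply(resid, bin, length)
  keep <- !is.na(sds) & ns >= 2
  ctr <- as.numeric(names(sds))[keep] + 0.5
  sds <- as.numeric(sds)[keep]; ns <- as.numeric(ns)[keep]
  if (!length(ctr)) { ctr <- mean(age); sds <- sd(resid); ns <- length(age) }
  deg_std <- min(3L, length(ctr) - 1L)
  std_coeffs <- poly_fit(ctr, sds, deg_std, w = ns)

  cohort_sd <- sd(value)
  std_floor <- max(std_floor_frac * cohort_sd, 1e-12)
  tibble::tibble(
    feature_id = as.integer(fid), gender = gender,
    b0 = mean_coeffs[1], b1 = mean_coeffs[2], b2 = mean_coeffs[3],
    b3 = mean_coeffs[4],
    s0 = std_coeffs[1], s1 = std_coeffs[2], s2 = std_coeffs[3],
    s3 = std_coeffs[4],
    age_min = min(age), age_max = max(age),
    n_fit = length(age), std_floor = std_floor)
}

# least-squares polynomial fit in raw powers, returned as 4 coefficients
# (higher-order terms zero when degree < 3)
poly_fit <- function(x, y, degree, w = NULL) {
  X <- outer(x, 0:degree, `^`)
  fit <- if (is.null(w)) stats::lm.fit(X, y) else stats::lm.wfit(X, y, w)
  co <- rep(0, 4)
  co[seq_len(degree + 1L)] <- ifelse(is.na(fit$coefficients), 0,
                                     fit$coefficients)
  co
}

poly_eval <- function(co, x) co[1] + co[2] * x + co[3] * x^2 + co[4] * x^3

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf(
    "<norm_model> %d feature x gender curves; alpha = %.4f, beta = %.4f; %s reference spectra\n",
    nrow(x$curves), x$alpha, x$beta,
    if (is.null(x$reference_spectra)) "no" else
      length(purrr::compact(x$reference_spectra))))
  invisible(x)
}

# look up one curve row; error for unknown feature/gender
norm_curve <- function(model, feature_id, gender) {
  row <- model$curves[model$curves$feature_id == feature_id &
                        model$curves$gender == gender, ]
  if (nrow(row) != 1L) {
    abort(paste0("no norm curve for feature ", feature_id, ", gender ",
                 gender), class = "handscale_validation_error")
  }
  row
}

# clamp age into the fitted support (cubic extrapolation is unsafe)
clamp_age <- function(age, lo, hi) {
  if (any(age < lo | age > hi)) {
    warn("age outside the fitted support; clamped to the boundary.")
  }
  pmin(pmax(age, lo), hi)
}

#' Evaluate norm curves
#'
#' `norm_mean()` and `norm_sd()` evaluate the fitted `f_mean` and `f_std`
#' cubics at the given ages (clamped to the fitted support, with a warning);
#' `f_std` is clipped below at the curve's positive floor.
#'
#' @param model A `norm_model`.
#' @param feature_id Catalogued feature id.
#' @param gender `"F"` or `"M"`.
#' @param age Ages in years (vectorized).
#' @return Numeric vector.
#' @export
norm_mean <- function(model, feature_id, gender, age) {
  row <- norm_curve(model, feature_id, gender)
  a <- clamp_age(age, row$age_min, row$age_max)
  poly_eval(c(row$b0, row$b1, row$b2, row$b3), a)
}

#' @rdname norm_mean
#' @export
norm_sd <- function(model, feature_id, gender, age) {
  row <- norm_curve(model, feature_id, gender)
  a <- clamp_age(age, row$age_min, row$age_max)
  pmax(poly_eval(c(row$s0, row$s1, row$s2, row$s3), a), row$std_floor)
}

#' Age- and gender-conditional Z-score of a feature value
#'
#' The one-sided (absolute) deviation from the age norm:
#' `|value - f_mean(age)| / f_std(age)`. Symmetric in the direction of the
#' deviation; 0 means exactly on the norm curve.
#'
#' @param value Feature value(s).
#' @param age Age in years.
#' @param gender `"F"` or `"M"`.
#' @param feature_id Catalogued feature id.
#' @param model A `norm_model`.
#' @return Non-negative Z-score(s).
#' @export
zscore <- function(value, age, gender, feature_id, model) {
  abs(value - norm_mean(model, feature_id, gender, age)) /
    norm_sd(model, feature_id, gender, age)
}

#' Bounded feature score from a Z-score
#'
#' `score = exp(-alpha * z^beta)`: 1 exactly on the norm, strictly
#' decreasing in the deviation, always in (0, 1]. With the defaults
#' (`alpha = log(2)`, `beta = 2`) a child one SD from the norm scores 0.5
#' and two SDs scores 0.0625.
#'
#' @param z Non-negative Z-score(s).
#' @param model Optional `norm_model` supplying `alpha`, `beta`.
#' @param alpha,beta Score parameters used when `model` is `NULL`.
#' @return Score(s) in (0, 1].
#' @export
feature_score <- function(z, model = NULL, alpha = log(2), beta = 2) {
  if (!is.null(model)) { alpha <- model$alpha; beta <- model$beta }
  if (any(z < 0, na.rm = TRUE)) {
    abort("Z-scores must be non-negative.",
          class = "handscale_validation_error")
  }
  exp(-alpha * z^beta)
}

#' Score every feature of one child
#'
#' Applies [zscore()] and [feature_score()] to each feature of a child's
#' feature tibble. Flagged (missing) features yield `NA` scores, never a
#' fabricated value.
#'
#' @param features Feature tibble from [extract_features()], or any tibble
#'   with `feature_id` and `value` columns.
#' @param age,gender Child metadata.
#' @param model A `norm_model`.
#' @return A tibble `feature_id, value, z, score`.
#' @export
score_vector <- function(features, age, gender, model) {
  suppressWarnings({   # age-clamp warning would repeat per feature
    z <- vapply(seq_len(nrow(features)), function(i) {
      v <- features$value[i]
      if (!is.finite(v)) return(NA_real_)
      zscore(v, age, gender, features$feature_id[i], model)
    }, numeric(1))
  })
  tibble::tibble(feature_id = features$feature_id, value = features$value,
                 z = z, score = ifelse(is.na(z), NA_real_,
                                       feature_score(z, model)))
}

# signed standardized deviations (value - f_mean)/f_std for a cohort table;
# rows = children, columns = f_<id>. This is the representation the severity
# scales are fitted on: age and gender effects are removed, direction kept.
standardized_deviations <- function(cohort, model, feature_ids) {
  cols <- paste0("f_", feature_ids)
  out <- matrix(NA_real_, nrow(cohort), length(cols),
                dimnames = list(cohort$child_id, cols))
  suppressWarnings(for (g in unique(cohort$gender)) {
    rows <- which(cohort$gender == g)
    for (j in seq_along(feature_ids)) {
      fid <- feature_ids[j]
      mu <- norm_mean(model, fid, g, cohort$age[rows])
      sg <- norm_sd(model, fid, g, cohort$age[rows])
      out[rows, j] <- (cohort[[cols[j]]][rows] - mu) / sg
    }
  })
  out
}

#' Persist a norm model as JSON
#'
#' @param model A `norm_model`.
#' @param path Output path.
#' @export
write_norm_model <- function(model, path) {
  doc <- list(
    schema = model$schema, alpha = model$alpha, beta = model$beta,
    curves = as.data.frame(model$curves),
    reference_spectra = lapply(purrr::compact(model$reference_spectra),
                               as.data.frame))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_model
#' @export
read_norm_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "handscale-norms-1")) {
    abort(paste0("unsupported norm model schema: ", doc$schema),
          class = "handscale_io_error")
  }
  ref <- NULL
  if (length(doc$reference_spectra)) {
    ref <- lapply(doc$reference_spectra,
                  function(df) new_spectrum(df$freq_hz, df$power))
  }
  structure(
    list(curves = tibble::as_tibble(doc$curves), reference_spectra = ref,
         alpha = doc$alpha, beta = doc$beta, schema = doc$schema),
    class = "norm_model")
}
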