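#' Fit an unsupervised handwriting severity scale
#'
#' The data-driven scale construction: per-child signed standardized
#' deviations `(value - f_mean(age)) / f_std(age)` (so age and gender
#' effects do not masquerade as handwriting variance) are restricted to the
#' requested category's features, centered and scaled by the fitting
#' cohort's per-feature mean and SD, and projected onto the three leading
#' principal axes. K-means with k = 2 (50 random restarts under a fixed
#' seed) splits the projections; the cluster holding the majority of
#' school-labeled children is the *typical* cluster, and its centroid the
#' typical-writer location. A child's score is `exp(-d / d_ref)` where `d`
#' is their Euclidean distance to that centroid and `d_ref` the mean
#' distance of the school children. Severity thresholds are set at
#' reference-cohort score quantiles via [threshold_from_quantiles()].
#'
#' @param cohort Cohort feature table with a `label` column; at least 10
#'   children labeled `"school"`, all the category's features present.
#' @param norms A fitted [fit_norms()] model.
#' @param category One of `"total"`, `"static"`, `"kinematic"`,
#'   `"pressure"`, `"tilt"`.
#' @param n_axes Principal axes retained; 3 by convention. Overriding it
#'   warns that thresholds must be refit.
#' @param restarts K-means random restarts; default 50.
#' @param seed RNG seed for the clustering.
#' @param fractions Reference-score fractions defining the four severity
#'   thresholds; default `c(vs = 0.02, s = 0.086, m = 0.15, l = 0.25)`.
#' @return A `scale_model` object. The fitting cohort's cluster assignments
#'   are kept in `$assignments` (`child_id`, `label`, `cluster`).
#' @export
fit_scale <- function(cohort, norms, category = c("total", "static",
                                                  "kinematic", "pressure",
                                                  "tilt"),
                      n_axes = 3, restarts = 50, seed = 1,
                      fractions = c(vs = 0.02, s = 0.086, m = 0.15,
                                    l = 0.25)) {
  category <- match.arg(category)
  cohort <- validate_cohort(cohort)
  if (!identical(n_axes, 3) && !identical(n_axes, 3L)) {
    warn("retaining a non-default number of axes; severity thresholds must be refit.")
  }
  fids <- scale_feature_ids(category, cohort)
  if (length(fids) < 4L) {
    abort(paste0("category ", category, " has fewer than 4 features in the cohort."),
          class = "handscale_validation_error")
  }
  school <- cohort$label == "school"
  if (sum(school) < 10L) {
    abort("fit_scale() needs at least 10 school-labeled children.",
          class = "handscale_validation_error")
  }
  dev <- standardized_deviations(cohort, norms, fids)
  if (anyNA(dev)) {
    bad <- colnames(dev)[colSums(is.na(dev)) > 0]
    abort(paste0("missing feature values in fitting cohort: ",
                 paste(bad, collapse = ", ")),
          class = "handscale_validation_error")
  }
  center <- colMeans(dev)
  spread <- apply(dev, 2, sd)
  if (all(spread < 1e-12)) {
    abort("degenerate clustering: cohort has no feature variance.",
          class = "handscale_degenerate")
  }
  spread <- pmax(spread, 1e-12)
  xs <- sweep(sweep(dev, 2, center), 2, spread, `/`)
  pca <- prcomp(xs, center = FALSE, scale. = FALSE)
  n_axes <- min(n_axes, ncol(pca$rotation))
  axes <- pca$rotation[, seq_len(n_axes), drop = FALSE]
  evf <- pca$sdev^2 / sum(pca$sdev^2)
  proj <- xs %*% axes
  if (max(stats::dist(proj)) < 1e-10) {
    abort("degenerate clustering: all children project to one point.",
          class = "handscale_degenerate")
  }
  km <- withr::with_seed(seed, kmeans(proj, centers = 2, nstart = restarts))
  if (min(km$size) == 0L || length(unique(km$cluster)) < 2L) {
    abort("degenerate clustering", class = "handscale_degenerate")
  }
  # typical cluster = the one holding the majority of school children,
  # ties broken toward the larger cluster
  school_count <- tapply(school, km$cluster, sum)
  typical_k <- as.integer(names(which.max(school_count)))
  if (school_count[[1]] == school_count[[2]]) {
    typical_k <- as.integer(names(which.max(table(km$cluster))))
  }
  centroid_typical <- km$centers[typical_k, ]
  centroid_atypical <- km$centers[setdiff(1:2, typical_k), ]
  d_school <- sqrt(rowSums(
    sweep(proj[school, , drop = FALSE], 2, centroid_typical)^2))
  d_ref <- mean(d_school)
  if (!(d_ref > 0)) {
    abort("degenerate clustering: zero reference distance.",
          class = "handscale_degenerate")
  }
  thresholds <- threshold_from_quantiles(exp(-d_school / d_ref), fractions)
  structure(
    list(category = category, feature_ids = fids,
         center = center, spread = spread,
         axes = axes, explained_variance_fractions = evf[seq_len(n_axes)],
         centroid_typical = centroid_typical,
         centroid_atypical = centroid_atypical,
         d_ref = d_ref, thresholds = thresholds, seed = seed,
         assignments = tibble::tibble(
           child_id = cohort$child_id, label = cohort$label,
           cluster = ifelse(km$cluster == typical_k, "typical", "atypical")),
         schema = "handscale-scale-1"),
    class = "scale_model")
}

scale_feature_ids <- function(category, cohort) {
  cat_tbl <- feature_catalogue()
  fids <- if (category == "total") cat_tbl$feature_id else
    cat_tbl$feature_id[cat_tbl$category == category]
  intersect(fids, cohort_feature_ids(cohort))
}

#' @export
print.scale_model <- function(x, ...) {
  cat(sprintf(
    "<scale_model> category %s: %d features -> %d axes (%.1f%%/%.1f%%/%.1f%% variance); d_ref = %.3f\n",
    x$category, length(x$feature_ids), ncol(x$axes),
    100 * x$explained_variance_fractions[1],
    100 * x$explained_variance_fractions[2],
    100 * x$explained_variance_fractions[3], x$d_ref))
  invisible(x)
}

#' Project a child onto a scale's principal axes
#'
#' Standardizes the child's feature deviations with the scale's fitted
#' center and spread, then takes dot products with the three loading
#' vectors.
#'
#' @param features Feature tibble (`feature_id`, `value`).
#' @param age,gender Child metadata.
#' @param scale A `scale_model`.
#' @param norms The `norm_model` the scale was fitted with.
#' @return Numeric vector of length `ncol(scale$axes)`.
#' @export
project <- function(features, age, gender, scale, norms) {
  v <- features$value[match(scale$feature_ids, features$feature_id)]
  missing <- scale$feature_ids[is.na(v)]
  if (length(missing)) {
    abort(paste0("missing feature values for ids: ",
                 paste(missing, collapse = ", ")),
          class = "handscale_validation_error")
  }
  suppressWarnings({
    mu <- vapply(scale$feature_ids, function(fid)
      norm_mean(norms, fid, gender, age), numeric(1))
    sg <- vapply(scale$feature_ids, function(fid)
      norm_sd(norms, fid, gender, age), numeric(1))
  })
  z <- (v - mu) / sg
  xs <- (z - scale$center) / scale$spread
  drop(xs %*% scale$axes)
}

#' Global handwriting score of a child on a fitted scale
#'
#' `exp(-d / d_ref)` where `d` is the Euclidean distance from the child's
#' projection to the typical-writer centroid: 1 exactly at the centroid,
#' `exp(-1)` at the reference distance, strictly decreasing outward and
#' always in (0, 1].
#'
#' @inheritParams project
#' @return A score in (0, 1].
#' @export
global_score <- function(features, age, gender, scale, norms) {
  p <- project(features, age, gender, scale, norms)
  d <- sqrt(sum((p - scale$centroid_typical)^2))
  exp(-d / scale$d_ref)
}

#' Score a whole cohort on a fitted scale
#'
#' @param cohort Cohort feature table.
#' @param scale A `scale_model`.
#' @param norms The matching `norm_model`.
#' @return A tibble `child_id, score, severity`.
#' @export
score_cohort <- function(cohort, scale, norms) {
  cohort <- validate_cohort(cohort)
  dev <- standardized_deviations(cohort, norms, scale$feature_ids)
  if (anyNA(dev)) {
    abort(paste0("missing feature values for: ",
                 paste(colnames(dev)[colSums(is.na(dev)) > 0], collapse = ", ")),
          class = "handscale_validation_error")
  }
  xs <- sweep(sweep(dev, 2, scale$center), 2, scale$spread, `/`)
  proj <- xs %*% scale$axes
  d <- sqrt(rowSums(sweep(proj, 2, scale$centroid_typical)^2))
  sc <- exp(-d / scale$d_ref)
  tibble::tibble(child_id = cohort$child_id, score = sc,
                 severity = categorize(sc, scale$thresholds))
}

#' Absolute feature importance of the retained axes
#'
#' Per axis, the absolute loadings of every feature, and each category's
#' share of the total absolute loading (shares sum to 1 per axis). The
#' `top_n` argument reproduces the reporting convention of keeping only the
#' most important features per category.
#'
#' @param scale A `scale_model`.
#' @param catalogue The feature catalogue (defaults to
#'   [feature_catalogue()]).
#' @param top_n Optional truncation: keep the `top_n` largest |loadings| per
#'   category and axis in the `loadings` table.
#' @return A list with `loadings` (tibble `axis, feature_id, category,
#'   loading`) and `category_shares` (tibble `axis, category, share`).
#' @export
axis_importance <- function(scale, catalogue = feature_catalogue(),
                            top_n = NULL) {
  ld <- dplyr::bind_rows(lapply(seq_len(ncol(scale$axes)), function(a) {
    tibble::tibble(axis = a, feature_id = scale$feature_ids,
                   loading = abs(scale$axes[, a]))
  }))
  ld <- dplyr::left_join(ld, catalogue[, c("feature_id", "category")],
                         by = "feature_id")
  shares <- dplyr::summarise(
    dplyr::group_by(ld, axis, category),
    share = sum(loading), .groups = "drop_last")
  shares <- dplyr::ungroup(
    dplyr::mutate(shares, share = share / sum(share)))
  if (!is.null(top_n)) {
    ld <- dplyr::ungroup(dplyr::slice_max(
      dplyr::group_by(ld, axis, category), loading, n = top_n))
  }
  list(loadings = dplyr::arrange(ld, axis, dplyr::desc(loading)),
       category_shares = shares)
}

#' Severity thresholds from reference-score quantiles
#'
#' The threshold for fraction `p` is the smallest reference score with at
#' least `ceiling(p * n)` scores at or below it, so that for distinct
#' scores exactly `ceiling(p * n) / n` of the reference cohort falls at or
#' below each threshold. With the default fractions, 2% of the reference
#' children fall below the *very severe* threshold, 8.6% below *severe*
#' (the conventional dysgraphia rate), 15% below *moderate* and 25% below
#' *light*. With heavily tied scores the realized fractions can only exceed
#' the nominal ones (documented bias direction). The fractions are
#' conventions, not clinical constants, and are freely configurable.
#'
#' @param reference_scores Numeric scores of the reference (school) cohort;
#'   at least 50 required.
#' @param fractions Strictly increasing fractions in (0, 1), named
#'   `vs, s, m, l`.
#' @return Named numeric vector `c(vs, s, m, l)`, strictly increasing.
#' @export
threshold_from_quantiles <- function(reference_scores,
                                     fractions = c(vs = 0.02, s = 0.086,
                                                   m = 0.15, l = 0.25)) {
  if (length(reference_scores) < 50L) {
    abort("threshold_from_quantiles() needs at least 50 reference scores.",
          class = "handscale_validation_error")
  }
  if (any(diff(fractions) <= 0) || any(fractions <= 0) || any(fractions >= 1)) {
    abort("threshold fractions must be strictly increasing within (0, 1).",
          class = "handscale_validation_error")
  }
  n <- length(reference_scores)
  srt <- sort(reference_scores)
  th <- srt[pmin(ceiling(fractions * n), n)]
  if (any(diff(th) <= 0)) {
    abort("tied reference scores collapse the severity thresholds.",
          class = "handscale_degenerate")
  }
  names(th) <- names(fractions) %||% c("vs", "s", "m", "l")
  th
}

#' Map scores to the five severity categories
#'
#' `very_severe` if score <= vs, `severe` if <= s, `moderate` if <= m,
#' `light` if <= l, `typical` otherwise: an exhaustive, mutually exclusive
#' partition of (0, 1].
#'
#' @param score Score(s) in (0, 1].
#' @param thresholds Named vector from [threshold_from_quantiles()].
#' @return Character vector of severity categories.
#' @export
categorize <- function(score, thresholds) {
  dplyr::case_when(
    score <= thresholds[["vs"]] ~ "very_severe",
    score <= thresholds[["s"]] ~ "severe",
    score <= thresholds[["m"]] ~ "moderate",
    score <= thresholds[["l"]] ~ "light",
    TRUE ~ "typical")
}

#' Fit the global scale and the four category sub-scales
#'
#' @inheritParams fit_scale
#' @return Named list of `scale_model`s
#'   (`total`, `static`, `kinematic`, `pressure`, `tilt`).
#' @export
fit_scales <- function(cohort, norms, n_axes = 3, restarts = 50, seed = 1,
                       fractions = c(vs = 0.02, s = 0.086, m = 0.15,
                                     l = 0.25)) {
  cats <- c("total", "static", "kinematic", "pressure", "tilt")
  setNames(lapply(cats, function(ct)
    fit_scale(cohort, norms, ct, n_axes = n_axes, restarts = restarts,
              seed = seed, fractions = fractions)), cats)
}

#' Build a child's handwriting profile
#'
#' Combines, for one child, the global score (total scale), the four
#' category scores (the same pipeline restricted to each category's
#' features), the severity category from the total scale's thresholds, and
#' the per-feature norm scores — the multi-granularity description of a
#' child's handwriting.
#'
#' @param features Feature tibble for the child.
#' @param age,gender Child metadata.
#' @param scales Named list of the five fitted scales (see [fit_scales()]).
#' @param norms The `norm_model` the scales were fitted with.
#' @param child_id Optional identifier.
#' @return A `handwriting_profile` object: list with `child_id`,
#'   `global_score`, `category_scores`, `severity`, `feature_scores`.
#' @export
profile <- function(features, age, gender, scales, norms,
                    child_id = NA_character_) {
  need <- c("total", "static", "kinematic", "pressure", "tilt")
  miss <- setdiff(need, names(scales))
  if (length(miss)) {
    abort(paste0("missing fitted scales: ", paste(miss, collapse = ", ")),
          class = "handscale_validation_error")
  }
  gs <- global_score(features, age, gender, scales$total, norms)
  cs <- vapply(c("static", "kinematic", "pressure", "tilt"), function(ct)
    global_score(features, age, gender, scales[[ct]], norms), numeric(1))
  structure(
    list(child_id = as.character(child_id), global_score = gs,
         category_scores = as.list(cs),
         severity = categorize(gs, scales$total$thresholds),
         feature_scores = score_vector(features, age, gender, norms)),
    class = "handwriting_profile")
}

#' @export
print.handwriting_profile <- function(x, ...) {
  cat(sprintf("<handwriting_profile> %s: global %.3f (%s)\n",
              x$child_id, x$global_score, x$severity))
  cat(sprintf("  categories: static %.3f | kinematic %.3f | pressure %.3f | tilt %.3f\n",
              x$category_scores$static, x$category_scores$kinematic,
              x$category_scores$pressure, x$category_scores$tilt))
  invisible(x)
}

#' Cluster-vs-label agreement of a fitted scale
#'
#' Sensitivity is the fraction of dysgraphic-labeled children assigned to
#' the atypical cluster; specificity the fraction of school-labeled
#' children assigned to the typical cluster.
#'
#' @param assignments Character vector in `{"typical", "atypical"}` (or a
#'   `scale_model`, whose fitting-cohort assignments are used).
#' @param labels Character vector in `{"school", "dysgraphic"}`; both must
#'   be present.
#' @return A list with `sensitivity` and `specificity`.
#' @export
evaluate_clustering <- function(assignments, labels = NULL) {
  if (inherits(assignments, "scale_model")) {
    labels <- assignments$assignments$label
    assignments <- assignments$assignments$cluster
  }
  keep <- labels %in% c("school", "dysgraphic")
  assignments <- assignments[keep]; labels <- labels[keep]
  if (!all(c("school", "dysgraphic") %in% labels)) {
    abort("both school and dysgraphic labels must be present.",
          class = "handscale_validation_error")
  }
  list(
    sensitivity = mean(assignments[labels == "dysgraphic"] == "atypical"),
    specificity = mean(assignments[labels == "school"] == "typical"))
}

#' Persist a scale model / profile as JSON
#'
#' @param scale A `scale_model`.
#' @param path Output path.
#' @export
write_scale_model <- function(scale, path) {
  doc <- list(
    schema = scale$schema, category = scale$category,
    feature_ids = scale$feature_ids,
    center = unname(scale$center), spread = unname(scale$spread),
    axes = unname(apply(scale$axes, 2, identity, simplify = FALSE)),
    explained_variance_fractions = scale$explained_variance_fractions,
    centroid_typical = unname(scale$centroid_typical),
    centroid_atypical = unname(scale$centroid_atypical),
    d_ref = scale$d_ref, thresholds = as.list(scale$thresholds),
    seed = scale$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale_model
#' @export
read_scale_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "handscale-scale-1")) {
    abort(paste0("unsupported scale model schema: ", doc$schema),
          class = "handscale_io_error")
  }
  fids <- as.integer(doc$feature_ids)
  # axes serialized as a list of columns; jsonlite may simplify to a
  # (n_axes x p) matrix, which must be transposed back
  axes <- if (is.list(doc$axes)) do.call(cbind, doc$axes) else t(doc$axes)
  cols <- paste0("f_", fids)
  structure(
    list(category = doc$category, feature_ids = fids,
         center = setNames(doc$center, cols),
         spread = setNames(doc$spread, cols),
         axes = axes,
         explained_variance_fractions = doc$explained_variance_fractions,
         centroid_typical = doc$centroid_typical,
         centroid_atypical = doc$centroid_atypical,
         d_ref = doc$d_ref, thresholds = unlist(doc$thresholds),
         seed = doc$seed, assignments = NULL,
         schema = doc$schema),
    class = "scale_model")
}

#' @rdname write_scale_model
#' @param prof A `handwriting_profile`.
#' @export
write_profile <- function(prof, path) {
  doc <- list(child_id = prof$child_id, global_score = prof$global_score,
              category_scores = prof$category_scores,
              severity = prof$severity,
              feature_scores = as.data.frame(prof$feature_scores))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_scale_model
#' @export
read_profile <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(
    list(child_id = doc$child_id, global_score = doc$global_score,
         category_scores = as.list(doc$category_scores),
         severity = doc$severity,
         feature_scores = tibble::as_tibble(doc$feature_scores)),
    class = "handwriting_profile")
}
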