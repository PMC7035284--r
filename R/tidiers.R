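#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted norm model
#'
#' One row per feature x gender curve with the cubic coefficients of the
#' mean and SD curves, the fitted age support and the sample size.
#'
#' @param x A `norm_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy norm_model
#' @export
tidy.norm_model <- function(x, ...) {
  x$curves
}

#' @rdname tidy.norm_model
#' @method glance norm_model
#' @export
glance.norm_model <- function(x, ...) {
  tibble::tibble(
    n_curves = nrow(x$curves),
    n_features = length(unique(x$curves$feature_id)),
    alpha = x$alpha, beta = x$beta,
    age_min = min(x$curves$age_min), age_max = max(x$curves$age_max),
    n_reference_spectra = length(purrr::compact(x$reference_spectra)))
}

#' Tidy a fitted scale model
#'
#' One row per feature x axis with the signed loading; `glance()` gives the
#' one-row model summary (explained variance, reference distance,
#' thresholds).
#'
#' @param x A `scale_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy scale_model
#' @export
tidy.scale_model <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(ncol(x$axes)), function(a) {
    tibble::tibble(axis = a, feature_id = x$feature_ids,
                   loading = x$axes[, a])
  }))
}

#' @rdname tidy.scale_model
#' @method glance scale_model
#' @export
glance.scale_model <- function(x, ...) {
  tibble::tibble(
    category = x$category, n_features = length(x$feature_ids),
    n_axes = ncol(x$axes),
    var_axis1 = x$explained_variance_fractions[1],
    var_axis2 = x$explained_variance_fractions[2],
    var_axis3 = x$explained_variance_fractions[3],
    d_ref = x$d_ref,
    vs = x$thresholds[["vs"]], s = x$thresholds[["s"]],
    m = x$thresholds[["m"]], l = x$thresholds[["l"]])
}

#' Tidy a handwriting profile
#'
#' Long tibble of the profile's scores: the global score, the four category
#' scores and the per-feature scores.
#'
#' @param x A `handwriting_profile`.
#' @param ... Unused.
#' @return A tibble `level, name, score`.
#' @method tidy handwriting_profile
#' @export
tidy.handwriting_profile <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(level = "global", name = "global", score = x$global_score),
    tibble::tibble(level = "category",
                   name = names(x$category_scores),
                   score = unlist(x$category_scores)),
    tibble::tibble(level = "feature",
                   name = paste0("f_", x$feature_scores$feature_id),
                   score = x$feature_scores$score))
}
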