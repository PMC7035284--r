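#' The handwriting feature catalogue
#'
#' The 62 catalogued features, keyed by their conventional identifiers
#' (1-36 and 38-63; id 37 is intentionally absent from the numbering) and
#' partitioned into four categories: static (12), kinematic (11),
#' pressure (13) and tilt (26).
#'
#' @param categories Optional subset of
#'   `c("static", "kinematic", "pressure", "tilt")` to filter on.
#' @return A tibble with columns `feature_id`, `name`, `category`,
#'   `description`.
#' @examples
#' dplyr::count(feature_catalogue(), category)
#' @export
feature_catalogue <- function(categories = NULL) {
  cat_tbl <- catalogue_table()
  if (!is.null(categories)) {
    categories <- match.arg(categories,
                            c("static", "kinematic", "pressure", "tilt"),
                            several.ok = TRUE)
    cat_tbl <- dplyr::filter(cat_tbl, category %in% categories)
  }
  cat_tbl
}

# The five spectral-summary blocks share naming; build them programmatically.
spectral_block <- function(ids, signal_label) {
  tibble::tibble(
    feature_id = ids,
    name = c(
      paste0("Bandwidth of the Power Spectral of ", signal_label, " Frequencies"),
      paste0("Median of the Power Spectral of ", signal_label, " Frequencies"),
      paste0("Entropy of Mean of ", signal_label, " Frequencies"),
      paste0("Correlation of Mean of ", signal_label, " Frequencies"),
      paste0("Distance of Mean of ", signal_label, " Frequencies")),
    description = c(
      paste0("Width of the frequency interval covering 90% of the ",
             signal_label, " spectral density"),
      paste0("Median frequency of the ", signal_label, " spectral density"),
      paste0("KL divergence of the writer's ", signal_label,
             " spectrum from the cohort-average spectrum"),
      paste0("Pearson correlation of the writer's ", signal_label,
             " spectrum with the cohort-average spectrum"),
      paste0("Euclidean distance of the writer's ", signal_label,
             " spectrum from the cohort-average spectrum"))
  )
}

catalogue_table <- function() {
  static <- dplyr::bind_rows(
    tibble::tribble(
      ~feature_id, ~name, ~description,
      1L, "Handwriting Moment",
      "Mean |dy| between consecutive barycenters of 300-point bins within a line of text (line straightness)",
      2L, "Handwriting Size",
      "Mean bounding-box area of 300-point bins within a line of text",
      3L, "Space Between Strokes",
      "Mean Euclidean distance from each stroke's last sample to the next stroke's first sample",
      4L, "Handwriting Density",
      "Mean number of samples per occupied 20-pixel grid cell",
      5L, "Average Stroke Direction",
      "Circular mean of per-step movement directions atan2(dy, dx), radians",
      6L, "Angle Smoothness",
      "Mean absolute turning angle over consecutive point triples, radians",
      7L, "Area of the Text's Convex Hull",
      "Area of the convex hull of all on-surface points"),
    spectral_block(8:12, "Tremor")
  )
  kinematic <- dplyr::bind_rows(
    tibble::tribble(
      ~feature_id, ~name, ~description,
      13L, "Mean Velocity", "Mean of the within-stroke pen speed",
      14L, "Maximum Velocity", "Maximum of the within-stroke pen speed",
      15L, "Standard Deviation of Velocity", "SD of the within-stroke pen speed",
      16L, "Increase in Velocity",
      "Least-squares slope of pen speed versus time",
      17L, "Nb of Peaks of Velocity Change Per Second",
      "Local extrema per second of the smoothed speed series (generalized-Gaussian window M=3, p=0.5, sigma=2)"),
    spectral_block(18:22, "Speed"),
    tibble::tibble(feature_id = 23L, name = "In-Air-Time Ratio",
                   description = "Fraction of total writing time the pen spends off the surface")
  )
  pressure <- dplyr::bind_rows(
    tibble::tribble(
      ~feature_id, ~name, ~description,
      24L, "Mean Pressure", "Mean pen pressure",
      25L, "Maximum Pressure", "Maximum pen pressure",
      26L, "Standard Deviation of Pressure", "SD of pen pressure",
      27L, "Mean Speed of Pressure Change",
      "Mean rate of change between consecutive 10-sample pressure bin means",
      28L, "Max Speed of Pressure Change",
      "Maximum rate of change between consecutive 10-sample pressure bin means",
      29L, "Standard Deviation of Speed of Pressure Change",
      "SD of the rate of change between consecutive 10-sample pressure bin means",
      30L, "Increase of Speed of Pressure Change",
      "Least-squares slope of the pressure rate-of-change series versus time",
      31L, "Nb of Peaks of Pressure Change Per Second",
      "Sign inversions per second of consecutive pressure differences"),
    spectral_block(32:36, "Speed of Pressure Change")
  )
  tilt <- dplyr::bind_rows(
    tibble::tribble(
      ~feature_id, ~name, ~description,
      38L, "Mean Tilt-Azimuth", "Mean tilt-azimuth angle",
      39L, "Maximum Tilt-Azimuth", "Maximum tilt-azimuth angle",
      40L, "Standard Deviation of Tilt-Azimuth", "SD of the tilt-azimuth angle",
      41L, "Mean Tilt-Altitude", "Mean tilt-altitude angle",
      42L, "Maximum Tilt-Altitude", "Maximum tilt-altitude angle",
      43L, "Standard Deviation of Tilt-Altitude", "SD of the tilt-altitude angle",
      44L, "Mean Speed of Tilt-Azimuth Change",
      "Mean rate of change between consecutive 10-sample tilt-azimuth bin means",
      45L, "Max Speed of Tilt-Azimuth Change",
      "Maximum rate of change between consecutive 10-sample tilt-azimuth bin means",
      46L, "Standard Deviation of Speed of Tilt-Azimuth Change",
      "SD of the rate of change between consecutive 10-sample tilt-azimuth bin means",
      47L, "Mean Speed of Tilt-Altitude Change",
      "Mean rate of change between consecutive 10-sample tilt-altitude bin means",
      48L, "Max Speed of Tilt-Altitude Change",
      "Maximum rate of change between consecutive 10-sample tilt-altitude bin means",
      49L, "Standard Deviation of Speed of Tilt-Altitude Change",
      "SD of the rate of change between consecutive 10-sample tilt-altitude bin means",
      50L, "Increase of Speed of Tilt-Azimuth Change",
      "Least-squares slope of the tilt-azimuth rate-of-change series versus time",
      51L, "Increase of Speed of Tilt-Altitude Change",
      "Least-squares slope of the tilt-altitude rate-of-change series versus time",
      52L, "Nb of Peaks of Tilt-Azimuth Change Per Second",
      "Sign inversions per second of consecutive tilt-azimuth differences",
      53L, "Nb of Peaks of Tilt-Altitude Change Per Second",
      "Sign inversions per second of consecutive tilt-altitude differences"),
    spectral_block(54:58, "Speed of Tilt-Azimuth Change"),
    spectral_block(59:63, "Speed of Tilt-Altitude Change")
  )
  dplyr::bind_rows(
    dplyr::mutate(static, category = "static"),
    dplyr::mutate(kinematic, category = "kinematic"),
    dplyr::mutate(pressure, category = "pressure"),
    dplyr::mutate(tilt, category = "tilt")
  )[, c("feature_id", "name", "category", "description")]
}

#' Export the feature catalogue as CSV
#'
#' @param path Output path.
#' @export
write_catalogue <- function(path) {
  utils::write.csv(feature_catalogue(), path, row.names = FALSE)
  invisible(path)
}
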