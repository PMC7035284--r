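#' Normalized magnitude spectrum
#'
#' A spectrum is a tibble with columns `freq_hz` (strictly increasing,
#' non-negative) and `power` (non-negative, summing to 1): a probability
#' vector over frequency lines. All frequency-domain features are summaries
#' of such spectra.
#'
#' @param freq_hz Strictly increasing non-negative frequencies, Hz.
#' @param power Non-negative magnitudes; normalized to sum 1 unless already.
#' @return A `spectrum` tibble.
#' @export
new_spectrum <- function(freq_hz, power) {
  stopifnot(length(freq_hz) == length(power), length(power) > 0)
  if (any(diff(freq_hz) <= 0) || any(freq_hz < 0)) {
    abort("freq_hz must be strictly increasing and non-negative.",
          class = "handscale_validation_error")
  }
  if (any(power < 0)) {
    abort("spectral power must be non-negative.",
          class = "handscale_validation_error")
  }
  s <- sum(power)
  if (s <= 0) {
    warn("all-zero spectrum; falling back to the uniform spectrum.")
    power <- rep(1 / length(power), length(power))
  } else if (abs(s - 1) > 1e-9) {
    power <- power / s
  }
  tibble::new_tibble(
    tibble::tibble(freq_hz = as.numeric(freq_hz), power = as.numeric(power)),
    class = "spectrum")
}

#' Tremor residual signal of a pen trace
#'
#' For each local displacement vector (between two consecutive points), the
#' residual is the magnitude of the 2-D cross product between that local
#' vector and the "global" direction vector, defined as the average of the
#' local vectors in a forward window of `window` points (i.e. `window - 1`
#' local vectors). Straight handwriting gives residuals near zero; shaky
#' handwriting gives local vectors poorly aligned with the global direction
#' and hence large residuals. The result depends only on the geometry of the
#' polyline, not on timing.
#'
#' @param samples Data frame of ordered on-surface samples with columns
#'   `x`, `y`.
#' @param window Points per direction window; default 10 (9 local vectors).
#' @return Numeric vector of non-negative residual magnitudes, one per local
#'   vector evaluated (`n - window + 1` for `n` input points); empty with a
#'   warning when fewer than `window + 1` samples are supplied.
#' @export
tremor_signal <- function(samples, window = 10) {
  n <- nrow(samples)
  if (n < window + 1L) {
    warn("too few samples for the tremor signal; returning empty result.")
    return(numeric(0))
  }
  dx <- diff(samples$x)
  dy <- diff(samples$y)
  k <- window - 1L                         # local vectors per window
  # forward rolling mean over k local vectors, aligned with the first
  gx <- rolling_mean(dx, k)
  gy <- rolling_mean(dy, k)
  m <- length(gx)                          # = n - window + 1
  abs(dx[seq_len(m)] * gy - dy[seq_len(m)] * gx)
}

rolling_mean <- function(v, k) {
  cs <- cumsum(c(0, v))
  (cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]) / k
}

#' Binned averaged Fourier spectrum of a time series
#'
#' The signal is split into consecutive non-overlapping bins of `bin_size`
#' points (the trailing partial bin is dropped). Each bin is mean-removed
#' and its discrete Fourier transform taken at the recording's nominal
#' sampling rate; magnitude spectra over the positive frequency lines
#' `k * rate / bin_size`, `k = 1 .. bin_size/2` (the 0 Hz line is excluded)
#' are averaged point-wise and normalized to sum 1. When sample times are
#' supplied, bins never span a gap longer than `max_gap_s` seconds (such a
#' gap restarts binning). An all-zero average (e.g. a constant signal) falls
#' back to the uniform spectrum with a warning.
#'
#' @param signal Real-valued time series.
#' @param times Optional sample times (seconds) used only to avoid binning
#'   across long gaps.
#' @param bin_size Points per bin; default 600.
#' @param sampling_rate_hz Nominal sampling rate; default 60.
#' @param max_gap_s Longest gap a bin may span; default 1 s.
#' @return A [new_spectrum()] on the grid `k * rate / bin_size`.
#' @export
mean_spectrum <- function(signal, times = NULL, bin_size = 600,
                          sampling_rate_hz = 60, max_gap_s = 1) {
  n <- length(signal)
  if (n < bin_size) {
    abort("insufficient samples for spectral features",
          class = "handscale_insufficient_data")
  }
  if (!is.null(times) && length(times) == n) {
    seg_id <- cumsum(c(0, diff(times) > max_gap_s))
    segments <- split(signal, seg_id)
  } else {
    segments <- list(signal)
  }
  nk <- floor(bin_size / 2)
  acc <- numeric(nk)
  nbins <- 0L
  for (seg in segments) {
    nb <- floor(length(seg) / bin_size)
    if (nb < 1L) next
    for (b in seq_len(nb)) {
      chunk <- seg[((b - 1L) * bin_size + 1L):(b * bin_size)]
      chunk <- chunk - mean(chunk)
      mag <- Mod(fft(chunk))[2:(nk + 1L)]
      acc <- acc + mag
      nbins <- nbins + 1L
    }
  }
  if (nbins == 0L) {
    abort("insufficient samples for spectral features",
          class = "handscale_insufficient_data")
  }
  freqs <- (1:nk) * sampling_rate_hz / bin_size
  new_spectrum(freqs, acc / nbins)
}

#' Spectral summaries
#'
#' `bandwidth90()` is the width of the smallest low-frequency interval
#' holding 90\% of the normalized power: the distance from the lowest
#' frequency line carrying positive power to the smallest frequency at which
#' the cumulative power reaches 0.9. A narrow bandwidth indicates clustered,
#' fluent spectral content; a one-line spectrum has bandwidth 0.
#' `spectral_median()` is the smallest frequency at which the cumulative
#' power reaches 0.5; large values indicate high-frequency content.
#'
#' @param spec A [new_spectrum()].
#' @return Frequency in Hz.
#' @export
bandwidth90 <- function(spec) {
  cum <- cumsum(spec$power)
  f90 <- spec$freq_hz[which(cum >= 0.9 - 1e-12)[1]]
  f_first <- spec$freq_hz[which(spec$power > 0)[1]]
  f90 - f_first
}

#' @rdname bandwidth90
#' @export
spectral_median <- function(spec) {
  cum <- cumsum(spec$power)
  spec$freq_hz[which(cum >= 0.5 - 1e-12)[1]]
}

#' Compare a spectrum against a reference spectrum
#'
#' Returns the three divergence summaries used by the feature catalogue:
#' `entropy`, the Kullback-Leibler divergence KL(spec || ref) with
#' epsilon-smoothing (both vectors get `eps` added and are renormalized, so
#' the divergence is finite even for disjoint supports); `correlation`, the
#' Pearson correlation of the two power vectors (1 when either vector has
#' zero variance and the vectors are identical, 0 when undefined otherwise);
#' and `distance`, the Euclidean norm of their difference. Both spectra must
#' share the same frequency grid.
#'
#' @param spec,ref Spectra on identical frequency grids.
#' @param eps Smoothing constant, default 1e-12.
#' @return A list with `entropy`, `correlation`, `distance`.
#' @export
spectrum_compare <- function(spec, ref, eps = 1e-12) {
  if (nrow(spec) != nrow(ref) ||
      any(abs(spec$freq_hz - ref$freq_hz) > 1e-9)) {
    abort("spectra must share the same frequency grid.",
          class = "handscale_validation_error")
  }
  p <- spec$power + eps; p <- p / sum(p)
  q <- ref$power + eps;  q <- q / sum(q)
  entropy <- sum(p * (log(p) - log(q)))
  if (sd(spec$power) == 0 || sd(ref$power) == 0) {
    correlation <- if (max(abs(spec$power - ref$power)) == 0) 1 else 0
  } else {
    correlation <- cor(spec$power, ref$power)
  }
  distance <- sqrt(sum((spec$power - ref$power)^2))
  list(entropy = max(entropy, 0), correlation = correlation, distance = distance)
}

#' Cohort-average reference spectrum
#'
#' Point-wise mean of the given spectra (all on a common grid),
#' renormalized to sum 1. This is the "average writer" spectrum against
#' which individual writers are compared.
#'
#' @param spectra Non-empty list of spectra on a common frequency grid.
#' @return A [new_spectrum()].
#' @export
reference_spectrum <- function(spectra) {
  spectra <- purrr::compact(spectra)
  if (!length(spectra)) {
    abort("reference_spectrum() needs at least one spectrum.",
          class = "handscale_validation_error")
  }
  f0 <- spectra[[1]]$freq_hz
  for (s in spectra) {
    if (nrow(s) != length(f0) || any(abs(s$freq_hz - f0) > 1e-9)) {
      abort("all spectra must share the same frequency grid.",
            class = "handscale_validation_error")
    }
  }
  avg <- Reduce(`+`, lapply(spectra, function(s) s$power)) / length(spectra)
  new_spectrum(f0, avg)
}

#' Five-number spectral summary against a reference
#'
#' Convenience wrapper returning, in catalogue order: 90\% bandwidth,
#' spectral median, and the entropy / correlation / distance against the
#' reference. When `ref` is `NULL` the three comparison values are `NA`.
#'
#' @param spec A spectrum.
#' @param ref Reference spectrum or `NULL`.
#' @return Named numeric vector
#'   `c(bandwidth, median, entropy, correlation, distance)`.
#' @export
spectral_summary <- function(spec, ref = NULL) {
  out <- c(bandwidth = bandwidth90(spec), median = spectral_median(spec),
           entropy = NA_real_, correlation = NA_real_, distance = NA_real_)
  if (!is.null(ref)) {
    cmp <- spectrum_compare(spec, ref)
    out["entropy"] <- cmp$entropy
    out["correlation"] <- cmp$correlation
    out["distance"] <- cmp$distance
  }
  out
}

#' Serialize a spectrum to two-column CSV
#'
#' @param spec A spectrum.
#' @param path Output path.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  new_spectrum(df$freq_hz, df$power)
}
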