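#' Time-domain features of one window
#'
#' The standard statistical feature list used by shallow HAR baselines. Each
#' name maps to one fixed definition (documented here rather than left to
#' interpretation): `amplitude = max - min`, `amplitude_peak = max(|x|)`,
#' `euclidean_norm = sqrt(sum(x^2))`, `mean_square = mean(x^2)`,
#' `mad = mean(|x - mean|)`, `sse = sum((x - mean)^2)`, population variance
#' and sd, `zero_crossing_rate` = sign changes / (w - 1), moment skewness
#' and excess kurtosis (0 for constant windows), lag-1 autocorrelation (0 for
#' constant windows), `area`/`abs_area` = trapezoidal sums of the values /
#' absolute values, `magnitude_difference` = mean absolute first difference.
#'
#' @param x Numeric window (length >= 2).
#' @return One-row tibble of named features.
#' @export
time_features <- function(x) {
  n <- length(x)
  if (n < 2) stop_parameter("window too short for time features")
  m <- mean(x)
  dev <- x - m
  v <- mean(dev^2)
  s <- sqrt(v)
  sgn <- sign(x[x != 0])
  zc <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0
  skew <- if (s > 0) mean(dev^3) / s^3 else 0
  kurt <- if (s > 0) mean(dev^4) / s^4 - 3 else 0
  ac1 <- if (v > 0) sum(dev[-n] * dev[-1]) / sum(dev^2) else 0
  trapz <- function(y) sum((y[-n] + y[-1]) / 2)
  tibble::tibble(
    min = min(x), max = max(x), amplitude = max(x) - min(x),
    amplitude_peak = max(abs(x)),
    sum = sum(x), abs_sum = sum(abs(x)),
    euclidean_norm = sqrt(sum(x^2)),
    mean = m, abs_mean = mean(abs(x)), mean_square = mean(x^2),
    mad = mean(abs(dev)), sse = sum(dev^2),
    variance = v, sd = s,
    zero_crossing_rate = zc / (n - 1),
    skewness = skew, kurtosis = kurt, autocorr_lag1 = ac1,
    area = trapz(x), abs_area = trapz(abs(x)),
    signal_magnitude_mean = mean(x), abs_signal_magnitude_mean = mean(abs(x)),
    magnitude_difference = mean(abs(diff(x))))
}

#' Frequency-domain features of one window
#'
#' Derived from the magnitude spectrum of the fast Fourier transform with
#' Parseval-consistent scaling: `energy = sum(|c_k|^2) / n` (equal to the
#' time-domain energy `sum(x^2)`), `energy_normalized = energy /
#' half-spectrum length`, `power = energy / n`, spectral centroid (magnitude-
#' weighted mean bin over the non-DC half spectrum), normalized spectral
#' entropy (`0 log 0 := 0`, divided by `log` of the bin count), `dc =
#' mean(x)`, `peak` = bin index of the largest non-DC magnitude, and the sum
#' of the half-spectrum magnitudes.
#'
#' @param x Numeric window (length >= 4).
#' @return One-row tibble of named features.
#' @export
freq_features <- function(x) {
  n <- length(x)
  if (n < 4) stop_parameter("window too short for frequency features")
  mag <- Mod(fft(x))
  nh <- n %/% 2 + 1          # DC .. Nyquist
  half <- mag[2:nh]          # non-DC half spectrum, bins 1 .. nh-1
  energy <- sum(mag^2) / n
  p <- half^2
  tot <- sum(p)
  ent <- if (tot > 0) {
    pr <- p[p > 0] / tot
    -sum(pr * log(pr)) / log(length(half))
  } else 0
  centroid <- if (sum(half) > 0) sum(seq_along(half) * half) / sum(half) else 0
  peak <- if (tot > 0) which.max(half) else 0L
  tibble::tibble(
    energy = energy,
    energy_normalized = energy / length(half),
    power = energy / n,
    centroid = centroid,
    entropy = ent,
    dc = mean(x),
    peak = as.integer(peak),
    coefficient_sum = sum(half))
}

#' Single-level Haar features
#'
#' A wavelet-flavoured alternative to [freq_features()]: one level of the
#' orthonormal Haar decomposition (pairwise sums and differences over
#' `sqrt(2)`) feeds the same feature list, with the detail coefficients
#' playing the role of the non-DC spectrum. Windows of odd length drop the
#' last sample.
#'
#' @param x Numeric window (length >= 4).
#' @return One-row tibble with the same columns as [freq_features()].
#' @export
wavelet_features <- function(x) {
  n <- length(x)
  if (n < 4) stop_parameter("window too short for wavelet features")
  if (n %% 2 == 1) x <- x[-n]
  odd <- x[seq(1, length(x), by = 2)]
  even <- x[seq(2, length(x), by = 2)]
  approx <- (odd + even) / sqrt(2)
  detail <- (odd - even) / sqrt(2)
  mag <- abs(detail)
  energy <- sum(approx^2) + sum(detail^2)   # orthonormal: equals sum(x^2)
  p <- detail^2
  tot <- sum(p)
  ent <- if (tot > 0) {
    pr <- p[p > 0] / tot
    -sum(pr * log(pr)) / log(length(detail))
  } else 0
  centroid <- if (sum(mag) > 0) sum(seq_along(mag) * mag) / sum(mag) else 0
  tibble::tibble(
    energy = energy,
    energy_normalized = energy / length(detail),
    power = energy / length(x),
    centroid = centroid,
    entropy = ent,
    dc = mean(x),
    peak = as.integer(if (tot > 0) which.max(mag) else 0L),
    coefficient_sum = sum(mag))
}

#' Baseline feature table for a set of instances
#'
#' Windows each axis of every instance, extracts per-axis time (and
#' optionally frequency or Haar) features, concatenates the three axis
#' vectors, and appends the cross-axis terms (pairwise Pearson correlations
#' and lag-0 normalized cross-correlations) computed at the instance level.
#' Feature order is fixed across runs.
#'
#' @param instances Instance tibble from [collect_instances()].
#' @param window_samples,overlap Windowing configuration (the baseline
#'   convention is longer windows than the symbolic pipelines).
#' @param domain `"time"`, `"fft"` or `"wavelet"`.
#' @return Tibble: one row per window per instance, columns `instance`,
#'   `label` then the named features.
#' @export
featurize_instances <- function(instances, window_samples, overlap = 0.5,
                                domain = c("time", "fft", "wavelet")) {
  domain <- match.arg(domain)
  extractor <- switch(domain, time = time_features, fft = freq_features,
                      wavelet = wavelet_features)
  purrr::pmap_dfr(instances, function(instance, label, x, y, z, ...) {
    axes <- list(x = x, y = y, z = z)
    wins <- lapply(axes, sliding_windows, window_samples = window_samples,
                   overlap = overlap)
    n_win <- nrow(wins$x)
    rows <- purrr::map_dfr(seq_len(n_win), function(i) {
      per_axis <- purrr::imap(wins, function(wtbl, ax) {
        f <- extractor(wtbl$values[[i]])
        names(f) <- paste0(ax, "_", names(f))
        f
      })
      xs <- wins$x$values[[i]]; ys <- wins$y$values[[i]]; zs <- wins$z$values[[i]]
      cross <- tibble::tibble(
        cor_xy = safe_cor(xs, ys), cor_xz = safe_cor(xs, zs),
        cor_yz = safe_cor(ys, zs),
        xcorr_xy = norm_xcorr(xs, ys), xcorr_xz = norm_xcorr(xs, zs),
        xcorr_yz = norm_xcorr(ys, zs))
      dplyr::bind_cols(per_axis$x, per_axis$y, per_axis$z, cross)
    })
    dplyr::bind_cols(tibble::tibble(instance = instance, label = label,
                                    window = seq_len(n_win)), rows)
  })
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

norm_xcorr <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
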