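#' Sliding-window segmentation
#'
#' Cuts one axis of a signal into fixed-length windows with fractional
#' overlap. Windows are half-open `[start, start + w)` with 0-based starts at
#' `0, stride, 2 stride, ...`, where `stride = round(w * (1 - overlap))`.
#'
#' @param values Numeric vector, one axis of a signal.
#' @param window_samples Window length `w` in samples (>= 2).
#' @param overlap Overlap fraction in `[0, 1)`; the default 0.5 halves the
#'   stride.
#' @param labels Optional per-sample labels used to label each window.
#' @param label_policy `"majority"` labels a window by its most frequent
#'   sample label (ties broken by the earliest sample in the window);
#'   `"strict"` discards windows containing more than one label.
#' @param stride Explicit stride in samples, overriding `overlap` (stride 1
#'   gives the dense extraction used by bag-of-patterns pipelines).
#' @return A tibble with columns `start_index` (0-based), `label` (`NA` when
#'   no labels are given) and the list-column `values`.
#' @export
sliding_windows <- function(values, window_samples, overlap = 0.5,
                            labels = NULL, label_policy = c("majority", "strict"),
                            stride = NULL) {
  label_policy <- match.arg(label_policy)
  w <- as.integer(window_samples)
  n <- length(values)
  if (w < 2) stop_parameter("`window_samples` must be >= 2")
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    stop_parameter("`overlap` must lie in [0, 1)")
  }
  if (n < w) stop_insufficient("series shorter than one window")
  stride <- if (is.null(stride)) {
    max(1L, as.integer(round(w * (1 - overlap))))
  } else {
    as.integer(stride)
  }
  if (stride < 1) stop_parameter("`stride` must be >= 1")
  starts <- seq.int(0L, n - w, by = stride)

  win_label <- rep(NA_character_, length(starts))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop_parameter("`labels` must match `values` in length")
    win_label <- vapply(starts, function(s) {
      lab <- labels[(s + 1):(s + w)]
      if (label_policy == "strict" && length(unique(lab)) > 1) return(NA_character_)
      counts <- table(lab)
      top <- names(counts)[counts == max(counts)]
      if (length(top) == 1) return(top)
      # tie: earliest sample among tied labels wins
      lab[match(TRUE, lab %in% top)]
    }, character(1))
  }
  out <- tibble::tibble(
    start_index = starts,
    label = win_label,
    values = lapply(starts, function(s) values[(s + 1):(s + w)])
  )
  if (!is.null(labels) && label_policy == "strict") {
    out <- out[!is.na(out$label), ]
  }
  out
}

#' Z-normalize a window
#'
#' Centers and scales to zero mean and unit *population* standard deviation.
#' Windows whose spread falls below `sd_floor` (near-constant signals, e.g.
#' rest postures) map to the all-zero vector instead of amplifying noise.
#'
#' @param x Numeric vector.
#' @param sd_floor Spread threshold below which the window is treated as
#'   constant.
#' @return Numeric vector of the same length.
#' @export
znormalize <- function(x, sd_floor = 1e-8) {
  if (length(x) == 0) stop_parameter("empty window")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s < sd_floor) return(numeric(length(x)) * 0)
  (x - m) / s
}

# Row-wise z-normalization of a windows-by-samples matrix; returns the matrix
# together with the per-row population sd (needed by the Fourier path).
znormalize_rows <- function(W, sd_floor = 1e-8) {
  m <- rowMeans(W)
  s <- sqrt(rowMeans(W^2) - m^2)
  s[!is.finite(s)] <- 0
  flat <- s < sd_floor
  Z <- (W - m) / ifelse(flat, 1, s)
  Z[flat, ] <- 0
  list(values = Z, sd = s, flat = flat)
}

# Stack the list-column of a sliding_windows() result into a matrix.
windows_matrix <- function(windows) {
  do.call(rbind, windows$values)
}
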