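#' Leading Fourier coefficients of one window
#'
#' Returns the interleaved real and imaginary parts of the first `l / 2`
#' Fourier coefficients of the window under the unnormalized forward
#' transform (`X_k = sum_t x_t exp(-2 pi i k t / w)`, so the DC term equals
#' the window sum). With `drop_dc` the DC term is skipped and coefficients
#' start at `k = 1`; with `normalize` the window is z-normalized first (which
#' forces the DC term to 0 and makes the words scale-invariant).
#'
#' @param x Numeric window.
#' @param l Even number of output values (`l / 2` complex coefficients).
#' @param drop_dc Skip the DC coefficient.
#' @param normalize Z-normalize the window before the transform (implies that
#'   the DC term carries no information).
#' @param sd_floor Passed to [znormalize()].
#' @return Numeric vector `c(Re(c1), Im(c1), Re(c2), Im(c2), ...)` of length `l`.
#' @export
fourier_approximate <- function(x, l, drop_dc = FALSE, normalize = FALSE,
                                sd_floor = 1e-8) {
  l <- as.integer(l)
  if (l %% 2 != 0 || l < 2) stop_parameter("`l` must be a positive even number")
  if (l > length(x)) stop_parameter("`l` exceeds the window length")
  if (normalize) x <- znormalize(x, sd_floor)
  X <- fft(x)
  start <- if (drop_dc) 2L else 1L
  k <- seq.int(start, start + l %/% 2 - 1)
  if (max(k) > length(x)) stop_parameter("too many coefficients for this window")
  cc <- X[k]
  as.numeric(rbind(Re(cc), Im(cc)))
}

# Full interleaved coefficient matrix for a windows-by-samples matrix.
# Returns n_windows x l numeric matrix; columns are (Re, Im) pairs starting
# at DC (drop_dc = FALSE) or at k = 1 (drop_dc = TRUE).
fourier_matrix <- function(W, l, drop_dc = FALSE, normalize = FALSE,
                           sd_floor = 1e-8) {
  if (normalize) W <- znormalize_rows(W, sd_floor)$values
  X <- t(stats::mvfft(t(W)))  # n_windows x w complex
  start <- if (drop_dc) 2L else 1L
  k <- seq.int(start, start + l %/% 2 - 1)
  out <- matrix(0, nrow(W), l)
  out[, seq(1, l, by = 2)] <- Re(X[, k, drop = FALSE])
  out[, seq(2, l, by = 2)] <- Im(X[, k, drop = FALSE])
  out
}

#' Sliding-window Fourier coefficients by incremental update (MFT)
#'
#' Computes the leading Fourier coefficients of every length-`w` window of
#' `series` at stride 1 with the momentary (incremental) update
#' `X_k(p + 1) = (X_k(p) - x_p + x_{p + w}) exp(2 pi i k / w)`, which agrees
#' with a direct transform of each window to floating-point precision while
#' costing O(l) per step instead of O(w log w).
#'
#' @param series Numeric vector (length >= `w`).
#' @param w Window length.
#' @param l Even number of interleaved coefficient values per window.
#' @param drop_dc,normalize,sd_floor As in [fourier_approximate()].
#' @return Matrix with one row per window start (0-based starts `0 .. n - w`).
#' @export
mft_coefficients <- function(series, w, l, drop_dc = FALSE, normalize = FALSE,
                             sd_floor = 1e-8) {
  n <- length(series)
  w <- as.integer(w)
  l <- as.integer(l)
  if (l %% 2 != 0 || l < 2) stop_parameter("`l` must be a positive even number")
  if (n < w) stop_insufficient("series shorter than one window")
  start <- if (drop_dc) 1L else 0L
  ks <- seq.int(start, start + l %/% 2 - 1)
  rot <- exp(2i * pi * ks / w)
  n_win <- n - w + 1L
  out <- matrix(0, n_win, l)

  window <- series[1:w]
  X <- vapply(ks, function(k) {
    sum(window * exp(-2i * pi * k * (0:(w - 1)) / w))
  }, complex(1))
  run_sum <- sum(window)
  run_sq <- sum(window^2)

  fill <- function(row, X, s, sq) {
    cc <- X
    if (normalize) {
      m <- s / w
      sd_w <- sqrt(max(sq / w - m^2, 0))
      if (sd_w < sd_floor) {
        cc[] <- 0
      } else {
        # z-normalization scales every coefficient by 1/sd and zeroes the DC
        cc <- cc / sd_w
        if (!drop_dc) cc[1] <- 0
      }
    }
    out[row, seq(1, l, by = 2)] <<- Re(cc)
    out[row, seq(2, l, by = 2)] <<- Im(cc)
  }
  fill(1L, X, run_sum, run_sq)
  if (n_win > 1) {
    for (p in seq_len(n_win - 1L)) {
      old <- series[p]
      new <- series[p + w]
      X <- (X - old + new) * rot
      run_sum <- run_sum - old + new
      run_sq <- run_sq - old^2 + new^2
      fill(p + 1L, X, run_sum, run_sq)
    }
  }
  out
}

#' Fit a multiple-coefficient-binning (MCB) quantizer
#'
#' Learns per-coefficient breakpoints from training windows, one breakpoint
#' row per selected Fourier coefficient column. The default `equi_depth`
#' variant places the `c - 1` breakpoints at the `i N / c`-th order statistics
#' of each column, so training coefficients spread evenly over the alphabet;
#' the `sorted_prefix` variant instead takes the first `c - 1` of the
#' column's ascending-sorted values. Tied or duplicated breakpoints are
#' perturbed upward by a tiny stable offset so every row stays strictly
#' increasing (a degenerate all-constant column still yields `c` distinct
#' bins covering the real line through the implicit infinite end bins).
#'
#' @param W Matrix of training windows (rows) — extract these *without*
#'   overlap so they are independent — or a tibble from [sliding_windows()].
#' @param word_length Letters per word `l` (even).
#' @param alphabet_size Alphabet size `c`.
#' @param variant `"equi_depth"` or `"sorted_prefix"`.
#' @param normalize Z-normalize windows (drops the DC coefficient so words
#'   are scale-invariant).
#' @param sd_floor Passed to [znormalize()].
#' @return An object of class `mcb_model` with fields `coeff_indices` and
#'   `breakpoints` (an `(c - 1) x l` matrix, one column per coefficient).
#' @export
fit_mcb <- function(W, word_length = 8, alphabet_size = 4,
                    variant = c("equi_depth", "sorted_prefix"),
                    normalize = TRUE, sd_floor = 1e-8) {
  variant <- match.arg(variant)
  if (is.data.frame(W)) W <- windows_matrix(W)
  l <- as.integer(word_length)
  c_ <- as.integer(alphabet_size)
  if (l %% 2 != 0 || l < 2) stop_parameter("`word_length` must be a positive even number")
  if (c_ < 2 || c_ > 26) stop_parameter("`alphabet_size` must lie in [2, 26]")
  if (nrow(W) < c_) stop_insufficient("need at least `alphabet_size` training segments")
  coeffs <- fourier_matrix(W, l, drop_dc = normalize, normalize = normalize,
                           sd_floor = sd_floor)
  bp <- apply(coeffs, 2, column_breakpoints, c_ = c_, variant = variant)
  structure(
    list(word_length = l, alphabet_size = c_, letters = letters[seq_len(c_)],
         coeff_indices = seq_len(l), breakpoints = matrix(bp, nrow = c_ - 1),
         normalize = normalize, drop_dc = normalize, variant = variant,
         sd_floor = sd_floor, supervised = FALSE),
    class = "mcb_model")
}

column_breakpoints <- function(col, c_, variant) {
  s <- sort(col)
  N <- length(s)
  bp <- if (variant == "equi_depth") {
    s[pmax(1L, floor(seq_len(c_ - 1) * N / c_))]
  } else {
    s[seq_len(c_ - 1)]
  }
  make_strictly_increasing(bp)
}

# Stable de-duplication: nudge later entries up by a scale-aware epsilon.
make_strictly_increasing <- function(bp) {
  eps <- max(abs(bp), 1) * 1e-9
  for (i in seq_along(bp)[-1]) {
    if (bp[i] <= bp[i - 1]) bp[i] <- bp[i - 1] + eps
  }
  bp
}

#' @export
print.mcb_model <- function(x, ...) {
  cat(if (isTRUE(x$supervised)) "Supervised SFA (SFA-W)" else "SFA/MCB",
      "model: word length", x$word_length, "| alphabet",
      paste(x$letters, collapse = ""),
      "| variant", x$variant,
      if (x$normalize) "| z-normalized" else "", "\n")
  invisible(x)
}

#' SFA word for one window
#'
#' Approximation then quantization: the window's selected Fourier
#' coefficients are each mapped to a letter through their own breakpoint row
#' (half-open bins; a coefficient at a breakpoint takes the higher letter,
#' and the outer bins extend to infinity).
#'
#' @param x Numeric window.
#' @param model A fitted [fit_mcb()] / [fit_sfa_supervised()] model.
#' @return Single word string.
#' @export
sfa_transform <- function(x, model) {
  co <- window_coefficients(matrix(x, nrow = 1), model)
  word_from_coeffs(co[1, ], model)
}

# Coefficient matrix restricted to the model's selected columns.
window_coefficients <- function(W, model) {
  need <- max(model$coeff_indices)
  need <- need + (need %% 2)  # full (Re, Im) pairs
  full <- fourier_matrix(W, need, drop_dc = model$drop_dc,
                         normalize = model$normalize, sd_floor = model$sd_floor)
  full[, model$coeff_indices, drop = FALSE]
}

word_from_coeffs <- function(co, model) {
  lets <- vapply(seq_along(co), function(j) {
    bin_letters(co[j], model$breakpoints[, j], model$letters)
  }, character(1))
  paste(lets, collapse = "")
}

# Vectorized SFA over a windows-by-samples matrix -> character vector.
sfa_words_matrix <- function(W, model) {
  co <- window_coefficients(W, model)
  idx <- vapply(seq_len(ncol(co)), function(j) {
    findInterval(co[, j], model$breakpoints[, j]) + 1L
  }, integer(nrow(co)))
  idx <- matrix(idx, nrow = nrow(co))
  apply(matrix(model$letters[idx], nrow = nrow(co)), 1, paste, collapse = "")
}
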