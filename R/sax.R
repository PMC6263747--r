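#' Piecewise aggregate approximation
#'
#' Reduces a length-`n` window to `M` frame means. When `M` divides `n` the
#' frames are the contiguous `n/M`-sample blocks; otherwise the frame
#' boundaries fall at fractional sample positions and boundary samples are
#' weighted proportionally to their overlap with each frame.
#'
#' @param x Numeric vector.
#' @param M Number of frames, `1 <= M <= length(x)`.
#' @return Numeric vector of length `M`.
#' @export
paa <- function(x, M) {
  n <- length(x)
  M <- as.integer(M)
  if (M < 1 || M > n) stop_parameter("`M` must satisfy 1 <= M <= length(x)")
  if (M == n) return(x)
  if (n %% M == 0) {
    return(as.numeric(colMeans(matrix(x, nrow = n %/% M))))
  }
  bounds <- (0:M) * (n / M)
  vapply(seq_len(M), function(i) {
    lo <- bounds[i]
    hi <- bounds[i + 1]
    j <- seq.int(floor(lo) + 1, ceiling(hi))
    wt <- pmin(j, hi) - pmax(j - 1, lo)
    sum(wt * x[j]) / (hi - lo)
  }, numeric(1))
}

#' Equal-probability Gaussian breakpoints
#'
#' Thresholds that divide the standard normal density into `alphabet_size`
#' equal-probability regions: the quantiles at `i / alphabet_size`.
#'
#' @param alphabet_size Alphabet size `c`, between 2 and 26.
#' @return Strictly increasing numeric vector of length `c - 1`, symmetric
#'   about 0.
#' @export
gaussian_breakpoints <- function(alphabet_size) {
  c_ <- as.integer(alphabet_size)
  if (c_ < 2 || c_ > 26) stop_parameter("`alphabet_size` must lie in [2, 26]")
  qnorm(seq_len(c_ - 1) / c_)
}

#' SAX discretization model
#'
#' Fixes the alphabet, word length and Gaussian breakpoints used by
#' [sax_transform()]. Bins are half-open `[beta_{i-1}, beta_i)`: a value
#' exactly at a breakpoint takes the higher letter.
#'
#' @param alphabet_size Alphabet size (default 4).
#' @param word_length Letters per word (default 8).
#' @param sd_floor Passed to [znormalize()].
#' @return An object of class `sax_model`.
#' @export
sax_model <- function(alphabet_size = 4, word_length = 8, sd_floor = 1e-8) {
  c_ <- as.integer(alphabet_size)
  l <- as.integer(word_length)
  if (c_ < 2 || c_ > 26) stop_parameter("`alphabet_size` must lie in [2, 26]")
  if (l < 1) stop_parameter("`word_length` must be >= 1")
  structure(
    list(alphabet_size = c_, word_length = l,
         letters = letters[seq_len(c_)],
         breakpoints = gaussian_breakpoints(c_),
         sd_floor = sd_floor),
    class = "sax_model")
}

#' @export
print.sax_model <- function(x, ...) {
  cat("SAX model: word length", x$word_length, "| alphabet",
      paste(x$letters, collapse = ""), "\n")
  invisible(x)
}

# Map numeric values to letters against a breakpoint vector (half-open bins,
# value at a breakpoint takes the higher letter).
bin_letters <- function(values, breakpoints, letters) {
  letters[findInterval(values, breakpoints) + 1L]
}

#' SAX word for one window
#'
#' Z-normalizes the window, reduces it to `word_length` PAA frame means, and
#' maps each mean to a letter through the model's Gaussian breakpoints.
#'
#' @param x Numeric window (length >= `word_length`).
#' @param model A [sax_model()].
#' @return Single word string.
#' @export
sax_transform <- function(x, model) {
  if (length(x) < model$word_length) {
    stop_parameter("window shorter than the word length")
  }
  means <- paa(znormalize(x, model$sd_floor), model$word_length)
  paste(bin_letters(means, model$breakpoints, model$letters), collapse = "")
}

# Vectorized SAX over a windows-by-samples matrix -> character vector.
sax_words_matrix <- function(W, model) {
  zn <- znormalize_rows(W, model$sd_floor)
  Z <- zn$values
  n <- ncol(Z)
  l <- model$word_length
  if (l > n) stop_parameter("window shorter than the word length")
  if (n %% l == 0) {
    blk <- n %/% l
    # frame means by aggregation matrix
    A <- matrix(0, n, l)
    A[cbind(seq_len(n), rep(seq_len(l), each = blk))] <- 1 / blk
    P <- Z %*% A
  } else {
    P <- t(apply(Z, 1, function(row) paa(row, l)))
  }
  idx <- matrix(findInterval(P, model$breakpoints) + 1L, nrow = nrow(P))
  apply(matrix(model$letters[idx], nrow = nrow(P)), 1, paste, collapse = "")
}

#' Discretize segmented windows into a word sequence
#'
#' @param windows A tibble from [sliding_windows()] (columns `start_index`,
#'   `label`, list-column `values`).
#' @param model A [sax_model()] or fitted [mcb_model].
#' @param axis_tag Axis tag recorded on every word (e.g. `"x"`, `"mag"`).
#' @return A word-sequence tibble with columns `axis_tag`, `start_index`,
#'   `letters`, `label`, and attribute `reduced = FALSE`.
#' @export
discretize_windows <- function(windows, model, axis_tag = "x") {
  W <- windows_matrix(windows)
  words <- if (inherits(model, "sax_model")) {
    sax_words_matrix(W, model)
  } else if (inherits(model, "mcb_model")) {
    sfa_words_matrix(W, model)
  } else {
    stop_parameter("`model` must be a sax_model or a fitted mcb_model")
  }
  out <- tibble::tibble(
    axis_tag = axis_tag,
    start_index = windows$start_index,
    letters = words,
    label = windows$label)
  attr(out, "reduced") <- FALSE
  out
}

#' Numerosity reduction
#'
#' Collapses consecutive runs of identical words (within each axis) to their
#' first occurrence. Because every word keeps its original start index, the
#' full sequence can be reconstructed exactly with [numerosity_expand()].
#'
#' @param words A word-sequence tibble (columns `axis_tag`, `start_index`,
#'   `letters`).
#' @return The reduced tibble, attribute `reduced = TRUE`.
#' @export
numerosity_reduce <- function(words) {
  out <- words |>
    dplyr::group_by(.data$axis_tag) |>
    dplyr::arrange(.data$start_index, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() == 1L |
                    .data$letters != dplyr::lag(.data$letters)) |>
    dplyr::ungroup()
  attr(out, "reduced") <- TRUE
  out
}

#' Expand a numerosity-reduced sequence back onto its original grid
#'
#' @param words A reduced word-sequence tibble.
#' @param starts Integer vector: the full ordered grid of window start
#'   indexes of the original (unreduced) sequence, shared by all axes.
#' @return The unreduced word sequence on `starts`.
#' @export
numerosity_expand <- function(words, starts) {
  starts <- sort(unique(as.integer(starts)))
  words |>
    dplyr::group_by(.data$axis_tag) |>
    dplyr::arrange(.data$start_index, .by_group = TRUE) |>
    dplyr::reframe({
      kept <- dplyr::pick(dplyr::everything())
      idx <- findInterval(starts, kept$start_index)
      if (any(idx == 0)) stop_parameter("`starts` precede the first retained word")
      tibble::tibble(start_index = starts, letters = kept$letters[idx],
                     label = if ("label" %in% names(kept)) kept$label[idx] else NA_character_)
    }) |>
    (\(x) {attr(x, "reduced") <- FALSE; x})()
}

#' SAX lower-bounding distance (MINDIST)
#'
#' Distance between two SAX words that never exceeds the Euclidean distance
#' of the underlying z-normalized series of length `n`:
#' `sqrt(n / l) * sqrt(sum(cell(a_i, b_i)^2))`, where adjacent or equal
#' letters contribute 0 and letters further apart contribute the gap between
#' the breakpoints that separate them.
#'
#' @param word1,word2 Word strings of equal length over the model alphabet.
#' @param model A [sax_model()].
#' @param n Length of the original windows.
#' @return Nonnegative distance.
#' @export
sax_mindist <- function(word1, word2, model, n) {
  a <- match(strsplit(word1, "")[[1]], model$letters)
  b <- match(strsplit(word2, "")[[1]], model$letters)
  if (length(a) != length(b) || anyNA(a) || anyNA(b)) {
    stop_parameter("words must share length and alphabet with the model")
  }
  l <- length(a)
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  cell <- numeric(l)
  far <- (hi - lo) > 1
  cell[far] <- model$breakpoints[hi[far] - 1] - model$breakpoints[lo[far]]
  sqrt(n / l) * sqrt(sum(cell^2))
}
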