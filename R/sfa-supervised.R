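#' Rank Fourier coefficient columns by one-way ANOVA F
#'
#' Scores every column of a coefficient matrix by the ratio of between-class
#' to within-class variance and returns the `l` highest-scoring column
#' indices, descending. Columns that are constant within every class but
#' differ between classes receive infinite F; entirely constant columns score
#' 0.
#'
#' @param coeffs Numeric matrix, instances by coefficient columns.
#' @param labels Class labels (length `nrow(coeffs)`, >= 2 classes).
#' @param l Number of columns to keep.
#' @return Integer vector of `l` column indices, descending F; the scores are
#'   attached as attribute `"f_statistic"` (full-length, per column).
#' @export
anova_f_select <- function(coeffs, labels, l) {
  labels <- as.factor(labels)
  g <- nlevels(labels)
  N <- nrow(coeffs)
  if (g < 2) stop_parameter("need at least 2 classes")
  if (min(table(labels)) < 1) stop_parameter("every class needs at least one sample")
  if (N < g + 1) stop_parameter("need more instances than classes")
  l <- as.integer(l)
  if (l < 1 || l > ncol(coeffs)) stop_parameter("`l` out of range")

  n_g <- as.numeric(table(labels))
  sums <- rowsum(coeffs, labels)
  means_g <- sums / n_g
  grand <- colMeans(coeffs)
  ssb <- colSums(means_g^2 * n_g) - N * grand^2
  sst <- colSums(coeffs^2) - N * grand^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (g - 1)) / (ssw / (N - g))
  f[ssw == 0 & ssb > 0] <- Inf
  f[!is.finite(f) & !(ssw == 0 & ssb > 0)] <- 0
  keep <- order(f, decreasing = TRUE)[seq_len(l)]
  attr(keep, "f_statistic") <- f
  keep
}

shannon_entropy <- function(labels) {
  p <- table(labels)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

#' Information-gain breakpoints for one coefficient column
#'
#' Places `c - 1` cuts by recursive binary splitting: each split evaluates
#' every midpoint between adjacent distinct values and keeps the one
#' maximizing the information gain of the class labels; splitting then
#' proceeds on the remaining partition with the largest label entropy until
#' all cuts are placed. If the labels carry no signal (single class, or zero
#' gain everywhere) or the column has fewer distinct values than `c`, the
#' cuts fall back to equi-depth placement on the distinct values.
#'
#' @param x Numeric column of coefficients.
#' @param labels Class labels aligned with `x`.
#' @param alphabet_size Number of bins `c`.
#' @return Sorted, strictly increasing numeric vector of `c - 1` cuts.
#' @export
info_gain_breakpoints <- function(x, labels, alphabet_size) {
  c_ <- as.integer(alphabet_size)
  if (length(x) != length(labels)) stop_parameter("`x` and `labels` lengths differ")
  ord <- order(x)
  xs <- x[ord]
  ls <- as.character(labels)[ord]
  distinct <- unique(xs)

  equi_depth_fallback <- function() {
    make_strictly_increasing(
      column_breakpoints(distinct, c_ = c_, variant = "equi_depth"))
  }
  if (length(distinct) < c_ || length(unique(ls)) < 2) {
    return(equi_depth_fallback())
  }

  best_cut <- function(lo, hi) {
    # best midpoint cut inside sorted range [lo, hi]; NULL if no valid cut
    seg_x <- xs[lo:hi]
    seg_l <- ls[lo:hi]
    splits <- which(diff(seg_x) > 0)
    if (length(splits) == 0) return(NULL)
    h0 <- shannon_entropy(seg_l)
    n <- length(seg_l)
    gains <- vapply(splits, function(s) {
      h0 - (s / n) * shannon_entropy(seg_l[1:s]) -
        ((n - s) / n) * shannon_entropy(seg_l[(s + 1):n])
    }, numeric(1))
    b <- which.max(gains)
    list(cut = (seg_x[splits[b]] + seg_x[splits[b] + 1]) / 2,
         at = lo + splits[b] - 1L, gain = gains[b])
  }

  first <- best_cut(1L, length(xs))
  if (is.null(first) || first$gain <= 0) return(equi_depth_fallback())

  cuts <- first$cut
  nodes <- list(c(1L, first$at), c(first$at + 1L, length(xs)))
  while (length(cuts) < c_ - 1) {
    if (length(nodes) == 0) break
    ent <- vapply(nodes, function(nd) shannon_entropy(ls[nd[1]:nd[2]]), numeric(1))
    pick <- which.max(ent)
    nd <- nodes[[pick]]
    nodes <- nodes[-pick]
    res <- best_cut(nd[1], nd[2])
    if (is.null(res)) next
    cuts <- c(cuts, res$cut)
    nodes <- c(nodes, list(c(nd[1], res$at)), list(c(res$at + 1L, nd[2])))
  }
  if (length(cuts) < c_ - 1) {
    # not enough splittable structure: pad with equi-depth cuts not yet used
    extra <- setdiff(equi_depth_fallback(), cuts)
    cuts <- c(cuts, head(extra, c_ - 1 - length(cuts)))
  }
  make_strictly_increasing(sort(cuts))
}

#' Fit a supervised SFA quantizer (SFA-W)
#'
#' The supervised variant used by WEASEL: windows are z-normalized, *all*
#' available Fourier coefficients (up to the window length) are computed, a
#' one-way ANOVA F test picks the `word_length` most class-discriminative
#' real/imaginary columns, and each selected column gets its breakpoints from
#' information-gain binning instead of equi-depth order statistics. Train on
#' windows extracted without overlap so they are independent.
#'
#' @param W Matrix of training windows (rows), or a [sliding_windows()] tibble
#'   (its `label` column is then used when `labels` is missing).
#' @param labels Class label per training window.
#' @param word_length,alphabet_size Word and alphabet sizes.
#' @param sd_floor Passed to [znormalize()].
#' @return An `mcb_model` with `supervised = TRUE` whose `coeff_indices`
#'   record the ANOVA-selected columns.
#' @export
fit_sfa_supervised <- function(W, labels = NULL, word_length = 8,
                               alphabet_size = 4, sd_floor = 1e-8) {
  if (is.data.frame(W)) {
    if (is.null(labels)) labels <- W$label
    W <- windows_matrix(W)
  }
  l <- as.integer(word_length)
  c_ <- as.integer(alphabet_size)
  if (l < 1) stop_parameter("`word_length` must be >= 1")
  w <- ncol(W)
  n_complex <- w %/% 2                      # k = 1 .. floor(w/2), DC dropped
  full_l <- 2L * n_complex
  coeffs <- fourier_matrix(W, full_l, drop_dc = TRUE, normalize = TRUE,
                           sd_floor = sd_floor)
  keep <- anova_f_select(coeffs, labels, l)
  bp <- vapply(keep, function(j) {
    info_gain_breakpoints(coeffs[, j], labels, c_)
  }, numeric(c_ - 1))
  structure(
    list(word_length = l, alphabet_size = c_, letters = letters[seq_len(c_)],
         coeff_indices = as.integer(keep), breakpoints = matrix(bp, nrow = c_ - 1),
         normalize = TRUE, drop_dc = TRUE, variant = "info_gain",
         sd_floor = sd_floor, supervised = TRUE,
         f_statistic = attr(keep, "f_statistic")),
    class = "mcb_model")
}
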