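test_that("ANOVA F ranking matches oneway.test and orders by signal", {
  set.seed(21)
  labels <- rep(c("A", "B", "C"), each = 12)
  strong <- rnorm(36, mean = rep(c(0, 10, 20), each = 12), sd = 0.1)
  flat <- rnorm(36)                        # same distribution in every class
  const <- rep(4, 36)                      # identical across classes
  X <- cbind(flat, strong, const)
  keep <- anova_f_select(X, labels, 3)
  f <- attr(keep, "f_statistic")
  expect_equal(keep[1], 2L)                # strong column first
  expect_equal(keep[3], 3L)                # constant column last
  for (j in 1:2) {
    ref <- stats::oneway.test(X[, j] ~ factor(labels), var.equal = TRUE)
    expect_equal(unname(f[j]), unname(ref$statistic), tolerance = 1e-8)
  }
})

test_that("ANOVA selection validates its inputs", {
  X <- matrix(rnorm(20), 10)
  expect_error(anova_f_select(X, rep("A", 10), 1),
               class = "symbolichar_error_parameter")
  expect_error(anova_f_select(X, rep(c("A", "B"), 5), 5),
               class = "symbolichar_error_parameter")
})

test_that("a perfectly separated two-class column gets one clean cut", {
  x <- c(runif(20, 0, 4.5), runif(20, 5.5, 10))
  labels <- rep(c("A", "B"), each = 20)
  cut <- info_gain_breakpoints(x, labels, 2)
  expect_length(cut, 1)
  expect_gt(cut, max(x[labels == "A"]))
  expect_lt(cut, min(x[labels == "B"]))

  # at the optimum the gain equals the prior label entropy (here 1 bit);
  # verify against an exhaustive scan over every candidate midpoint
  xs <- sort(x)
  gains <- vapply(seq_len(39), function(s) {
    h <- function(l) {
      p <- table(l) / length(l)
      -sum(ifelse(p > 0, p * log2(p), 0))
    }
    ls <- rep(c("A", "B"), each = 20)[order(x)]
    h(ls) - (s / 40) * h(ls[1:s]) - ((40 - s) / 40) * h(ls[(s + 1):40])
  }, numeric(1))
  expect_equal(max(gains), 1, tolerance = 1e-12)
})

test_that("information gain binning degrades gracefully", {
  x <- rnorm(30)
  expect_equal(info_gain_breakpoints(x, rep("A", 30), 4),
               symbolichar:::column_breakpoints(unique(sort(x)), 4,
                                                "equi_depth"))
  # label renaming leaves the cuts unchanged
  set.seed(22)
  x2 <- rnorm(60)
  l2 <- sample(c("A", "B", "C"), 60, replace = TRUE)
  relabel <- c(A = "Z", B = "Y", C = "X")[l2]
  expect_equal(info_gain_breakpoints(x2, l2, 4),
               info_gain_breakpoints(x2, relabel, 4))
  # fewer distinct values than bins -> equi-depth on the distinct values
  x3 <- rep(c(1, 2), 10)
  bp <- info_gain_breakpoints(x3, rep(c("A", "B"), 10), 4)
  expect_length(bp, 3)
  expect_true(all(diff(bp) > 0))
})

test_that("recursive splitting places all cuts, larger entropy first", {
  set.seed(23)
  x <- c(rnorm(30, 0, 0.1), rnorm(30, 5, 0.1), rnorm(30, 10, 0.1))
  labels <- rep(c("A", "B", "C"), each = 30)
  cuts <- info_gain_breakpoints(x, labels, 4)
  expect_length(cuts, 3)
  expect_true(all(diff(cuts) > 0))
  # both class gaps receive a cut
  expect_true(any(cuts > 1 & cuts < 4))
  expect_true(any(cuts > 6 & cuts < 9))
})

test_that("supervised SFA recovers the informative frequency", {
  # one class carries a fixed-phase 5 Hz tone, the other only noise, so the
  # class difference in coefficient means is confined to the 5 Hz columns
  # (a tone both classes share would leak into every normalized column)
  set.seed(24)
  w <- 50
  t_axis <- (0:(w - 1)) / w
  make_win <- function(tone) {
    tone * cos(2 * pi * 5 * t_axis) + rnorm(w, 0, 0.3)
  }
  W <- rbind(t(replicate(40, make_win(1))), t(replicate(40, make_win(0))))
  labels <- rep(c("hasfive", "nofive"), each = 40)
  coeffs <- symbolichar:::fourier_matrix(W, 2 * (w %/% 2), drop_dc = TRUE,
                                         normalize = TRUE)
  keep <- anova_f_select(coeffs, labels, 4)
  # interleaved layout: Re of k = 5 is column 2*5 - 1 = 9, Im is 10
  expect_equal(keep[1], 9L)

  model <- fit_sfa_supervised(W, labels, word_length = 4, alphabet_size = 4)
  expect_true(9L %in% model$coeff_indices)
  expect_true(model$supervised)
  word <- sfa_transform(W[1, ], model)
  expect_equal(nchar(word), 4)
})
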