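words_for_instances <- function(seqs, labels, window_size = 50) {
  purrr::imap_dfr(seqs, function(ws, i) {
    tibble::tibble(instance = paste0("i", i), label = labels[i],
                   axis_tag = "x", window_size = window_size,
                   start_index = seq_along(ws) - 1L, letters = ws)
  })
}

test_that("bigrams pair consecutive non-overlapping words", {
  toks <- symbolichar:::sequence_tokens(c("aab", "abc", "acc", "aaa"), 50, "x")
  expect_true("w50:x:aab abc" %in% toks)
  expect_true("w50:x:acc aaa" %in% toks)
  expect_false("w50:x:abc acc" %in% toks)   # overlapping pair is not formed
  expect_equal(sum(grepl(" ", toks)), 2)
  # odd-length sequences leave the trailing word unpaired
  toks3 <- symbolichar:::sequence_tokens(c("aa", "bb", "cc"), 25, "y")
  expect_equal(sum(grepl(" ", toks3)), 1)
})

test_that("non-discriminative features are masked, discriminative kept", {
  n <- 25
  seqs <- c(
    lapply(1:n, function(i) c("key", "bg", "bg2", "bg")),
    lapply(1:n, function(i) c("alt", "bg", "bg2", "bg")))
  labels <- rep(c("A", "B"), each = n)
  feats <- weasel_featurize(words_for_instances(seqs, labels),
                            chi2_threshold = 2)
  # class-exclusive unigram: counts (n, 0) against expected (n/2, n/2)
  expect_true("w50:x:key" %in% feats$vocabulary)
  expect_equal(feats$chi2[["w50:x:key"]], n)
  # identical class-conditional frequencies score exactly 0 and are masked
  expect_equal(feats$chi2[["w50:x:bg2 bg"]], 0)
  expect_false("w50:x:bg2 bg" %in% feats$vocabulary)
  expect_false("w50:x:bg" %in% feats$vocabulary)
})

test_that("the chi-squared statistic matches a hand contingency computation", {
  seqs <- list(c("u", "v"), c("u", "v"), c("w", "v"), c("w", "v"))
  labels <- c("A", "A", "B", "B")
  feats <- weasel_featurize(words_for_instances(seqs, labels),
                            chi2_threshold = 0)
  # token totals: u -> (A = 2, B = 0); all-token class totals are equal,
  # so E = (1, 1) and chi2 = (2-1)^2/1 + (0-1)^2/1 = 2
  expect_equal(feats$chi2[["w50:x:u"]], 2)
  expect_equal(feats$chi2[["w50:x:v"]], 0)
})

test_that("the keep direction flag can invert the screening", {
  seqs <- list(c("u", "v"), c("u", "v"), c("w", "v"), c("w", "v"))
  labels <- c("A", "A", "B", "B")
  disc <- weasel_featurize(words_for_instances(seqs, labels),
                           chi2_threshold = 1, keep = "discriminative")
  inv <- weasel_featurize(words_for_instances(seqs, labels),
                          chi2_threshold = 1, keep = "nonsignificant")
  expect_true("w50:x:u" %in% disc$vocabulary)
  expect_false("w50:x:u" %in% inv$vocabulary)
  expect_true("w50:x:v" %in% inv$vocabulary)
})

test_that("transform mode reuses the fitted vocabulary and mask", {
  set.seed(52)
  seqs <- c(lapply(1:6, function(i) c("key", "bg")),
            lapply(1:6, function(i) c("bg", "bg")))
  labels <- rep(c("A", "B"), each = 6)
  fitted <- weasel_featurize(words_for_instances(seqs, labels),
                             chi2_threshold = 1)
  new_words <- words_for_instances(list(c("key", "novel")), "A")
  out <- weasel_featurize(new_words, fitted = fitted)
  expect_identical(out$vocabulary, fitted$vocabulary)
  expect_false(any(grepl("novel", colnames(out$x))))
})

test_that("the linear model separates separable data deterministically", {
  set.seed(53)
  n <- 30
  x <- Matrix::Matrix(c(rnorm(n, 5), rnorm(n, -5)), ncol = 1, sparse = TRUE)
  colnames(x) <- "f1"
  y <- rep(c("A", "B"), each = n)
  m1 <- train_linear_classifier(x, y, seed = 9)
  expect_equal(mean(predict(m1, x) == y), 1)
  m2 <- train_linear_classifier(x, y, seed = 9)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_error(train_linear_classifier(x, rep("A", 2 * n)),
               class = "symbolichar_error_parameter")
})

test_that("the informative feature dominates the fitted weights", {
  set.seed(54)
  n <- 40
  informative <- c(rnorm(n, 3, 0.5), rnorm(n, -3, 0.5))
  noise <- matrix(rnorm(2 * n * 5), ncol = 5)
  x <- cbind(informative, noise)
  colnames(x) <- c("signal", paste0("noise", 1:5))
  y <- rep(c("A", "B"), each = n)
  m <- train_linear_classifier(Matrix::Matrix(x, sparse = TRUE), y, seed = 3)
  td <- tidy(m)
  mags <- tapply(abs(td$estimate[td$term != "(Intercept)"]),
                 td$term[td$term != "(Intercept)"], max)
  expect_equal(names(which.max(mags)), "signal")
})
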