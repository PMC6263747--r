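#' WEASEL feature extraction: unigrams, bigrams, chi-squared screening
#'
#' Turns per-instance word sequences (possibly from several window sizes and
#' axes) into sparse count vectors. Each unigram token is tagged with its
#' window size and axis (`"w50:x:abcd"`); bigrams pair consecutive
#' *non-overlapping* words in sequence order (`w1 w2`, `w3 w4`, ...). At fit
#' time a Pearson chi-squared statistic of each feature's class-conditional
#' count distribution screens the vocabulary; by default high-statistic
#' (class-discriminative) features are kept and the rest are masked.
#'
#' @param words Tibble with columns `instance`, `letters`, `start_index`,
#'   `axis_tag`, `window_size`, and at fit time `label`.
#' @param labels Optional explicit class label per instance (otherwise taken
#'   from the `label` column).
#' @param chi2_threshold Screening threshold on the chi-squared statistic.
#' @param keep `"discriminative"` keeps features with statistic >= threshold
#'   (the default); `"nonsignificant"` keeps the complement.
#' @param fitted A fitted `weasel_features` object: transform-only mode that
#'   reuses its vocabulary and mask.
#' @return An object of class `weasel_features`: `vocabulary` (kept tokens),
#'   `chi2` (statistic per candidate token), `x` (sparse instance-by-feature
#'   count matrix over the kept vocabulary), `instances`, `labels`.
#' @export
weasel_featurize <- function(words, labels = NULL, chi2_threshold = 2,
                             keep = c("discriminative", "nonsignificant"),
                             fitted = NULL) {
  keep <- match.arg(keep)
  if (nrow(words) == 0) {
    abort("no words to featurize", class = "symbolichar_error_empty_features")
  }
  if (!"window_size" %in% names(words)) words$window_size <- NA_integer_
  if (!"instance" %in% names(words)) words$instance <- "inst1"

  counts <- words |>
    dplyr::group_by(.data$instance, .data$window_size, .data$axis_tag) |>
    dplyr::arrange(.data$start_index, .by_group = TRUE) |>
    dplyr::reframe(token = sequence_tokens(.data$letters,
                                           .data$window_size[1],
                                           .data$axis_tag[1])) |>
    dplyr::count(.data$instance, .data$token, name = "count")

  instances <- unique(words$instance)

  if (is.null(fitted)) {
    if (is.null(labels)) {
      if (!"label" %in% names(words)) stop_parameter("fit requires labels")
      lab_tbl <- dplyr::distinct(words, .data$instance, .data$label)
      labels <- stats::setNames(lab_tbl$label, lab_tbl$instance)[instances]
    } else {
      labels <- stats::setNames(as.character(labels), instances)
    }
    if (dplyr::n_distinct(labels) < 2) stop_parameter("fit requires >= 2 classes")
    chi2 <- feature_chi2(counts, labels)
    vocab <- if (keep == "discriminative") {
      names(chi2)[chi2 >= chi2_threshold]
    } else {
      names(chi2)[chi2 < chi2_threshold]
    }
    vocab <- sort(vocab)
  } else {
    chi2 <- fitted$chi2
    vocab <- fitted$vocabulary
    labels <- NULL
  }

  kept <- counts[counts$token %in% vocab, ]
  x <- Matrix::sparseMatrix(
    i = match(kept$instance, instances),
    j = match(kept$token, vocab),
    x = kept$count,
    dims = c(length(instances), length(vocab)),
    dimnames = list(instances, vocab))
  structure(list(vocabulary = vocab, chi2 = chi2, x = x,
                 instances = instances, labels = labels,
                 chi2_threshold = chi2_threshold, keep = keep),
            class = "weasel_features")
}

# Unigram + non-overlapping bigram tokens for one ordered word sequence.
sequence_tokens <- function(letters_seq, window_size, axis_tag) {
  prefix <- paste0("w", window_size, ":", axis_tag, ":")
  uni <- paste0(prefix, letters_seq)
  n <- length(letters_seq)
  if (n >= 2) {
    first <- seq(1, n - 1, by = 2)
    bi <- paste0(prefix, letters_seq[first], " ", letters_seq[first + 1])
    c(uni, bi)
  } else {
    uni
  }
}

# Pearson chi-squared statistic per token: observed per-class total counts
# vs the expectation under the pooled class proportions of all token counts.
feature_chi2 <- function(counts, labels) {
  counts$label <- labels[counts$instance]
  by_class <- counts |>
    dplyr::count(.data$token, .data$label, wt = .data$count, name = "n")
  class_tot <- tapply(by_class$n, by_class$label, sum)
  classes <- names(class_tot)
  p <- class_tot / sum(class_tot)
  tokens <- unique(by_class$token)
  O <- matrix(0, length(tokens), length(classes),
              dimnames = list(tokens, classes))
  O[cbind(match(by_class$token, tokens), match(by_class$label, classes))] <-
    by_class$n
  tok_tot <- rowSums(O)
  E <- outer(tok_tot, p)
  stats::setNames(rowSums((O - E)^2 / E), tokens)
}

#' @export
print.weasel_features <- function(x, ...) {
  cat("WEASEL features:", nrow(x$x), "instances x", length(x$vocabulary),
      "kept tokens (chi2 >= ", x$chi2_threshold, ")\n")
  invisible(x)
}

#' Multinomial logistic regression over WEASEL features
#'
#' Thin contract over a ridge-regularized multinomial logistic fit (glmnet at
#' a single fixed lambda): deterministic given the seed, exposes per-feature
#' weights, and attains 100% training accuracy on linearly separable data for
#' small `regularization`.
#'
#' @param features A `weasel_features` object (or a numeric matrix).
#' @param labels Class label per instance/row.
#' @param regularization Ridge penalty lambda (single value).
#' @param seed Integer seed.
#' @return An object of class `weasel_model` with `fit`, `feature_names`,
#'   `classes`.
#' @export
train_linear_classifier <- function(features, labels, regularization = 1e-3,
                                    seed = 1) {
  x <- if (inherits(features, "weasel_features")) features$x else features
  labels <- as.character(labels)
  if (dplyr::n_distinct(labels) < 2) stop_parameter("need >= 2 classes")
  if (min(table(labels)) < 2) stop_parameter("need >= 2 instances per class")
  x <- methods::as(x, "CsparseMatrix")
  padded <- FALSE
  if (ncol(x) < 2) {  # glmnet requires >= 2 predictors; pad with a null column
    x <- cbind(x, 0)
    colnames(x) <- c(colnames(x)[1], ".null")
    padded <- TRUE
  }
  set.seed(seed)
  fit <- glmnet::glmnet(x, factor(labels), family = "multinomial",
                        alpha = 0, lambda = regularization,
                        standardize = FALSE, maxit = 1e6)
  structure(list(fit = fit, feature_names = colnames(x), padded = padded,
                 classes = levels(factor(labels)),
                 regularization = regularization, seed = seed),
            class = "weasel_model")
}

#' @rdname train_linear_classifier
#' @param object A `weasel_model`.
#' @param newdata A `weasel_features` object or matrix aligned with the
#'   training vocabulary.
#' @param ... Unused.
#' @export
predict.weasel_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "weasel_features")) newdata$x else newdata
  x <- methods::as(x, "CsparseMatrix")
  if (object$padded) x <- cbind(x, 0)
  as.character(predict(object$fit, x, type = "class")[, 1])
}

#' @rdname train_linear_classifier
#' @param x A `weasel_model`.
#' @export
tidy.weasel_model <- function(x, ...) {
  cf <- coef(x$fit)
  purrr::imap_dfr(cf, function(beta, cls) {
    tibble::tibble(class = cls,
                   term = rownames(beta),
                   estimate = as.numeric(beta))
  }) |>
    dplyr::filter(.data$term != ".null")
}
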