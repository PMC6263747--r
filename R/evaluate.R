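#' Stratified k-fold cross-validation of a symbolic pipeline
#'
#' Splits instances into `k` stratified folds (at the instance or the user
#' level), fits the full pipeline on each training split — including every
#' data-dependent component: MCB breakpoints, idf table, chi-squared mask,
#' PCA fusion, linear model — and scores the held-out fold. Deterministic
#' given the seed.
#'
#' @param instances Instances from [collect_instances()].
#' @param pipeline A [har_pipeline()], or a list with elements `fit(train,
#'   fs, seed)` and `predict(model, test)` for a custom pipeline.
#' @param k Number of folds.
#' @param unit `"instance"` (random instances of all users in every fold) or
#'   `"user"` (whole users held out together; exposes cross-user
#'   generalization and the leakage question that instance-level folds hide).
#' @param seed Integer seed for fold assignment and downstream fits.
#' @param fs Sampling rate; defaults to the instances' `fs` attribute.
#' @return An object of class `har_cv` with per-instance `predictions`,
#'   per-fold accuracy, mean accuracy, a confusion matrix, the pipeline echo
#'   and the seed.
#' @export
cross_validate <- function(instances, pipeline, k = 10,
                           unit = c("instance", "user"), seed = 1, fs = NULL) {
  unit <- match.arg(unit)
  fs <- fs %||% attr(instances, "fs")
  n <- nrow(instances)
  if (n < k) stop_insufficient("fewer instances than folds")

  fold <- integer(n)
  set.seed(derive_seed(seed, 7L))
  if (unit == "instance") {
    # stratified and globally balanced: each class spreads evenly over the
    # folds, remainders go to the currently least-loaded folds
    load <- integer(k)
    for (cls in unique(instances$label)) {
      idx <- sample(which(instances$label == cls))
      n_c <- length(idx)
      counts <- rep(n_c %/% k, k)
      extra <- n_c %% k
      if (extra > 0) {
        ord <- sample(seq_len(k))
        ord <- ord[order(load[ord])]
        counts[ord[seq_len(extra)]] <- counts[ord[seq_len(extra)]] + 1L
      }
      fold[idx] <- rep(seq_len(k), times = counts)
      load <- load + counts
    }
  } else {
    users <- unique(sub("_.*$", "", instances$instance))
    ufold <- stats::setNames(rep_len(seq_len(k), length(users)), sample(users))
    fold <- ufold[sub("_.*$", "", instances$instance)]
  }

  for (f in seq_len(k)) {
    missing <- setdiff(unique(instances$label), instances$label[fold != f])
    if (length(missing) > 0) {
      stop_parameter(paste0("stratification impossible: class `", missing[1],
                            "` absent from the training split of fold ", f))
    }
  }

  preds <- purrr::map_dfr(seq_len(k), function(f) {
    train <- instances[fold != f, ]
    test <- instances[fold == f, ]
    predicted <- if (inherits(pipeline, "har_pipeline")) {
      fit <- fit_har(pipeline, train, fs = fs, seed = derive_seed(seed, f))
      unname(predict(fit, test))
    } else {
      m <- pipeline$fit(train, fs, derive_seed(seed, f))
      unname(pipeline$predict(m, test))
    }
    tibble::tibble(instance = test$instance, label = test$label,
                   fold = f, predicted = predicted)
  })

  fold_acc <- preds |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(accuracy = mean(.data$predicted == .data$label),
                     n = dplyr::n(), .groups = "drop")
  classes <- sort(unique(instances$label))
  confusion <- table(factor(preds$label, classes),
                     factor(preds$predicted, levels = sort(unique(
                       c(classes, preds$predicted)))))
  structure(list(predictions = preds, fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc$accuracy),
                 confusion = confusion, pipeline = pipeline,
                 k = k, unit = unit, seed = seed),
            class = "har_cv")
}

#' @export
print.har_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s level): %s / %s fusion\n", x$k, x$unit,
              x$pipeline$classifier %||% "custom",
              x$pipeline$fusion %||% "none"))
  cat(sprintf("  mean accuracy: %.1f%% (fold range %.1f%% - %.1f%%)\n",
              100 * x$mean_accuracy, 100 * min(x$fold_accuracy$accuracy),
              100 * max(x$fold_accuracy$accuracy)))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `har_cv`.
#' @param ... Unused.
#' @export
tidy.har_cv <- function(x, ...) {
  x$fold_accuracy
}

#' @rdname cross_validate
#' @export
glance.har_cv <- function(x, ...) {
  tibble::tibble(classifier = x$pipeline$classifier %||% "custom",
                 fusion = x$pipeline$fusion %||% "none",
                 k = x$k, unit = x$unit,
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = sd(x$fold_accuracy$accuracy),
                 n = nrow(x$predictions))
}

# ---------------------------------------------------------------------------
# Representation-size accounting and bit packing

# Paper-of-record layout for a stored word: ceil(l * log2(c) / 8) bytes of
# packed letters plus a 4-byte start index.
packed_word_bytes <- function(word_length, alphabet_size) {
  ceiling(word_length * log2(alphabet_size) / 8) + 4
}

# Reflected 2-bit code for a 4-letter alphabet; larger alphabets use the
# plain binary code of the letter index.
letter_codes <- function(alphabet_size) {
  if (alphabet_size == 4) c(a = 0L, b = 2L, c = 3L, d = 1L)
  else stats::setNames(seq_len(alphabet_size) - 1L,
                       letters[seq_len(alphabet_size)])
}

#' Pack symbolic words into bits
#'
#' Encodes each letter in `ceil(log2(c))` bits (for the default 4-letter
#' alphabet: `a = 00`, `b = 10`, `c = 11`, `d = 01`) and packs the codes into
#' bytes, one padded byte-aligned block per word. [unpack_words()] inverts
#' the encoding exactly.
#'
#' @param words Character vector of equal-length words.
#' @param alphabet_size Alphabet size.
#' @return Raw vector; attributes record the layout.
#' @export
pack_words <- function(words, alphabet_size = 4) {
  codes <- letter_codes(alphabet_size)
  bits_per <- ceiling(log2(alphabet_size))
  l <- nchar(words[1])
  bytes_per <- ceiling(l * bits_per / 8)
  out <- raw(length(words) * bytes_per)
  for (i in seq_along(words)) {
    lets <- strsplit(words[i], "")[[1]]
    if (length(lets) != l) stop_parameter("words must share one length")
    bits <- unlist(lapply(codes[lets], function(v) {
      as.integer(intToBits(v))[bits_per:1]
    }))
    bits <- c(bits, integer(bytes_per * 8 - length(bits)))
    bytes <- vapply(seq_len(bytes_per), function(b) {
      as.raw(sum(bits[((b - 1) * 8 + 1):(b * 8)] * 2^(7:0)))
    }, raw(1))
    out[((i - 1) * bytes_per + 1):(i * bytes_per)] <- bytes
  }
  structure(out, word_length = l, alphabet_size = alphabet_size,
            n_words = length(words))
}

#' @rdname pack_words
#' @param packed Raw vector from [pack_words()].
#' @export
unpack_words <- function(packed) {
  l <- attr(packed, "word_length")
  alphabet_size <- attr(packed, "alphabet_size")
  n_words <- attr(packed, "n_words")
  codes <- letter_codes(alphabet_size)
  decode <- stats::setNames(names(codes), codes)
  bits_per <- ceiling(log2(alphabet_size))
  bytes_per <- ceiling(l * bits_per / 8)
  vapply(seq_len(n_words), function(i) {
    bytes <- packed[((i - 1) * bytes_per + 1):(i * bytes_per)]
    bits <- unlist(lapply(bytes, function(b) as.integer(rawToBits(b))[8:1]))
    lets <- vapply(seq_len(l), function(j) {
      chunk <- bits[((j - 1) * bits_per + 1):(j * bits_per)]
      decode[[as.character(sum(chunk * 2^((bits_per - 1):0)))]]
    }, character(1))
    paste(lets, collapse = "")
  }, character(1))
}

#' Cost profile of a pipeline run
#'
#' Implementation-independent byte accounting: raw data cost is
#' `samples x 3 axes x 8` bytes; a symbolic representation costs the packed
#' word bytes (`ceil(l log2 c / 8)` per word) plus a 4-byte index per word; a
#' feature table costs 8 bytes per value. Stage timings are carried through
#' as reported (they are hardware-bound and never asserted).
#'
#' @param n_samples Number of raw triaxial samples.
#' @param n_words Number of stored symbolic words (use the numerosity-reduced
#'   count when reduction is on), or `NULL`.
#' @param word_length,alphabet_size Word layout.
#' @param n_features Number of stored feature values, or `NULL`.
#' @param extract_ms,train_ms Optional stage timings in milliseconds.
#' @return One-row tibble with `bytes_raw`, `bytes_repr`, `ratio`,
#'   `extract_ms`, `train_ms`.
#' @export
profile_cost <- function(n_samples, n_words = NULL, word_length = 8,
                         alphabet_size = 4, n_features = NULL,
                         extract_ms = NA_real_, train_ms = NA_real_) {
  bytes_raw <- n_samples * 3 * 8
  bytes_repr <- 0
  if (!is.null(n_words)) {
    bytes_repr <- bytes_repr +
      n_words * packed_word_bytes(word_length, alphabet_size)
  }
  if (!is.null(n_features)) bytes_repr <- bytes_repr + n_features * 8
  tibble::tibble(bytes_raw = bytes_raw, bytes_repr = bytes_repr,
                 ratio = bytes_repr / bytes_raw,
                 extract_ms = extract_ms, train_ms = train_ms)
}

#' Median wall-clock time of an expression
#'
#' @param f A zero-argument function to time.
#' @param times Number of runs (median reported).
#' @return Median elapsed milliseconds.
#' @export
time_median_ms <- function(f, times = 3) {
  ms <- vapply(seq_len(times), function(i) {
    unname(system.time(f())["elapsed"]) * 1000
  }, numeric(1))
  median(ms)
}
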