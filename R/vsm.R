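#' Logarithmic term frequency
#'
#' `log10(1 + f)` for positive counts and exactly 0 for a zero count, so a
#' word absent from a bag contributes nothing to its weight vector.
#'
#' @param f Nonnegative count(s).
#' @param base Logarithm base (default 10).
#' @return Numeric vector of tf weights.
#' @export
tf_weight <- function(f, base = 10) {
  if (any(f < 0)) stop_parameter("counts must be nonnegative")
  ifelse(f > 0, log(1 + f, base = base), 0)
}

#' Inverse document frequency over class bags
#'
#' `log10(T / d)` where `T` is the number of classes and `d` the number of
#' class bags containing the word: 0 for a word shared by every class, and
#' largest for class-exclusive words.
#'
#' @param word Word string(s).
#' @param class_bags Tibble with columns `label`, `word`, `count` (see
#'   [build_class_bags()]).
#' @param base Logarithm base (default 10).
#' @return Numeric idf value per word; `NA` for words in no class bag (the
#'   classifier treats them as zero-weight).
#' @export
idf_weight <- function(word, class_bags, base = 10) {
  T_ <- dplyr::n_distinct(class_bags$label)
  df <- class_bags |>
    dplyr::filter(.data$count > 0) |>
    dplyr::distinct(.data$label, .data$word) |>
    dplyr::count(.data$word, name = "df")
  d <- df$df[match(word, df$word)]
  log(T_ / d, base = base)
}

#' Group labeled words into per-class bags
#'
#' Pools the word sequences of every training instance of a class into one
#' bag of words. When `reduce` is set, numerosity reduction is applied per
#' sequence (grouped by instance and axis) before counting, so immobile
#' stretches that repeat one word do not dominate the bag.
#'
#' @param words Tibble with columns `letters`, `label`, and (for reduction /
#'   axis tagging) `axis_tag`, `start_index`, optionally `instance`.
#' @param reduce Apply numerosity reduction before counting.
#' @param tag_axis Prefix tokens with their axis tag (`"x:abcd"`) so words
#'   from different axes never collide in a shared bag.
#' @return Tibble with columns `label`, `word`, `count` (all counts >= 1).
#' @export
build_class_bags <- function(words, reduce = TRUE, tag_axis = TRUE) {
  if (nrow(words) == 0) stop_parameter("no words to bag")
  toks <- word_tokens(words, reduce = reduce, tag_axis = tag_axis)
  toks |>
    dplyr::count(.data$label, .data$word, name = "count") |>
    dplyr::arrange(.data$label, .data$word)
}

# Shared tokenization: optional numerosity reduction per sequence, optional
# axis tagging. Returns a tibble with columns label (if present), word.
word_tokens <- function(words, reduce = TRUE, tag_axis = TRUE) {
  if (reduce && !isTRUE(attr(words, "reduced"))) {
    # one grouped pass over (instance, axis) sequences: keep run heads only
    grouping <- intersect(c("instance", "axis_tag"), names(words))
    words <- words |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
      dplyr::arrange(.data$start_index, .by_group = TRUE) |>
      dplyr::filter(dplyr::row_number() == 1L |
                      .data$letters != dplyr::lag(.data$letters)) |>
      dplyr::ungroup()
  }
  tok <- if (tag_axis && "axis_tag" %in% names(words)) {
    paste0(words$axis_tag, ":", words$letters)
  } else {
    words$letters
  }
  out <- tibble::tibble(word = tok)
  if ("label" %in% names(words)) out$label <- words$label
  if ("instance" %in% names(words)) out$instance <- words$instance
  out
}

#' Instance histogram (bag of words)
#'
#' @param words Word-sequence tibble for one instance.
#' @param reduce,tag_axis As in [build_class_bags()].
#' @return Named integer vector of word counts.
#' @export
word_histogram <- function(words, reduce = TRUE, tag_axis = TRUE) {
  toks <- word_tokens(words, reduce = reduce, tag_axis = tag_axis)
  tab <- table(toks$word)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-class tf-idf weight matrix
#'
#' Builds the class-by-vocabulary weight matrix whose entries are
#' `tf(count) * idf(word)`. A word absent from a class has weight exactly 0
#' in that class's row, and a word present in every class gets an identically
#' zero column (its idf is 0).
#'
#' @param class_bags Tibble from [build_class_bags()].
#' @param base Logarithm base for tf and idf.
#' @return An object of class `tfidf_model` with fields `classes`,
#'   `vocabulary`, `weights` (class x word matrix), `idf` (named vector) and
#'   `log_base`.
#' @export
tfidf_matrix <- function(class_bags, base = 10) {
  classes <- sort(unique(class_bags$label))
  if (length(classes) < 2) {
    warn("tf-idf over a single class: every idf (and weight) is 0")
  }
  vocab <- sort(unique(class_bags$word))
  idf <- idf_weight(vocab, class_bags, base = base)
  names(idf) <- vocab
  Wm <- matrix(0, length(classes), length(vocab),
               dimnames = list(classes, vocab))
  Wm[cbind(match(class_bags$label, classes), match(class_bags$word, vocab))] <-
    tf_weight(class_bags$count, base = base)
  Wm <- sweep(Wm, 2, idf, `*`)
  structure(list(classes = classes, vocabulary = vocab, weights = Wm,
                 idf = idf, log_base = base),
            class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("tf-idf weight matrix:", length(x$classes), "classes x",
      length(x$vocabulary), "words\n")
  invisible(x)
}

#' @rdname tfidf_matrix
#' @param x A `tfidf_model`.
#' @param ... Unused.
#' @export
tidy.tfidf_model <- function(x, ...) {
  tibble::tibble(
    label = rep(x$classes, times = length(x$vocabulary)),
    word = rep(x$vocabulary, each = length(x$classes)),
    weight = as.numeric(x$weights))
}

#' Cosine similarity of two nonnegative weight vectors
#'
#' @param q,a Aligned numeric vectors.
#' @return Similarity in `[0, 1]` for nonnegative weights.
#' @export
cosine_similarity <- function(q, a) {
  nq <- sqrt(sum(q^2))
  na <- sqrt(sum(a^2))
  if (nq == 0 && na == 0) {
    abort("cosine similarity undefined: both vectors are zero",
          class = "symbolichar_error_undefined_similarity")
  }
  if (nq == 0 || na == 0) return(0)
  sum(q * a) / (nq * na)
}

#' Vector-space classification of a query word sequence
#'
#' Builds the query's histogram, weights it by `tf(query count) * training
#' idf` (words unseen in training contribute 0), and returns the class whose
#' tf-idf vector has the highest cosine similarity. Ties are broken by class
#' order with a warning.
#'
#' @param query Either a word-sequence tibble or a named count vector
#'   (a [word_histogram()]).
#' @param model A `tfidf_model` from [tfidf_matrix()].
#' @param reduce,tag_axis Histogram construction options (must match
#'   training).
#' @param on_no_evidence What to do when the query shares no word with any
#'   class: `"error"` (classed condition) or `"fallback"` (return the first
#'   class, with a warning).
#' @return The predicted class label; the per-class similarities are attached
#'   as attribute `"similarity"`.
#' @export
classify_vsm <- function(query, model, reduce = TRUE, tag_axis = TRUE,
                         on_no_evidence = c("error", "fallback")) {
  on_no_evidence <- match.arg(on_no_evidence)
  counts <- if (is.data.frame(query)) {
    word_histogram(query, reduce = reduce, tag_axis = tag_axis)
  } else {
    query
  }
  q <- numeric(length(model$vocabulary))
  names(q) <- model$vocabulary
  shared <- intersect(names(counts), model$vocabulary)
  q[shared] <- tf_weight(counts[shared], base = model$log_base) *
    model$idf[shared]
  if (sum(q) == 0) {
    if (on_no_evidence == "error") {
      stop_no_evidence("query shares no (weighted) word with any class")
    }
    warn("query shares no word with any class; falling back to first class")
    return(model$classes[1])
  }
  sims <- apply(model$weights, 1, function(a) {
    na <- sqrt(sum(a^2))
    if (na == 0) 0 else sum(q * a) / (sqrt(sum(q^2)) * na)
  })
  best <- which(sims == max(sims))
  if (length(best) > 1) {
    warn(paste0("similarity tie between classes ",
                paste(model$classes[best], collapse = ", "),
                "; keeping the first"))
  }
  out <- model$classes[best[1]]
  attr(out, "similarity") <- sims
  out
}
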