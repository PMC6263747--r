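#' BOSS histogram distance
#'
#' Squared-difference distance restricted to the words present in the first
#' histogram: `sum_{w : h1(w) > 0} (h1(w) - h2(w))^2`. The restriction makes
#' the distance deliberately asymmetric — words that only the second series
#' produced are ignored, so a noisy query is compared on its own evidence.
#'
#' @param h1,h2 Named count vectors (see [word_histogram()]) or tibbles with
#'   columns `word`, `count`.
#' @return Nonnegative distance; 0 for identical histograms.
#' @export
boss_distance <- function(h1, h2) {
  h1 <- as_counts(h1)
  h2 <- as_counts(h2)
  h1 <- h1[h1 > 0]
  if (length(h1) == 0) return(0)
  other <- h2[names(h1)]
  other[is.na(other)] <- 0
  sum((as.numeric(h1) - as.numeric(other))^2)
}

as_counts <- function(h) {
  if (is.data.frame(h)) return(stats::setNames(h$count, h$word))
  h
}

#' Fit a BOSS 1-nearest-neighbour model
#'
#' Stores one labeled histogram per training instance; prediction assigns a
#' query the label of the training histogram with the smallest
#' [boss_distance()] (ties go to the earliest training instance, with a
#' warning).
#'
#' @param histograms List of named count vectors, one per training instance.
#' @param labels Class label per histogram.
#' @return An object of class `boss_model`.
#' @export
boss_model <- function(histograms, labels) {
  if (length(histograms) == 0) stop_parameter("need at least one training histogram")
  if (length(histograms) != length(labels)) {
    stop_parameter("`histograms` and `labels` lengths differ")
  }
  structure(list(histograms = histograms, labels = as.character(labels)),
            class = "boss_model")
}

#' @export
print.boss_model <- function(x, ...) {
  cat("BOSS 1-NN model:", length(x$histograms), "training histograms,",
      dplyr::n_distinct(x$labels), "classes\n")
  invisible(x)
}

#' @rdname boss_model
#' @param query Named count vector for the query instance.
#' @param model A `boss_model`.
#' @return Predicted label with the distances attached as attribute
#'   `"distance"`.
#' @export
classify_boss_1nn <- function(query, model) {
  d <- vapply(model$histograms, boss_distance, numeric(1), h1 = query)
  best <- which(d == min(d))
  if (length(best) > 1 &&
      dplyr::n_distinct(model$labels[best]) > 1) {
    warn("1-NN distance tie across classes; keeping the earliest training instance")
  }
  out <- model$labels[best[1]]
  attr(out, "distance") <- d
  out
}
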