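#' Persist and reload symbolic artifacts
#'
#' Word sequences go to TSV (columns `axis_tag`, `start_index`, `letters`,
#' with the reduction flag on a leading `#` header line); histograms and
#' tf-idf weight matrices go to JSON. A write followed by a read returns an
#' artifact equal to the original (weights to 1e-12).
#'
#' @param words A word-sequence tibble.
#' @param path Output path.
#' @return `path` invisibly (writers); the reloaded artifact (readers).
#' @name persistence
NULL

#' @rdname persistence
#' @export
write_word_seq <- function(words, path) {
  force(words)  # evaluate before the connection truncates `path`
  con <- tryCatch(file(path, "w"), error = function(e) stop_io(conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste0("# reduced=", isTRUE(attr(words, "reduced"))), con)
  writeLines(paste("axis_tag", "start_index", "letters", sep = "\t"), con)
  if (nrow(words) > 0) {
    writeLines(paste(words$axis_tag, words$start_index, words$letters,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname persistence
#' @export
read_word_seq <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read file: ", path))
  lines <- readLines(path)
  reduced <- identical(lines[1], "# reduced=TRUE")
  body <- lines[-(1:2)]
  if (length(body) == 0) {
    out <- tibble::tibble(axis_tag = character(), start_index = integer(),
                          letters = character())
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    out <- tibble::tibble(
      axis_tag = vapply(parts, `[`, "", 1),
      start_index = as.integer(vapply(parts, `[`, "", 2)),
      letters = vapply(parts, `[`, "", 3))
  }
  attr(out, "reduced") <- reduced
  out
}

#' @rdname persistence
#' @param histogram Named count vector (see [word_histogram()]).
#' @param class_label Optional class label stored alongside the counts.
#' @export
write_histogram <- function(histogram, path, class_label = NULL) {
  payload <- list(
    class_label = class_label,
    counts = as.list(stats::setNames(as.integer(histogram), names(histogram))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname persistence
#' @export
read_histogram <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read file: ", path))
  payload <- jsonlite::read_json(path)
  counts <- unlist(payload$counts)
  out <- if (is.null(counts)) {
    stats::setNames(integer(0), character(0))
  } else {
    stats::setNames(as.integer(counts), names(counts))
  }
  attr(out, "class_label") <- payload$class_label
  out
}

#' @rdname persistence
#' @param model A `tfidf_model`.
#' @export
write_weight_matrix <- function(model, path) {
  payload <- list(classes = model$classes, vocabulary = model$vocabulary,
                  log_base = model$log_base,
                  idf = as.numeric(model$idf),
                  weights = unname(apply(model$weights, 1, identity,
                                         simplify = FALSE)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname persistence
#' @export
read_weight_matrix <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read file: ", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  Wm <- matrix(0, length(p$classes), length(p$vocabulary),
               dimnames = list(p$classes, p$vocabulary))
  if (length(p$vocabulary) > 0 && length(p$classes) > 0) {
    Wm[] <- if (is.matrix(p$weights)) {
      p$weights
    } else {
      matrix(unlist(p$weights), nrow = length(p$classes), byrow = TRUE)
    }
  }
  structure(list(classes = p$classes, vocabulary = p$vocabulary,
                 weights = Wm,
                 idf = stats::setNames(p$idf, p$vocabulary),
                 log_base = p$log_base),
            class = "tfidf_model")
}
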