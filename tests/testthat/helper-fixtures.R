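# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except through the package's own writers.

# A small labeled word-sequence tibble on one axis.
make_word_seq <- function(letters_vec, starts = seq_along(letters_vec) - 1L,
                          axis = "x", label = NA_character_) {
  out <- tibble::tibble(axis_tag = axis, start_index = as.integer(starts),
                        letters = letters_vec, label = label)
  attr(out, "reduced") <- FALSE
  out
}

# Random word sequence over a c-letter alphabet (repeats are likely, so
# numerosity reduction has work to do).
random_word_seq <- function(n_words, word_length = 4, alphabet_size = 3,
                            n_distinct = 5) {
  pool <- vapply(seq_len(n_distinct), function(i) {
    paste(sample(letters[seq_len(alphabet_size)], word_length, replace = TRUE),
          collapse = "")
  }, character(1))
  make_word_seq(sample(pool, n_words, replace = TRUE))
}

# Random histogram as a named count vector.
random_histogram <- function(n_words = 8, vocab = sprintf("w%02d", 1:15),
                             max_count = 5) {
  words <- sample(vocab, n_words)
  stats::setNames(sample.int(max_count, n_words, replace = TRUE), words)
}

# Tiny synthetic instance set (4 classes, fast to fit).
small_instances <- function(n_users = 3, bouts = 2, seed = 42, ...) {
  spec <- synthetic_spec(n_users = n_users, bouts_per_user_per_class = bouts,
                         seed = seed, ...)
  collect_instances(generate_synthetic_har(spec))
}

# Write lines to a temp file and return its path.
write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
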