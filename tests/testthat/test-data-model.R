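test_that("clean-dialect logs parse into a signal frame", {
  path <- write_lines_tmp(c(
    "user,activity,timestamp,x,y,z",
    "u1,walk,0.00,0.1,0.2,0.3",
    "u1,walk,0.02,0.2,0.3,0.4",
    "u1,walk,0.04,0.3,0.4,0.5"))
  fr <- read_har_csv(path, "clean")
  expect_s3_class(fr, "signal_frame")
  expect_equal(nrow(fr), 3)
  expect_equal(unique(fr$user_id), "u1")
  expect_equal(sampling_rate(fr), 50, tolerance = 1e-9)
  expect_equal(attr(fr, "load_report")$skipped, 0)
})

test_that("wisdm dialect tolerates trailing semicolons and no header", {
  path <- write_lines_tmp("1,Walking,100,1.0,2.0,3.0;")
  fr <- read_har_csv(path, "wisdm", fs = 20)
  expect_equal(nrow(fr), 1)
  expect_equal(c(fr$x, fr$y, fr$z), c(1, 2, 3))
})

test_that("malformed lines are skipped and counted", {
  path <- write_lines_tmp(c(
    "u1,walk,0.00,1,2,3;",
    "u1,walk,0.05,4",
    "u1,walk,0.10,7,8,9;"))
  fr <- read_har_csv(path, "wisdm", fs = 20)
  expect_equal(nrow(fr), 2)
  expect_equal(attr(fr, "load_report")$skipped, 1)
})

test_that("both dialects of the same samples yield identical frames", {
  body <- c("u1,walk,0.00,0.1,0.2,0.3", "u1,run,0.05,0.4,0.5,0.6")
  p_clean <- write_lines_tmp(c("user,activity,timestamp,x,y,z", body))
  p_wisdm <- write_lines_tmp(paste0(body, ";"))
  a <- read_har_csv(p_clean, "clean", fs = 20)
  b <- read_har_csv(p_wisdm, "wisdm", fs = 20)
  attr(a, "load_report") <- attr(b, "load_report") <- NULL
  expect_equal(a, b)
})

test_that("unreadable and empty inputs raise classed errors", {
  expect_error(read_har_csv(file.path(tempdir(), "nope.csv")),
               class = "symbolichar_error_io")
  path <- write_lines_tmp(c("user,activity,timestamp,x,y,z", "garbage line"))
  expect_error(read_har_csv(path, "clean", fs = 20),
               class = "symbolichar_error_insufficient_data")
})

test_that("irregular sampling is rejected when fs must be inferred", {
  path <- write_lines_tmp(c(
    "user,activity,timestamp,x,y,z",
    "u1,walk,0.00,1,1,1", "u1,walk,0.02,1,1,1", "u1,walk,0.30,1,1,1"))
  expect_error(read_har_csv(path, "clean"), "irregular")
  expect_silent(fr <- read_har_csv(path, "clean", fs = 50))
})

test_that("signal frames enforce ordered timestamps and positive fs", {
  df <- data.frame(user_id = "u1", activity = "walk",
                   timestamp = c(2, 1), x = 0, y = 0, z = 0)
  expect_error(signal_frame(df, 50), "nondecreasing")
  expect_error(signal_frame(df[1, ], 0), class = "symbolichar_error_parameter")
})

test_that("word sequences round-trip through TSV byte-stably", {
  words <- make_word_seq(c("abca", "bbcd", "aaaa"), starts = c(0L, 5L, 10L))
  words$label <- NULL
  path <- withr::local_tempfile()
  write_word_seq(words, path)
  expect_equal(read_word_seq(path), words, ignore_attr = "reduced")
  first <- readBin(path, "raw", file.size(path))
  reloaded <- read_word_seq(path)
  write_word_seq(reloaded, path)
  expect_identical(readBin(path, "raw", file.size(path)), first)
})

test_that("empty and populated histograms round-trip through JSON", {
  path <- withr::local_tempfile()
  empty <- stats::setNames(integer(0), character(0))
  write_histogram(empty, path)
  expect_equal(unname(read_histogram(path)), unname(empty))
  h <- c(abca = 3L, bbcd = 1L)
  write_histogram(h, path, class_label = "walk")
  back <- read_histogram(path)
  expect_equal(back, h, ignore_attr = TRUE)
  expect_equal(attr(back, "class_label"), "walk")
})

test_that("weight matrices round-trip within 1e-12", {
  bags <- tibble::tibble(
    label = c("A", "A", "B", "B"),
    word = c("aa", "ab", "ab", "cd"),
    count = c(3L, 1L, 2L, 5L))
  m <- tfidf_matrix(bags)
  path <- withr::local_tempfile()
  write_weight_matrix(m, path)
  back <- read_weight_matrix(path)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_equal(back$vocabulary, m$vocabulary)
  expect_equal(back$idf, m$idf, tolerance = 1e-12)
})

test_that("round-trip persistence is lossless on random artifacts", {
  set.seed(11)
  path <- withr::local_tempfile()
  for (i in 1:10) {
    ws <- random_word_seq(sample(1:12, 1))
    ws$label <- NULL
    write_word_seq(ws, path)
    expect_equal(read_word_seq(path), ws, ignore_attr = "reduced")

    h <- random_histogram()
    write_histogram(h, path)
    expect_equal(read_histogram(path), h, ignore_attr = TRUE)

    bags <- tibble::tibble(
      label = rep(c("A", "B"), each = 4),
      word = c(sample(letters, 4), sample(letters, 4)),
      count = sample.int(9, 8, replace = TRUE))
    m <- tfidf_matrix(bags)
    write_weight_matrix(m, path)
    expect_equal(read_weight_matrix(path)$weights, m$weights,
                 tolerance = 1e-12)
  }
})
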