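test_that("tf weight follows the log rule with an exact zero branch", {
  expect_identical(tf_weight(0), 0)
  expect_equal(tf_weight(9), 1)            # log10(10)
  f <- 0:20
  expect_true(all(diff(tf_weight(f)) > 0))
  expect_error(tf_weight(-1), class = "symbolichar_error_parameter")
})

test_that("idf weight reflects how many classes share a word", {
  bags <- tibble::tibble(
    label = rep(sprintf("c%02d", 1:10), each = 1),
    word = c("shared", rep("other", 9)),
    count = 1L)
  bags <- rbind(bags, tibble::tibble(label = sprintf("c%02d", 2:10),
                                     word = "shared", count = 1L))
  expect_equal(idf_weight("shared", bags), 0)        # in all 10 classes
  bags2 <- tibble::tibble(label = sprintf("c%02d", 1:10),
                          word = rep(c("rare", "x"), c(1, 9)), count = 1L)
  expect_equal(idf_weight("rare", bags2), 1)         # log10(10 / 1)
  # nonincreasing in the number of classes containing the word
  df_counts <- 1:10
  idfs <- log10(10 / df_counts)
  expect_true(all(diff(idfs) < 0))
})

test_that("class bags conserve and add counts", {
  words <- make_word_seq(c("aa", "ab", "aa", "cd", "cd"),
                         label = c("A", "A", "A", "B", "B"))
  bags <- build_class_bags(words, reduce = FALSE, tag_axis = FALSE)
  sums <- tapply(bags$count, bags$label, sum)
  expect_equal(as.numeric(sums), c(3, 2))
  doubled <- build_class_bags(rbind(words, words), reduce = FALSE,
                              tag_axis = FALSE)
  expect_equal(doubled$count, bags$count * 2L)
})

test_that("numerosity reduction collapses runs before bagging", {
  words <- make_word_seq(c("aa", "aa", "ab"), label = "A")
  bags <- build_class_bags(words, reduce = TRUE, tag_axis = FALSE)
  expect_equal(bags$count[bags$word == "aa"], 1L)
  expect_equal(bags$count[bags$word == "ab"], 1L)
})

test_that("tf-idf weights vanish exactly where the model says they must", {
  bags <- tibble::tibble(
    label = c("A", "A", "B", "B"),
    word = c("accbb", "cdaaa", "cdaaa", "ddbca"),
    count = c(2L, 5L, 5L, 1L))
  m <- tfidf_matrix(bags)
  expect_equal(m$weights["B", "accbb"], 0)      # absent from class B
  expect_equal(unname(m$weights[, "cdaaa"]), c(0, 0))  # shared by all classes
  expect_true(m$weights["A", "accbb"] > 0)
  expect_true(all(m$weights >= 0))
})

test_that("disjoint vocabularies give a block-diagonal weight pattern", {
  bags <- tibble::tibble(label = rep(c("A", "B"), each = 2),
                         word = c("w1", "w2", "w3", "w4"),
                         count = 3L)
  m <- tfidf_matrix(bags)
  expect_true(all(m$weights["A", c("w1", "w2")] > 0))
  expect_true(all(m$weights["A", c("w3", "w4")] == 0))
  expect_true(all(m$weights["B", c("w3", "w4")] > 0))
  expect_true(all(m$weights["B", c("w1", "w2")] == 0))
  expect_warning(tfidf_matrix(bags[bags$label == "A", ]), "single class")
})

test_that("tidy() lays the weight matrix out long", {
  bags <- tibble::tibble(label = c("A", "B"), word = c("w1", "w2"), count = 2L)
  td <- tidy(tfidf_matrix(bags))
  expect_equal(nrow(td), 4)
  expect_named(td, c("label", "word", "weight"))
})

test_that("cosine similarity matches the closed forms", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 0.7071068,
               tolerance = 1e-6)
  expect_error(cosine_similarity(c(0, 0), c(0, 0)),
               class = "symbolichar_error_undefined_similarity")
})

test_that("vector-space classification follows the tf-idf oracle", {
  bags <- tibble::tibble(label = c("A", "B"), word = c("ab", "cd"),
                         count = c(3L, 3L))
  m <- tfidf_matrix(bags)
  expect_equal(as.character(classify_vsm(c(ab = 1L), m)), "A")
  # query equal to a class bag recovers that class
  expect_equal(as.character(classify_vsm(c(cd = 3L), m)), "B")
  # unseen words carry no weight
  expect_error(classify_vsm(c(zz = 4L), m),
               class = "symbolichar_error_no_evidence")
  expect_warning(out <- classify_vsm(c(zz = 4L), m,
                                     on_no_evidence = "fallback"))
  expect_equal(as.character(out), "A")
})

test_that("training bags are classified back to their own class", {
  set.seed(31)
  bags <- tibble::tibble(
    label = rep(c("A", "B", "C"), each = 4),
    word = paste0(rep(c("a", "b", "c"), each = 4), 1:4),
    count = sample.int(6, 12, replace = TRUE))
  m <- tfidf_matrix(bags)
  for (cls in c("A", "B", "C")) {
    sub <- bags[bags$label == cls, ]
    q <- stats::setNames(sub$count, sub$word)
    expect_equal(as.character(classify_vsm(q, m)), cls)
  }
})
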