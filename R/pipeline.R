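#' Symbolic classification pipeline specification
#'
#' Bundles the choices that define one end-to-end symbolic HAR pipeline:
#' which classifier (and hence which discretizer), how the three axes are
#' fused, and the windowing/word parameters. Defaults follow the common
#' symbolic-representation settings: 1 s windows (`window_samples = NULL`
#' resolves to the sampling rate), dense word extraction at stride 1 with
#' numerosity reduction (the bag-of-patterns convention; set `overlap` for
#' sparser extraction), and 8-letter words over a 4-letter alphabet.
#'
#' @param classifier `"boss"` (SFA words, per-instance histograms, 1-NN on
#'   the BOSS distance), `"bossvs"` (SFA words, per-class tf-idf, cosine),
#'   `"saxvsm"` (SAX words, per-class tf-idf, cosine) or `"weasel"`
#'   (supervised SFA words, unigram/bigram features, chi-squared screening,
#'   logistic regression).
#' @param fusion `"stack"` (per-axis words pooled into one axis-tagged
#'   histogram), `"magnitude"` or `"pca"` (one fused series; PCA is fitted on
#'   training data only).
#' @param window_samples Window length in samples; `NULL` means one second.
#' @param overlap Window overlap fraction for word extraction, or `NULL`
#'   (default) for dense stride-1 extraction.
#' @param word_length,alphabet_size Word parameters.
#' @param mcb_variant MCB breakpoint variant for SFA (see [fit_mcb()]).
#' @param normalize Z-normalize windows before the Fourier transform.
#' @param reduce Apply numerosity reduction before counting words.
#' @param chi2_threshold,regularization WEASEL-specific controls.
#' @return An object of class `har_pipeline`.
#' @export
har_pipeline <- function(classifier = c("boss", "bossvs", "saxvsm", "weasel"),
                         fusion = c("stack", "magnitude", "pca"),
                         window_samples = NULL, overlap = NULL,
                         word_length = 8, alphabet_size = 4,
                         mcb_variant = c("equi_depth", "sorted_prefix"),
                         normalize = TRUE, reduce = TRUE,
                         chi2_threshold = 2, regularization = 1e-3) {
  structure(list(
    classifier = match.arg(classifier), fusion = match.arg(fusion),
    window_samples = window_samples, overlap = overlap,
    word_length = as.integer(word_length),
    alphabet_size = as.integer(alphabet_size),
    mcb_variant = match.arg(mcb_variant), normalize = normalize,
    reduce = reduce, chi2_threshold = chi2_threshold,
    regularization = regularization),
    class = "har_pipeline")
}

#' @export
print.har_pipeline <- function(x, ...) {
  cat("HAR pipeline:", x$classifier, "| fusion", x$fusion,
      "| word", x$word_length, "x alphabet", x$alphabet_size, "\n")
  invisible(x)
}

# Fused series per instance: a named list of one or three numeric vectors.
fuse_instance <- function(pipeline, inst_row, pca_obj = NULL) {
  switch(pipeline$fusion,
    stack = list(x = inst_row$x[[1]], y = inst_row$y[[1]], z = inst_row$z[[1]]),
    magnitude = list(
      mag = fuse_magnitude(inst_row$x[[1]], inst_row$y[[1]], inst_row$z[[1]])),
    pca = list(
      pc1 = fuse_pca(pca_obj, tibble::tibble(
        x = inst_row$x[[1]], y = inst_row$y[[1]], z = inst_row$z[[1]]))))
}

# Word table for a set of instances given fitted per-axis discretizers.
instances_to_words <- function(pipeline, instances, w, discretizers,
                               pca_obj = NULL) {
  purrr::map_dfr(seq_len(nrow(instances)), function(i) {
    inst <- instances[i, ]
    series <- fuse_instance(pipeline, inst, pca_obj)
    purrr::imap_dfr(series, function(s, ax) {
      wins <- if (is.null(pipeline$overlap)) {
        sliding_windows(s, w, stride = 1L)
      } else {
        sliding_windows(s, w, overlap = pipeline$overlap)
      }
      out <- discretize_windows(wins, discretizers[[ax]], axis_tag = ax)
      out$instance <- inst$instance
      out$label <- inst$label
      out$window_size <- w
      out
    })
  })
}

# Non-overlapping training windows per axis (independent MCB training set).
training_windows <- function(pipeline, instances, w, pca_obj = NULL) {
  axes <- switch(pipeline$fusion, stack = c("x", "y", "z"),
                 magnitude = "mag", pca = "pc1")
  out <- stats::setNames(vector("list", length(axes)), axes)
  for (i in seq_len(nrow(instances))) {
    inst <- instances[i, ]
    series <- fuse_instance(pipeline, inst, pca_obj)
    for (ax in axes) {
      wins <- sliding_windows(series[[ax]], w, overlap = 0)
      out[[ax]] <- c(out[[ax]], list(
        list(mat = windows_matrix(wins),
             labels = rep(inst$label, nrow(wins)))))
    }
  }
  lapply(out, function(pieces) {
    list(mat = do.call(rbind, lapply(pieces, `[[`, "mat")),
         labels = unlist(lapply(pieces, `[[`, "labels")))
  })
}

#' Fit a symbolic HAR pipeline on training instances
#'
#' Runs the full training path: axis fusion (PCA fitted here, on the training
#' instances only), per-axis discretizer fitting (MCB quantizers are trained
#' on non-overlapping windows), word extraction with overlap, and the
#' classifier-specific model fit.
#'
#' @param pipeline A [har_pipeline()].
#' @param instances Training instances from [collect_instances()].
#' @param fs Sampling rate in Hz (defaults to the instances' `fs` attribute).
#' @param seed Seed forwarded to stochastic components (the linear model).
#' @return An object of class `har_fit`.
#' @export
fit_har <- function(pipeline, instances, fs = NULL, seed = 1) {
  fs <- fs %||% attr(instances, "fs")
  if (is.null(fs)) stop_parameter("supply `fs` or instances with an fs attribute")
  w <- pipeline$window_samples %||% as.integer(round(fs))

  pca_obj <- NULL
  if (pipeline$fusion == "pca") {
    samples <- tibble::tibble(
      x = unlist(instances$x), y = unlist(instances$y), z = unlist(instances$z))
    pca_obj <- fit_pca_fusion(samples)
  }

  use_sax <- pipeline$classifier == "saxvsm"
  axes <- switch(pipeline$fusion, stack = c("x", "y", "z"),
                 magnitude = "mag", pca = "pc1")
  if (use_sax) {
    model <- sax_model(pipeline$alphabet_size, pipeline$word_length)
    discretizers <- stats::setNames(rep(list(model), length(axes)), axes)
  } else {
    tw <- training_windows(pipeline, instances, w, pca_obj)
    discretizers <- purrr::imap(tw, function(piece, ax) {
      if (pipeline$classifier == "weasel") {
        fit_sfa_supervised(piece$mat, piece$labels,
                           word_length = pipeline$word_length,
                           alphabet_size = pipeline$alphabet_size)
      } else {
        fit_mcb(piece$mat, word_length = pipeline$word_length,
                alphabet_size = pipeline$alphabet_size,
                variant = pipeline$mcb_variant,
                normalize = pipeline$normalize)
      }
    })
  }

  words <- instances_to_words(pipeline, instances, w, discretizers, pca_obj)

  feats <- NULL
  model <- switch(pipeline$classifier,
    saxvsm = ,
    bossvs = {
      bags <- build_class_bags(words, reduce = pipeline$reduce)
      tfidf_matrix(bags)
    },
    boss = {
      hs <- split_histograms(words, pipeline$reduce)
      boss_model(hs$histograms, hs$labels)
    },
    weasel = {
      feats <- weasel_featurize(words, chi2_threshold = pipeline$chi2_threshold)
      train_linear_classifier(feats, feats$labels,
                              regularization = pipeline$regularization,
                              seed = seed)
    })

  structure(list(pipeline = pipeline, window_samples = w, fs = fs,
                 pca = pca_obj, discretizers = discretizers, model = model,
                 features = feats,
                 classes = sort(unique(instances$label))),
            class = "har_fit")
}

split_histograms <- function(words, reduce) {
  by_inst <- split(words, words$instance)
  list(histograms = lapply(by_inst, word_histogram, reduce = reduce),
       labels = vapply(by_inst, function(d) d$label[1], character(1)))
}

#' @export
print.har_fit <- function(x, ...) {
  cat("Fitted", x$pipeline$classifier, "pipeline (fusion:", x$pipeline$fusion,
      "| window", x$window_samples, "samples)\n")
  invisible(x)
}

#' Predict activity labels for new instances
#'
#' @param object A fitted `har_fit`.
#' @param instances Instances from [collect_instances()].
#' @param ... Unused.
#' @return Character vector of predicted labels, one per instance.
#' @export
predict.har_fit <- function(object, instances, ...) {
  pipeline <- object$pipeline
  words <- instances_to_words(pipeline, instances, object$window_samples,
                              object$discretizers, object$pca)
  by_inst <- split(words, words$instance)[unique(words$instance)]
  inst_ids <- instances$instance
  switch(pipeline$classifier,
    saxvsm = ,
    bossvs = vapply(inst_ids, function(id) {
      as.character(classify_vsm(by_inst[[id]], object$model,
                                reduce = pipeline$reduce,
                                on_no_evidence = "fallback"))
    }, character(1)),
    boss = vapply(inst_ids, function(id) {
      as.character(classify_boss_1nn(
        word_histogram(by_inst[[id]], reduce = pipeline$reduce),
        object$model))
    }, character(1)),
    weasel = {
      feats <- weasel_featurize(words, fitted = object$features)
      preds <- predict(object$model, feats)
      stats::setNames(preds, feats$instances)[inst_ids]
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
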