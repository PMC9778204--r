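# Feature assembly, cross-validated evaluation and classifier
# comparison.
#
# Each denoised segment yields the four-component feature vector
# (MSEN1, MSEN2 scale-window means; alpha0 and alpha_min of the
# wavelet-leader spectrum) or, in per-scale mode, the 24-component
# vector (11 + 11 per-scale entropies + the two singularity indices).
# Evaluation is stratified 5-fold cross-validation with pooled
# confusion matrices; the positive class is Normal (NSR).

#' Extract classifier features from one segment
#'
#' @param segment A (denoised) `ecg_segment` or signal-like object
#'   longer than 256 samples.
#' @param scales Entropy scale window (default `10:20`).
#' @param m Embedding dimension (default 2).
#' @param r_frac Similarity tolerance fraction (default 0.15).
#' @param qmax,dq,j1 Multifractal grid parameters (defaults 5, 0.25, 1).
#' @param per_scale If `TRUE`, emit one entropy column per scale and
#'   moment instead of the scale-window means.
#' @param segment_id Identifier stored in the output row.
#' @return A one-row tibble: `segment_id`, `label`, the feature
#'   columns, and `ok` (`FALSE` when any feature is undefined).
#' @export
extract_features <- function(segment, scales = 10:20, m = 2, r_frac = 0.15,
                             qmax = 5, dq = 0.25, j1 = 1,
                             per_scale = FALSE, segment_id = NA_character_) {
  x <- signal_values(segment)
  label <- if (is.list(segment) && !is.null(segment$label)) {
    segment$label
  } else {
    NA_character_
  }
  if (is.na(segment_id) && is.list(segment) && !is.null(segment$record_id)) {
    segment_id <- paste0(segment$record_id, "@",
                         if (!is.null(segment$start)) segment$start else 0)
  }
  spec <- mf_spectrum(x, qmax = qmax, dq = dq, j1 = j1)
  base <- tibble::tibble(segment_id = segment_id, label = label)
  if (per_scale) {
    p1 <- mse_profile(x, scales, m, r_frac, moment = 1)
    p2 <- mse_profile(x, scales, m, r_frac, moment = 2)
    e1 <- stats::setNames(as.list(p1$entropy), paste0("msen1_s", p1$scale))
    e2 <- stats::setNames(as.list(p2$entropy), paste0("msen2_s", p2$scale))
    feat <- tibble::as_tibble(c(e1, e2))
  } else {
    feat <- tibble::tibble(
      msen1 = as.numeric(mse_feature(x, min(scales), max(scales), m,
                                     r_frac, moment = 1)),
      msen2 = as.numeric(mse_feature(x, min(scales), max(scales), m,
                                     r_frac, moment = 2))
    )
  }
  feat$alpha0 <- spec$features$alpha0
  feat$alpha_min <- spec$features$alpha_min
  out <- dplyr::bind_cols(base, feat)
  out$ok <- !anyNA(feat)
  if (!out$ok) {
    rlang::warn(paste0("segment ", segment_id,
                       ": undefined feature component; flagged"))
  }
  out
}

#' Feature table for a list of segments
#'
#' Maps [extract_features()] over segments and binds the rows.
#'
#' @param segments List of segments.
#' @param ... Passed to [extract_features()].
#' @return A tibble, one row per segment.
#' @export
feature_table <- function(segments, ...) {
  purrr::map_dfr(seq_along(segments), function(i) {
    extract_features(segments[[i]], ..., segment_id = paste0("seg", i))
  })
}

#' Stratified k-fold split
#'
#' Partitions indices into `k` folds, stratified by label: within each
#' class the (seed-shuffled) indices are dealt round-robin, so fold
#' sizes differ by at most one per class and every fold sees both
#' classes.
#'
#' @param labels Vector of class labels, length `n >= k`.
#' @param k Number of folds (default 5).
#' @param seed Integer RNG seed for the within-class shuffle.
#' @return List of `k` lists with integer vectors `train` and `test`.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2) stop_invalid("k must be at least 2")
  if (n < k) stop_invalid("fewer samples than folds")
  fold <- integer(n)
  with_rng(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}

#' Confusion-matrix metric suite
#'
#' The five standard metrics as percentages rounded half-up to two
#' decimals: accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1
#' `2TP/(2TP+FN+FP)`. The positive class is Normal (NSR). Ratios with
#' zero denominators are reported as `NA`.
#'
#' @param tp,tn,fp,fn Confusion-matrix counts (positive = Normal/NSR).
#' @return A one-row tibble with the counts and `acc`, `ppv`, `sen`,
#'   `spe`, `f1` in percent.
#' @export
evaluate_confusion <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop_invalid("confusion counts must be non-negative and not all zero")
  }
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    acc = round_half_up(ratio(tp + tn, tp + tn + fp + fn)),
    ppv = round_half_up(ratio(tp, tp + fp)),
    sen = round_half_up(ratio(tp, tp + fn)),
    spe = round_half_up(ratio(tn, tn + fp)),
    f1 = round_half_up(ratio(2 * tp, 2 * tp + fn + fp))
  )
}

confusion_counts <- function(truth, pred, positive) {
  tibble::tibble(
    tp = sum(truth == positive & pred == positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive),
    fn = sum(truth == positive & pred != positive)
  )
}

#' Cross-validated evaluation of the ELM classifier
#'
#' Runs stratified k-fold cross-validation on a feature table: for each
#' fold an ELM is trained on the remaining folds and evaluated on the
#' held-out fold. Per-fold confusion matrices are summed (pooled)
#' before computing the headline metrics; per-fold accuracies are also
#' reported. Rows flagged `ok = FALSE` (undefined features) are dropped
#' from both training and testing with a count in the report.
#'
#' @param features Tibble from [feature_table()] with a `label` column.
#' @param hidden Hidden nodes for the ELM (default 60).
#' @param k Number of folds (default 5; must be at least 2).
#' @param seed Integer seed controlling fold assignment and the ELM
#'   input layer.
#' @param positive Positive class label (default `"NSR"`).
#' @return An object of class `mf_eval`: list with `per_fold` (tibble
#'   of fold confusion counts and accuracies), `pooled` (one-row metric
#'   tibble), `metrics_mean` (metrics averaged over folds), `n_dropped`,
#'   and the configuration.
#' @export
run_pipeline <- function(features, hidden = 60L, k = 5L, seed = 1L,
                         positive = "NSR") {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  if (k < 2) stop_invalid("k must be at least 2")
  n_dropped <- 0L
  if ("ok" %in% names(features)) {
    n_dropped <- sum(!features$ok)
    features <- dplyr::filter(features, .data$ok)
  }
  labels <- factor(features$label)
  if (nlevels(labels) < 2) stop_invalid("need both classes present")
  if (min(table(labels)) < k) {
    stop_invalid("need at least k segments per class")
  }
  feat_cols <- setdiff(names(features), c("segment_id", "label", "ok"))
  X <- as_feature_matrix(features[feat_cols])
  folds <- kfold_split(as.character(labels), k = k, seed = seed)
  per_fold <- purrr::map_dfr(seq_along(folds), function(f) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    if (length(unique(labels[tr])) < 2) {
      rlang::abort("stratification failure: a training fold lost a class")
    }
    model <- elm_train(X[tr, , drop = FALSE], labels[tr], hidden = hidden,
                       seed = seed + f)
    pred <- predict(model, X[te, , drop = FALSE])
    cm <- confusion_counts(labels[te], pred, positive)
    cm$fold <- f
    cm$acc <- round_half_up(100 * (cm$tp + cm$tn) / length(te))
    cm
  })
  pooled <- evaluate_confusion(sum(per_fold$tp), sum(per_fold$tn),
                               sum(per_fold$fp), sum(per_fold$fn))
  fold_metrics <- purrr::map_dfr(seq_len(nrow(per_fold)), function(i) {
    evaluate_confusion(per_fold$tp[i], per_fold$tn[i], per_fold$fp[i],
                       per_fold$fn[i])
  })
  metrics_mean <- dplyr::summarise(
    fold_metrics,
    dplyr::across(c("acc", "ppv", "sen", "spe", "f1"),
                  ~ round_half_up(mean(.x, na.rm = TRUE)))
  )
  structure(
    list(per_fold = per_fold, pooled = pooled, metrics_mean = metrics_mean,
         n_dropped = n_dropped,
         config = list(hidden = hidden, k = k, seed = seed,
                       positive = positive, features = feat_cols)),
    class = "mf_eval"
  )
}

#' @export
print.mf_eval <- function(x, ...) {
  cat("<mf_eval>", x$config$k, "-fold | hidden =", x$config$hidden,
      "| positive =", x$config$positive, "\n")
  cat("pooled:\n")
  print(x$pooled)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `mf_eval` report (for `tidy`/`glance`).
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mf_eval <- function(x, ...) x$per_fold

#' @rdname run_pipeline
#' @exportS3Method generics::glance
glance.mf_eval <- function(x, ...) {
  dplyr::bind_cols(x$pooled,
                   tibble::tibble(k = x$config$k,
                                  hidden = x$config$hidden,
                                  n_dropped = x$n_dropped))
}

#' @exportS3Method ggplot2::autoplot
autoplot.mf_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(x = factor(.data$fold), y = .data$acc)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(90, 100)) +
    ggplot2::labs(x = "fold", y = "accuracy (%)",
                  title = "Per-fold accuracy")
}

#' Compare ELM with standard SVM and KNN classifiers
#'
#' Feeds the identical stratified folds to the native ELM, a radial
#' support vector machine (`e1071`, `gamma = 0.05`) and k-nearest
#' neighbors (`class`, `K = round(sqrt(training size))`). Missing
#' optional dependencies skip the corresponding rows with a message.
#'
#' @inheritParams run_pipeline
#' @param gamma RBF kernel width for the SVM (default 0.05).
#' @return A tibble with one row per algorithm: per-fold accuracies and
#'   the pooled overall accuracy `oa`.
#' @export
compare_classifiers <- function(features, hidden = 60L, k = 5L, seed = 1L,
                                positive = "NSR", gamma = 0.05) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  if ("ok" %in% names(features)) features <- dplyr::filter(features, .data$ok)
  labels <- factor(features$label)
  feat_cols <- setdiff(names(features), c("segment_id", "label", "ok"))
  X <- as_feature_matrix(features[feat_cols])
  Xs <- scale(X)
  folds <- kfold_split(as.character(labels), k = k, seed = seed)
  run_algo <- function(name, fit_predict) {
    acc <- numeric(k)
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- folds[[f]]$train
      te <- folds[[f]]$test
      pred <- fit_predict(tr, te, f)
      acc[f] <- round_half_up(100 * mean(pred == labels[te]))
      correct <- correct + sum(pred == labels[te])
    }
    out <- tibble::as_tibble(stats::setNames(as.list(acc),
                                             paste0("fold", seq_len(k))))
    dplyr::bind_cols(tibble::tibble(algorithm = name), out,
                     tibble::tibble(oa = round_half_up(100 * correct /
                                                         length(labels))))
  }
  rows <- list(
    run_algo("ELM", function(tr, te, f) {
      model <- elm_train(X[tr, , drop = FALSE], labels[tr], hidden = hidden,
                         seed = seed + f)
      predict(model, X[te, , drop = FALSE])
    })
  )
  if (requireNamespace("e1071", quietly = TRUE)) {
    rows <- c(rows, list(run_algo("SVM", function(tr, te, f) {
      fit <- e1071::svm(x = Xs[tr, , drop = FALSE], y = labels[tr],
                        kernel = "radial", gamma = gamma)
      predict(fit, Xs[te, , drop = FALSE])
    })))
  } else {
    message("e1071 not installed; SVM comparison skipped")
  }
  if (requireNamespace("class", quietly = TRUE)) {
    rows <- c(rows, list(run_algo("KNN", function(tr, te, f) {
      class::knn(Xs[tr, , drop = FALSE], Xs[te, , drop = FALSE],
                 labels[tr], k = round(sqrt(length(tr))))
    })))
  } else {
    message("class not installed; KNN comparison skipped")
  }
  dplyr::bind_rows(rows)
}
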