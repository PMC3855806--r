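# Linear SVM training and evaluation: recall/precision from confusion
# counts, repeated stratified cross-validation with per-fold
# standardization, and the step-wise recall-precision AUC.

.check_counts <- function(counts) {
  counts <- as.list(counts)
  for (k in c("tp", "fp", "fn", "tn")) {
    if (is.null(counts[[k]])) counts[[k]] <- 0
    if (counts[[k]] < 0) stop("negative confusion counts", call. = FALSE)
  }
  counts
}

#' Recall from confusion counts
#'
#' `TP / (TP + FN)`; defined as 0 (with a warning) when no positives were
#' evaluated.
#'
#' @param counts Named list or vector with elements `tp`, `fp`, `fn`, `tn`.
#' @return Recall in `[0, 1]`.
#' @export
recall <- function(counts) {
  counts <- .check_counts(counts)
  denom <- counts$tp + counts$fn
  if (denom == 0) {
    warning("no positive samples evaluated; recall defined as 0", call. = FALSE)
    return(0)
  }
  counts$tp / denom
}

#' Precision from confusion counts
#'
#' `TP / (TP + FP)`; defined as 0 (with a warning) when nothing was predicted
#' positive.
#'
#' @inheritParams recall
#' @return Precision in `[0, 1]`.
#' @export
precision <- function(counts) {
  counts <- .check_counts(counts)
  denom <- counts$tp + counts$fp
  if (denom == 0) {
    warning("no positive predictions; precision defined as 0", call. = FALSE)
    return(0)
  }
  counts$tp / denom
}

#' Train a linear soft-margin SVM
#'
#' Features are standardized (training statistics stored in the model) and a
#' linear SVM with cost `C` is fitted. The returned model exposes the
#' primal weight vector and bias oriented so that a higher decision value
#' `x . w + b` means the positive (+1) class.
#'
#' @inheritParams permutation_pvalues
#' @param cost Soft-margin cost C (default 1).
#' @return An object of class `svm_linear` with elements `weights`, `bias`,
#'   `center`, `scale`.
#' @export
train_svm <- function(X, y, cost = 1) {
  Xm <- as_feature_matrix(X)
  if (length(unique(y)) != 2) stop("need two classes to train", call. = FALSE)
  ctr <- colMeans(Xm)
  scl <- apply(Xm, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(Xm, center = ctr, scale = scl)
  fit <- .fit_linear_svm(Xs, y, cost)
  structure(list(weights = setNames(fit$weights, colnames(Xm)),
                 bias = fit$bias, center = ctr, scale = scl, cost = cost),
            class = "svm_linear")
}

#' Decision values of a linear SVM model
#'
#' @param object An `svm_linear` model.
#' @param X Feature tibble or matrix with the model's feature columns.
#' @return Numeric decision values; positive means predicted +1.
#' @export
decision_values <- function(object, X) {
  Xm <- as_feature_matrix(X)
  Xm <- Xm[, names(object$weights), drop = FALSE]
  Xs <- scale(Xm, center = object$center, scale = object$scale)
  drop(Xs %*% object$weights) + object$bias
}

#' @export
predict.svm_linear <- function(object, newdata, ...) {
  ifelse(decision_values(object, newdata) >= 0, 1, -1)
}

#' @export
print.svm_linear <- function(x, ...) {
  cat(sprintf("Linear SVM (C = %g) on %d features\n",
              x$cost, length(x$weights)))
  invisible(x)
}

.stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified cross-validation of the linear SVM
#'
#' Stratified folds are redrawn each repeat from a seeded generator. Within
#' each fold, features are standardized using training-fold statistics only,
#' a linear SVM is trained, and held-out predictions are pooled into
#' per-repeat confusion counts from which recall and precision are computed
#' (micro-averaged); grand means are taken over repeats. Held-out decision
#' values from the first repeat provide the recall-precision curve and its
#' AUC.
#'
#' @inheritParams permutation_pvalues
#' @param folds Number of folds (default 10); every class must have at least
#'   `folds` members.
#' @param repeats Number of random re-partitions (default 100).
#' @param cost SVM cost.
#' @param compute_curve Keep decision scores and compute the PR curve/AUC
#'   (default `TRUE`).
#' @return An object of class `cv_metrics` with grand-mean `recall` and
#'   `precision`, a `per_repeat` tibble, and (if requested) `pr_curve` and
#'   `pr_auc`.
#' @export
cross_validate <- function(X, y, folds = 10, repeats = 100, seed = 1,
                           cost = 1, compute_curve = TRUE) {
  Xm <- as_feature_matrix(X)
  if (any(table(y) < folds)) {
    stop("every class needs at least as many samples as folds", call. = FALSE)
  }
  per_repeat <- vector("list", repeats)
  scores1 <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_of <- .stratified_folds(y, folds)
      cts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
      scores <- numeric(length(y))
      for (f in seq_len(folds)) {
        tr <- fold_of != f
        ctr <- colMeans(Xm[tr, , drop = FALSE])
        scl <- apply(Xm[tr, , drop = FALSE], 2, sd)
        scl[scl == 0] <- 1
        Xtr <- scale(Xm[tr, , drop = FALSE], ctr, scl)
        Xte <- scale(Xm[!tr, , drop = FALSE], ctr, scl)
        fit <- .fit_linear_svm(Xtr, y[tr], cost)
        dv <- drop(Xte %*% fit$weights) + fit$bias
        pred <- ifelse(dv >= 0, 1, -1)
        truth <- y[!tr]
        cts["tp"] <- cts["tp"] + sum(pred == 1 & truth == 1)
        cts["fp"] <- cts["fp"] + sum(pred == 1 & truth == -1)
        cts["fn"] <- cts["fn"] + sum(pred == -1 & truth == 1)
        cts["tn"] <- cts["tn"] + sum(pred == -1 & truth == -1)
        scores[!tr] <- dv
      }
      per_repeat[[r]] <- tibble::tibble(
        repeat_id = r,
        recall = recall(as.list(cts)),
        precision = precision(as.list(cts)),
        tp = cts[["tp"]], fp = cts[["fp"]],
        fn = cts[["fn"]], tn = cts[["tn"]])
      if (r == 1) scores1 <- scores
    }
  })
  per_repeat <- dplyr::bind_rows(per_repeat)
  out <- list(recall = mean(per_repeat$recall),
              precision = mean(per_repeat$precision),
              per_repeat = per_repeat,
              folds = folds, repeats = repeats, seed = seed)
  if (compute_curve) {
    out$pr_curve <- pr_curve(scores1, y)
    out$pr_auc <- pr_auc(scores1, y)
  }
  structure(out, class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d repeats: recall %.4f, precision %.4f",
              x$folds, x$repeats, x$recall, x$precision))
  if (!is.null(x$pr_auc)) cat(sprintf(", PR-AUC %.4f", x$pr_auc))
  cat("\n")
  invisible(x)
}

#' Recall-precision curve
#'
#' Sweeps every distinct decision score as a threshold (descending); at each
#' threshold samples with score at or above it are called positive.
#'
#' @param scores Finite decision scores, higher meaning more positive.
#' @param labels Vector of +1/-1 labels with both classes present.
#' @return Tibble with columns `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(unique(labels)) != 2) {
    stop("both classes must be present", call. = FALSE)
  }
  pos <- labels == 1
  thr <- sort(unique(scores), decreasing = TRUE)
  stats <- purrr::map(thr, function(t) {
    called <- scores >= t
    c(recall = sum(called & pos) / sum(pos),
      precision = sum(called & pos) / sum(called))
  })
  tibble::tibble(threshold = thr,
                 recall = purrr::map_dbl(stats, "recall"),
                 precision = purrr::map_dbl(stats, "precision"))
}

#' Area under the recall-precision curve
#'
#' Step-wise (right-continuous) summation
#' `sum_k (recall_k - recall_{k-1}) * precision_k` over descending score
#' thresholds, with recall_0 = 0. Step interpolation avoids the optimism of
#' linear interpolation in PR space.
#'
#' @inheritParams pr_curve
#' @return AUC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  curve <- pr_curve(scores, labels)
  r <- curve$recall
  sum((r - c(0, head(r, -1))) * curve$precision)
}
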