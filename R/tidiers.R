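# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a feature-selection result
#'
#' @param x A `selection_result` from [select_features()].
#' @param ... Unused.
#' @return Per-feature tibble: `feature`, `statistic`, `p_value`, `q_value`,
#'   `elim_rank`, `selected`.
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) x$table

#' @rdname tidy.selection_result
#' @return For `glance`: one-row tibble of the global summaries.
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$table), pi0 = x$pi0,
                 q_cutoff = x$q_cutoff, n_survivors = x$n_survivors,
                 n_selected = x$n_selected,
                 full_recall = x$full_recall,
                 full_precision = x$full_precision,
                 selected_recall = x$selected_recall,
                 selected_precision = x$selected_precision)
}

#' Tidy cross-validation metrics
#'
#' @param x A `cv_metrics` object from [cross_validate()].
#' @param ... Unused.
#' @return Per-repeat tibble of pooled confusion counts and metrics.
#' @method tidy cv_metrics
#' @export
tidy.cv_metrics <- function(x, ...) x$per_repeat

#' @rdname tidy.cv_metrics
#' @method glance cv_metrics
#' @export
glance.cv_metrics <- function(x, ...) {
  tibble::tibble(recall = x$recall, precision = x$precision,
                 pr_auc = if (is.null(x$pr_auc)) NA_real_ else x$pr_auc,
                 folds = x$folds, repeats = x$repeats)
}

#' Tidy a linear SVM model
#'
#' @param x An `svm_linear` model from [train_svm()].
#' @param ... Unused.
#' @return Tibble of model terms (features and bias) and weights.
#' @method tidy svm_linear
#' @export
tidy.svm_linear <- function(x, ...) {
  tibble::tibble(term = c(names(x$weights), "(bias)"),
                 estimate = c(unname(x$weights), x$bias))
}

#' @rdname tidy.svm_linear
#' @method glance svm_linear
#' @export
glance.svm_linear <- function(x, ...) {
  tibble::tibble(n_features = length(x$weights), cost = x$cost)
}
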