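# Downstream biomarker integration: paired fold-change differential
# expression, hypergeometric overlap statistics and candidate intersection.

.split_expression <- function(expr) {
  stopifnot(is.data.frame(expr))
  case_cols <- grep("^case", names(expr), value = TRUE)
  ctrl_cols <- grep("^control", names(expr), value = TRUE)
  if (length(case_cols) == 0 || length(case_cols) != length(ctrl_cols)) {
    stop("expression table needs equal numbers of case_* and control_* columns",
         call. = FALSE)
  }
  id_col <- setdiff(names(expr), c(case_cols, ctrl_cols))[1]
  list(gene_id = expr[[id_col]],
       case = as.matrix(expr[, case_cols, drop = FALSE]),
       control = as.matrix(expr[, ctrl_cols, drop = FALSE]))
}

#' Paired expression fold changes
#'
#' For each gene, the ratio of total case expression to total control
#' expression over the m sample pairs (`ratio_of_sums`, the default, equal to
#' the ratio of means and robust to single near-zero control values), or the
#' mean of per-pair ratios (`mean_of_ratios`). Values above 1 indicate
#' up-regulation in cases, below 1 down-regulation.
#'
#' @param expr Expression tibble: a gene id column, then `case_*` and
#'   `control_*` columns pairing by position; values linear-scale and
#'   positive.
#' @param method `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @return Tibble with columns `gene_id`, `fold_change`.
#' @export
fold_change <- function(expr, method = c("ratio_of_sums", "mean_of_ratios")) {
  method <- match.arg(method)
  parts <- .split_expression(expr)
  if (any(parts$control <= 0)) {
    stop("control expression values must be positive", call. = FALSE)
  }
  fc <- if (method == "ratio_of_sums") {
    rowSums(parts$case) / rowSums(parts$control)
  } else {
    rowMeans(parts$case / parts$control)
  }
  tibble::tibble(gene_id = parts$gene_id, fold_change = unname(fc))
}

#' Paired t-test per gene
#'
#' Two-sided paired t-test on the per-pair differences (case - control) with
#' m - 1 degrees of freedom. Degenerate genes whose differences have zero
#' variance get p = 1 when every difference is 0, and the smallest
#' representable positive double when the differences are a constant shift
#' (an exact effect that a t statistic cannot scale).
#'
#' @inheritParams fold_change
#' @return Tibble with columns `gene_id`, `statistic`, `p_value`.
#' @export
paired_ttest <- function(expr) {
  parts <- .split_expression(expr)
  m <- ncol(parts$case)
  if (m < 2) stop("paired t-test needs at least 2 sample pairs", call. = FALSE)
  d <- parts$case - parts$control
  mu <- rowMeans(d)
  s <- sqrt(rowSums((d - mu)^2) / (m - 1))
  t_stat <- mu / (s / sqrt(m))
  p <- 2 * pt(-abs(t_stat), df = m - 1)
  zero_var <- s == 0
  p[zero_var & mu == 0] <- 1
  p[zero_var & mu != 0] <- .Machine$double.xmin
  t_stat[zero_var] <- ifelse(mu[zero_var] == 0, 0,
                             sign(mu[zero_var]) * Inf)
  tibble::tibble(gene_id = parts$gene_id, statistic = unname(t_stat),
                 p_value = unname(p))
}

#' Select differentially expressed genes
#'
#' A gene is kept iff its fold change is at least `fc_threshold` (inclusive)
#' or at most `1/fc_threshold`, and its p-value is below `p_threshold`.
#'
#' @param fc Tibble from [fold_change()] (or a numeric vector).
#' @param pvals Tibble from [paired_ttest()] (or a numeric vector aligned
#'   with `fc`).
#' @param fc_threshold Fold-change cutoff (default 1.5; the down-regulation
#'   cutoff is its reciprocal).
#' @param p_threshold p-value cutoff (default 0.05).
#' @return Character vector of selected gene ids (indices if no ids given).
#' @export
select_deg <- function(fc, pvals, fc_threshold = 1.5, p_threshold = 0.05) {
  if (is.data.frame(fc)) {
    ids <- fc$gene_id
    fcv <- fc$fold_change
  } else {
    ids <- as.character(seq_along(fc))
    fcv <- fc
  }
  pv <- if (is.data.frame(pvals)) {
    pvals$p_value[match(ids, pvals$gene_id)]
  } else {
    pvals
  }
  keep <- (fcv >= fc_threshold | fcv <= 1 / fc_threshold) & pv < p_threshold
  ids[keep]
}

#' Full differential-expression table
#'
#' Convenience wrapper combining [fold_change()], [paired_ttest()] and the
#' [select_deg()] rule into one tibble.
#'
#' @inheritParams fold_change
#' @inheritParams select_deg
#' @return Tibble with `gene_id`, `fold_change`, `statistic`, `p_value`,
#'   `de` (logical).
#' @export
differential_expression <- function(expr, fc_threshold = 1.5,
                                    p_threshold = 0.05,
                                    method = c("ratio_of_sums",
                                               "mean_of_ratios")) {
  fc <- fold_change(expr, method = method)
  tt <- paired_ttest(expr)
  out <- dplyr::left_join(fc, tt, by = "gene_id")
  out$de <- out$gene_id %in% select_deg(fc, tt, fc_threshold, p_threshold)
  out
}

.check_query <- function(N, S, n, s) {
  vals <- c(N = N, S = S, n = n, s = s)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("N, S, n, s must be non-negative integers", call. = FALSE)
  }
  if (S > N || n > N) stop("S and n cannot exceed N", call. = FALSE)
  if (s > min(S, n)) stop("s cannot exceed min(S, n)", call. = FALSE)
}

#' Hypergeometric point probability
#'
#' Probability of drawing exactly `s` marked items in `n` draws without
#' replacement from a population of `N` items of which `S` are marked:
#' `C(S,s) C(N-S,n-s) / C(N,n)`, evaluated in log space via log-gamma so it
#' is exact to at least 10 significant digits for populations up to 1e6.
#'
#' @param N Population size.
#' @param S Number of marked items in the population.
#' @param n Number of draws.
#' @param s Number of marked items drawn.
#' @return The point probability.
#' @export
hypergeom_pmf <- function(N, S, n, s) {
  .check_query(N, S, n, s)
  if (n - s > N - S) return(0)
  exp(lchoose(S, s) + lchoose(N - S, n - s) - lchoose(N, n))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= s)`, the probability of an overlap at least as large as observed,
#' summed from the point probabilities in log space.
#'
#' @inheritParams hypergeom_pmf
#' @return The tail probability.
#' @export
hypergeom_tail <- function(N, S, n, s) {
  .check_query(N, S, n, s)
  ks <- s:min(S, n)
  lp <- lchoose(S, ks) + lchoose(N - S, n - ks) - lchoose(N, n)
  lp <- lp[is.finite(lp)]  # impossible terms (n - k > N - S) contribute 0
  if (length(lp) == 0) return(0)
  mx <- max(lp)
  exp(mx) * sum(exp(lp - mx))
}

#' Intersect biomarker evidence streams
#'
#' Final candidate list: genes differentially expressed in the disease
#' tissue, predicted blood-secretory, and predicted movable from blood to
#' saliva. Candidates are ordered by their manifold rank when a ranking is
#' supplied, otherwise by id.
#'
#' @param deg_ids,blood_secretory_ids,saliva_predicted_ids Character id
#'   vectors.
#' @param ranking Optional `ranking_result` from [manifold_rank()].
#' @return Tibble with columns `id` and `rank` (NA when unranked).
#' @export
intersect_candidates <- function(deg_ids, blood_secretory_ids,
                                 saliva_predicted_ids, ranking = NULL) {
  ids <- intersect(intersect(deg_ids, blood_secretory_ids),
                   saliva_predicted_ids)
  rk <- rep(NA_integer_, length(ids))
  if (!is.null(ranking)) {
    rk <- ranking$rank[match(ids, ranking$id)]
  }
  out <- tibble::tibble(id = ids, rank = rk)
  out[order(is.na(out$rank), out$rank, out$id), ]
}
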