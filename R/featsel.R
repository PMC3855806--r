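# Two-stage feature selection: a label-permutation test with Storey
# q-values removes irrelevant feature elements, then SVM recursive feature
# elimination with correlation-group collapsing removes redundant ones.

#' Convert a feature tibble to a numeric matrix
#'
#' Drops the `id` column (using it for row names) and returns the numeric
#' feature matrix the statistical internals operate on.
#'
#' @param X Feature tibble (as produced by [featurize()]) or numeric matrix.
#' @return Numeric matrix, samples in rows.
#' @export
as_feature_matrix <- function(X) {
  if (is.matrix(X)) return(X)
  stopifnot(is.data.frame(X))
  keep <- names(X) != "id"
  m <- as.matrix(X[, keep, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- if ("id" %in% names(X)) X$id else NULL
  m
}

# Welch |t| for every column given a class-1 indicator; NaN (constant
# feature) is the caller's degenerate case.
.welch_t_rows <- function(ind, S, Q, X, X2, n) {
  n1 <- rowSums(ind)
  n2 <- n - n1
  S1 <- ind %*% X
  Q1 <- ind %*% X2
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2, S, "+") / n2
  v1 <- pmax(sweep(Q1 - S1^2 / n1, 1, n1 - 1, "/"), 0)
  v2 <- pmax(sweep(sweep(-Q1, 2, Q, "+") - (sweep(-S1, 2, S, "+"))^2 / n2,
                   1, n2 - 1, "/"), 0)
  abs((m1 - m2) / sqrt(v1 / n1 + v2 / n2))
}

#' Permutation p-values for per-feature class relevance
#'
#' The per-feature statistic is the absolute Welch t between the two classes.
#' The null is generated by shuffling the labels jointly for all features;
#' the p-value uses the add-one estimator
#' `p = (1 + #permuted |t| >= observed |t|) / (1 + n_perm)`, so p is never
#' exactly 0 and the q-value machinery downstream stays well defined.
#' Features constant across all samples get p = 1.
#'
#' @param X Feature tibble (id column allowed) or numeric matrix, samples in
#'   rows.
#' @param y Label vector with exactly two classes (+1/-1).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return Numeric vector of p-values, one per feature column, with the
#'   observed statistics in attribute `"statistic"`.
#' @export
permutation_pvalues <- function(X, y, n_perm = 10000, seed = 1) {
  Xm <- as_feature_matrix(X)
  if (length(unique(y)) != 2) stop("y must contain exactly two classes", call. = FALSE)
  stopifnot(n_perm >= 1)
  n <- nrow(Xm)
  pos <- y == max(y)
  X2 <- Xm^2
  S <- colSums(Xm)
  Q <- colSums(X2)
  obs <- .welch_t_rows(matrix(as.numeric(pos), 1, n), S, Q, Xm, X2, n)[1, ]
  degenerate <- is.nan(obs)
  exceed <- numeric(ncol(Xm))
  withr::with_seed(seed, {
    block <- 1000L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      ind <- matrix(0, b, n)
      for (r in seq_len(b)) ind[r, sample.int(n)[seq_len(sum(pos))]] <- 1
      Tb <- .welch_t_rows(ind, S, Q, Xm, X2, n)
      Tb[is.nan(Tb)] <- 0
      cmp <- Tb >= matrix(obs, b, ncol(Xm), byrow = TRUE)
      exceed <- exceed + colSums(cmp)
      done <- done + b
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  p[degenerate] <- 1
  names(p) <- colnames(Xm)
  attr(p, "statistic") <- obs
  p
}

#' Storey q-values
#'
#' Storey-Tibshirani q-values with the proportion of true nulls estimated at
#' a fixed lambda of 0.5: `pi0 = min(1, #{p > 0.5} / (0.5 m))`, then
#' `q(p_(i)) = min_{j >= i} pi0 * m * p_(j) / j` over the ascending-sorted
#' p-values, capped at 1 and mapped back to input order.
#'
#' @param pvals Vector of p-values in `(0, 1]`.
#' @return Vector of q-values, same length and order; the `pi0` estimate is
#'   attached as an attribute.
#' @export
qvalues <- function(pvals) {
  p <- as.numeric(pvals)
  if (any(p <= 0 | p > 1 | is.na(p))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  lambda <- 0.5
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  ord <- order(p)
  raw <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(raw))))
  q <- numeric(m)
  q[ord] <- q_sorted
  names(q) <- names(pvals)
  attr(q, "pi0") <- pi0
  q
}

# Greedy correlation grouping: columns whose absolute correlation with a
# group's representative exceeds the threshold join that group.
.correlation_groups <- function(Xm, threshold) {
  mcols <- ncol(Xm)
  sds <- apply(Xm, 2, sd)
  groups <- list()
  reps <- integer(0)
  for (j in seq_len(mcols)) {
    placed <- FALSE
    if (length(reps) > 0) {
      for (g in seq_along(reps)) {
        r <- reps[g]
        cr <- if (sds[j] == 0 || sds[r] == 0) {
          as.numeric(sds[j] == 0 && sds[r] == 0)
        } else {
          cor(Xm[, j], Xm[, r])
        }
        if (abs(cr) > threshold) {
          groups[[g]] <- c(groups[[g]], j)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- j
      reps <- c(reps, j)
    }
  }
  list(groups = groups, reps = reps)
}

.fit_linear_svm <- function(Xm, y, cost = 1) {
  fy <- factor(y, levels = sort(unique(y)))
  fit <- e1071::svm(Xm, fy, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm decision values are oriented toward its first internal label;
  # reorient so that higher x.w + b always means the larger class label
  pred <- predict(fit, Xm, decision.values = TRUE)
  first <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1]][1]
  if (first != as.character(max(y))) {
    w <- -w
    b <- -b
  }
  list(weights = w, bias = b, fit = fit)
}

#' SVM recursive feature elimination
#'
#' Iteratively trains a linear soft-margin SVM (C = 1) on the standardized
#' features, scores features by squared weight and eliminates the weakest
#' `ceiling(step_fraction x remaining)` (at least 1) per iteration. Before
#' ranking, features with pairwise absolute correlation above `cor_threshold`
#' are collapsed to one representative and eliminated or retained as a group,
#' so statistically dependent feature elements share one elimination rank.
#'
#' @inheritParams permutation_pvalues
#' @param step_fraction Fraction of remaining feature groups removed per
#'   iteration (default 0.1).
#' @param cor_threshold Absolute-correlation threshold for group collapsing
#'   (default 0.98).
#' @param cost SVM cost parameter.
#' @param seed Unused randomness guard; the procedure is deterministic but
#'   the argument keeps call sites uniform.
#' @return Tibble with columns `feature`, `group`, `elim_rank` (1 =
#'   eliminated first; the last surviving group has the highest rank), in
#'   input column order. The grouping and the group elimination order are
#'   attached as attributes.
#' @export
svm_rfe <- function(X, y, step_fraction = 0.1, cor_threshold = 0.98,
                    cost = 1, seed = 1) {
  Xm <- as_feature_matrix(X)
  if (ncol(Xm) < 2) stop("need at least two features", call. = FALSE)
  if (length(unique(y)) != 2) stop("labels must be binary", call. = FALSE)
  ctr <- colMeans(Xm)
  scl <- apply(Xm, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(Xm, center = ctr, scale = scl)
  grp <- .correlation_groups(Xs, cor_threshold)
  n_groups <- length(grp$groups)
  remaining <- seq_len(n_groups)
  elim_order <- integer(0)
  while (length(remaining) > 1) {
    fitted <- .fit_linear_svm(Xs[, grp$reps[remaining], drop = FALSE], y, cost)
    score <- fitted$weights^2
    k <- max(1L, ceiling(step_fraction * length(remaining)))
    k <- min(k, length(remaining) - 1L)
    drop_idx <- order(score, seq_along(score))[seq_len(k)]
    elim_order <- c(elim_order, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  elim_order <- c(elim_order, remaining)
  group_rank <- integer(n_groups)
  group_rank[elim_order] <- seq_len(n_groups)
  feat_group <- integer(ncol(Xm))
  for (g in seq_len(n_groups)) feat_group[grp$groups[[g]]] <- g
  out <- tibble::tibble(feature = colnames(Xm),
                        group = feat_group,
                        elim_rank = group_rank[feat_group])
  attr(out, "groups") <- grp$groups
  attr(out, "elimination_order") <- elim_order
  out
}

#' Two-stage feature selection
#'
#' Stage 1 keeps features whose Storey q-value from the label-permutation
#' test is below `q_cutoff`. Stage 2 ranks the survivors by [svm_rfe()] and
#' picks the smallest nested subset (walking the elimination order from the
#' most important group outward) whose mean cross-validated recall and
#' precision are each within `perf_tolerance` of the full survivor set's
#' performance.
#'
#' @inheritParams permutation_pvalues
#' @inheritParams svm_rfe
#' @param q_cutoff Storey q-value cutoff for stage 1 (default 0.005).
#' @param perf_tolerance Maximum absolute drop in CV recall and precision the
#'   reduced subset may incur (default 0.01).
#' @param cv_folds Folds for the stage-2 cross-validation (default 10).
#' @param n_perm Permutations for stage 1.
#' @return An object of class `selection_result`; see [tidy.selection_result()].
#' @export
select_features <- function(X, y, q_cutoff = 0.005, perf_tolerance = 0.01,
                            cv_folds = 10, n_perm = 10000,
                            step_fraction = 0.1, cor_threshold = 0.98,
                            cost = 1, seed = 1) {
  Xm <- as_feature_matrix(X)
  p <- permutation_pvalues(Xm, y, n_perm = n_perm, seed = seed)
  q <- qvalues(p)
  survivors <- which(q < q_cutoff)
  if (length(survivors) == 0) {
    stop("no features pass the q-value cutoff; consider a larger q_cutoff",
         call. = FALSE)
  }
  rfe <- svm_rfe(Xm[, survivors, drop = FALSE], y,
                 step_fraction = step_fraction,
                 cor_threshold = cor_threshold, cost = cost, seed = seed)
  elim_order <- attr(rfe, "elimination_order")
  groups <- attr(rfe, "groups")
  n_groups <- length(groups)
  cv_eval <- function(cols) {
    m <- cross_validate(Xm[, cols, drop = FALSE], y, folds = cv_folds,
                        repeats = 1, seed = seed + 1L, cost = cost,
                        compute_curve = FALSE)
    c(recall = m$recall, precision = m$precision)
  }
  base <- cv_eval(survivors)
  chosen <- survivors
  chosen_perf <- base
  for (j in seq_len(n_groups)) {
    top_groups <- elim_order[seq(n_groups - j + 1L, n_groups)]
    cols <- survivors[sort(unlist(groups[top_groups]))]
    perf <- cv_eval(cols)
    if (perf["recall"] >= base["recall"] - perf_tolerance &&
        perf["precision"] >= base["precision"] - perf_tolerance) {
      chosen <- cols
      chosen_perf <- perf
      break
    }
  }
  tab <- tibble::tibble(
    feature = colnames(Xm),
    statistic = unname(attr(p, "statistic")),
    p_value = unname(p),
    q_value = unname(as.numeric(q)),
    elim_rank = NA_integer_,
    selected = FALSE)
  tab$elim_rank[survivors] <- rfe$elim_rank
  tab$selected[chosen] <- TRUE
  structure(list(
    table = tab,
    pi0 = attr(q, "pi0"),
    q_cutoff = q_cutoff,
    n_survivors = length(survivors),
    n_selected = length(chosen),
    full_recall = unname(base["recall"]),
    full_precision = unname(base["precision"]),
    selected_recall = unname(chosen_perf["recall"]),
    selected_precision = unname(chosen_perf["precision"]),
    seed = seed),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Two-stage feature selection\n")
  cat(sprintf("  features: %d, q < %g survivors: %d, selected: %d (pi0 = %.3f)\n",
              nrow(x$table), x$q_cutoff, x$n_survivors, x$n_selected, x$pi0))
  cat(sprintf("  CV recall %.3f -> %.3f, precision %.3f -> %.3f\n",
              x$full_recall, x$selected_recall,
              x$full_precision, x$selected_precision))
  invisible(x)
}
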