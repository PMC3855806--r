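# Manifold ranking: Gaussian affinity graph over the feature space and
# Zhou-style label propagation from the known positive set to the
# background proteins.

#' Manifold ranking configuration
#'
#' @param alpha Propagation weight in `(0, 1)` (default 0.99): the balance
#'   between neighborhood evidence and the prior labels.
#' @param sigma Gaussian kernel bandwidth, or `"auto"` for the median of the
#'   pairwise Euclidean distances.
#' @param k_neighbors Integer k for a sparse kNN graph, or `"dense"` to keep
#'   the full graph below 2000 nodes and fall back to k = 20 above.
#' @param tolerance Convergence tolerance on the maximum absolute score
#'   change (default 1e-9).
#' @param max_iter Iteration cap (default 10000).
#' @return List of class `ranking_config`.
#' @export
ranking_config <- function(alpha = 0.99, sigma = "auto", k_neighbors = "dense",
                           tolerance = 1e-9, max_iter = 10000) {
  stopifnot(alpha > 0, alpha < 1,
            identical(sigma, "auto") || (is.numeric(sigma) && sigma > 0))
  structure(list(alpha = alpha, sigma = sigma, k_neighbors = k_neighbors,
                 tolerance = tolerance, max_iter = max_iter),
            class = "ranking_config")
}

#' Gaussian affinity matrix over the feature space
#'
#' `W_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))` with zero diagonal. With
#' `sigma = "auto"` the bandwidth is the median pairwise Euclidean distance.
#' A finite `k_neighbors` keeps each node's k largest weights and symmetrizes
#' by the elementwise maximum.
#'
#' @param X Feature tibble (id column used for node names) or matrix;
#'   features should already be standardized.
#' @param config A [ranking_config()].
#' @return Symmetric non-negative matrix with zero diagonal, dimnames set to
#'   the node ids.
#' @export
build_affinity <- function(X, config = ranking_config()) {
  Xm <- as_feature_matrix(X)
  n <- nrow(Xm)
  if (n < 2) stop("need at least two nodes", call. = FALSE)
  d <- as.matrix(dist(Xm))
  sigma <- config$sigma
  if (identical(sigma, "auto")) {
    sigma <- median(d[upper.tri(d)])
    if (sigma == 0) {
      stop("median pairwise distance is 0 (identical rows); supply an explicit sigma",
           call. = FALSE)
    }
  }
  W <- exp(-d^2 / (2 * sigma^2))
  diag(W) <- 0
  k <- config$k_neighbors
  if (identical(k, "dense")) k <- if (n < 2000) Inf else 20
  if (is.finite(k) && k < n - 1) {
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- order(W[i, ], decreasing = TRUE)[seq_len(k)]
      keep[i, nb] <- TRUE
    }
    W[!(keep | t(keep))] <- 0
  }
  rn <- rownames(Xm)
  if (is.null(rn)) rn <- as.character(seq_len(n))
  dimnames(W) <- list(rn, rn)
  W
}

#' @importFrom stats dist

#' Manifold ranking by label propagation
#'
#' Normalizes the affinity matrix as `S = D^-1/2 W D^-1/2` (isolated nodes
#' get a zero row) and iterates `f <- alpha S f + (1 - alpha) y` from
#' `f = y`, where `y` is 1 on the positive set and 0 elsewhere, until the
#' maximum absolute change falls below the tolerance. The fixed point is
#' `(1 - alpha)(I - alpha S)^-1 y`: every positive node propagates its
#' presence through the graph and each node accumulates the evidence
#' reaching it. Background nodes are ranked by decreasing score, ties broken
#' by id; positive nodes drive the propagation but are excluded from the
#' reported ordering.
#'
#' @param W Symmetric non-negative affinity matrix with zero diagonal and
#'   node ids as dimnames.
#' @param positive_ids Character vector of node ids forming the true set.
#' @param config A [ranking_config()].
#' @return An object of class `ranking_result`: tibble with columns `id`,
#'   `score`, `positive`, `rank` (NA for positives), plus convergence info in
#'   attributes.
#' @export
manifold_rank <- function(W, positive_ids, config = ranking_config()) {
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10)) || any(W < 0)) {
    stop("W must be a symmetric non-negative matrix", call. = FALSE)
  }
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  y <- as.numeric(ids %in% positive_ids)
  if (sum(y) == 0) stop("positive set is empty", call. = FALSE)
  deg <- rowSums(W)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  S <- W * tcrossprod(inv_sqrt)
  alpha <- config$alpha
  f <- y
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    f_new <- alpha * drop(S %*% f) + (1 - alpha) * y
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("manifold ranking did not converge in %d iterations (residual %.3g)",
                 config$max_iter, delta), call. = FALSE)
  }
  out <- tibble::tibble(id = ids, score = unname(f), positive = y == 1)
  bg <- out[!out$positive, ]
  bg <- bg[order(-bg$score, bg$id), ]
  out$rank <- NA_integer_
  out$rank[match(bg$id, out$id)] <- seq_len(nrow(bg))
  out <- out[order(!out$positive, out$rank), ]
  structure(out, class = c("ranking_result", class(tibble::tibble())),
            iterations = iter, converged = converged, alpha = alpha)
}

#' Closed-form manifold ranking scores
#'
#' Direct linear solve of `(I - alpha S) f = (1 - alpha) y`, used as the
#' exact counterpart of the iterative propagation on small graphs.
#'
#' @inheritParams manifold_rank
#' @return Numeric score vector named by node id.
#' @export
manifold_rank_direct <- function(W, positive_ids, config = ranking_config()) {
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  y <- as.numeric(ids %in% positive_ids)
  deg <- rowSums(W)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  S <- W * tcrossprod(inv_sqrt)
  f <- solve(diag(nrow(W)) - config$alpha * S, (1 - config$alpha) * y)
  setNames(drop(f), ids)
}

#' Evaluate a ranking against a known protein set
#'
#' Counts how many known proteins fall in the top `top_n` of the background
#' ordering and scores the overlap with the hypergeometric point probability
#' over a population of `population_N` proteins.
#'
#' @param result A `ranking_result` from [manifold_rank()].
#' @param known_ids Character vector of proteins with independent evidence.
#' @param top_n Size of the top list.
#' @param population_N Population size for the enrichment test.
#' @return One-row tibble: `top_n`, `overlap`, `p_value`.
#' @export
evaluate_ranking <- function(result, known_ids, top_n, population_N) {
  bg <- result[!result$positive, ]
  if (top_n > nrow(bg)) stop("top_n exceeds the number of ranked proteins", call. = FALSE)
  top <- bg$id[bg$rank <= top_n]
  s <- length(intersect(known_ids, top))
  p <- hypergeom_pmf(N = population_N, S = length(known_ids), n = top_n, s = s)
  tibble::tibble(top_n = top_n, overlap = s, p_value = p)
}
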