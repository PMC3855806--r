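# Shared fixtures, built in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(L) paste(sample(AA20, L, replace = TRUE), collapse = "")

# Gaussian features with a planted mean shift on the first `n_signal`
# columns; labels balanced +1/-1.
planted_data <- function(n = 200, m = 500, n_signal = 10, effect = 2,
                         seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * m), n, m)
    colnames(X) <- sprintf("f%04d", seq_len(m))
    y <- rep(c(1, -1), length.out = n)
    if (n_signal > 0) {
      X[, seq_len(n_signal)] <- X[, seq_len(n_signal)] + effect * (y == 1)
    }
    list(X = X, y = y)
  })
}

# Small annotated protein tibble for the training-set rules.
toy_pool <- function() {
  tibble::tibble(
    id = sprintf("P%02d", 1:12),
    sequence = c("MKVLYAADDE", "MKVLYAADDK", "ACDEFGHIKL", "YYWWRRHHKK",
                 "LLLLVVVVII", "GGGGSSSSTT", "PPPPGGGGAA", "MMMMFFFFWW",
                 "KKKKRRRRHH", "DDDDEEEENN", "QQQQNNNNSS", "TTTTYYYYVV"),
    family_ids = list("F1", "F1", "F1", "F1", "F2", "F2", "F2", "F3",
                      "F3", "F3", "F4", "F4"),
    saliva_evidence = c(TRUE, rep(FALSE, 11)),
    peptide_count = c(10L, 8L, 7L, 2L, 9L, 9L, 9L, 6L, 6L, 4L, 11L, 11L))
}

# Independent direct-summation autocorrelation oracle (kept deliberately
# naive: explicit loops, no shared code with the implementation).
oracle_autocorr <- function(seq, scale, method, d) {
  aa <- strsplit(seq, "")[[1]]
  P <- as.numeric(scale[aa])
  L <- length(P)
  if (method == "moreau_broto") {
    acc <- 0
    for (i in 1:(L - d)) acc <- acc + P[i] * P[i + d]
    return(acc / (L - d))
  }
  Pbar <- mean(P)
  if (method == "moran") {
    num <- 0
    for (i in 1:(L - d)) num <- num + (P[i] - Pbar) * (P[i + d] - Pbar)
    num <- num / (L - d)
    den <- sum((P - Pbar)^2) / L
    if (den == 0) return(0)
    return(num / den)
  }
  num <- 0
  for (i in 1:(L - d)) num <- num + (P[i] - P[i + d])^2
  num <- num / (2 * (L - d))
  den <- sum((P - Pbar)^2) / (L - 1)
  if (den == 0) return(0)
  num / den
}

# Independent brute-force Storey q-values: scan every threshold.
oracle_qvalues <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (t in sort(unique(p[p >= p[i]]))) {
      cand <- min(cand, pi0 * m * t / sum(p <= t))
    }
    q[i] <- min(1, cand)
  }
  q
}

# Independent PR-AUC oracle: enumerate every threshold, step summation.
oracle_pr_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  auc <- 0
  prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & labels == 1)
    rec <- tp / npos
    prec <- tp / sum(called)
    auc <- auc + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  auc
}
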