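# Synthetic fixtures with the statistical structure the pipeline assumes:
# labeled protein sets whose class signal enters only through residue
# composition, family structure for the training-set rules, and paired
# log-scale expression with planted fold changes.

#' Synthetic-data specification
#'
#' Defaults emulate the study conditions the pipeline was designed for:
#' moderate training sets of a few hundred proteins of realistic length,
#' family structure for the expansion/exclusion rules, and a paired
#' case/control expression cohort of 43 pairs with planted 2-fold effects on
#' a log-normal background.
#'
#' @param n_pos,n_neg Positive/negative protein counts (default 100 each).
#' @param length_range Sequence length range, residues (default 80-600).
#' @param pos_bias Named multipliers on the uniform residue sampling weights
#'   for the positive class; the planted class difference. Default boosts
#'   C, G, P and S (cysteine- and Gly/Pro-rich character typical of secreted
#'   proteins) by 1.8.
#' @param neg_bias Multipliers for the negative class (default none).
#' @param n_families Number of protein families per class (default 10).
#' @param n_genes,m_pairs,n_de,true_fc,noise_sd Expression cohort: genes,
#'   sample pairs, planted differential genes (half up at `true_fc`, half
#'   down at its reciprocal), true fold change, log-scale noise sd.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_pos = 100, n_neg = 100, length_range = c(80, 600),
                       pos_bias = c(C = 1.8, G = 1.8, P = 1.8, S = 1.8),
                       neg_bias = NULL,
                       n_families = 10,
                       n_genes = 1000, m_pairs = 43, n_de = 100,
                       true_fc = 2, noise_sd = 0.3) {
  stopifnot(n_pos >= 0, n_neg >= 0, length_range[1] >= 2,
            length_range[2] >= length_range[1],
            n_families >= 1, n_genes >= 1, m_pairs >= 1,
            n_de >= 0, n_de <= n_genes, true_fc > 0, noise_sd >= 0)
  structure(list(n_pos = n_pos, n_neg = n_neg, length_range = length_range,
                 pos_bias = pos_bias, neg_bias = neg_bias,
                 n_families = n_families, n_genes = n_genes,
                 m_pairs = m_pairs, n_de = n_de, true_fc = true_fc,
                 noise_sd = noise_sd),
            class = "synth_spec")
}

.class_weights <- function(bias) {
  w <- setNames(rep(1, 20), AA_ALPHABET)
  if (!is.null(bias)) {
    stopifnot(all(names(bias) %in% AA_ALPHABET), all(bias > 0))
    w[names(bias)] <- w[names(bias)] * bias
  }
  w / sum(w)
}

.random_proteins <- function(n, prefix, fam_prefix, n_families, spec, weights) {
  if (n == 0) {
    return(tibble::tibble(id = character(0), sequence = character(0),
                          family_ids = list(), saliva_evidence = logical(0),
                          peptide_count = integer(0)))
  }
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]), n,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = weights),
          collapse = "")
  }, character(1))
  fams <- sprintf("%s%03d", fam_prefix, rep_len(seq_len(n_families), n))
  tibble::tibble(
    id = sprintf("%s%04d", prefix, seq_len(n)),
    sequence = seqs,
    family_ids = as.list(fams),
    saliva_evidence = rep(prefix == "SP", n),
    peptide_count = stats::rpois(n, 10))
}

#' Generate annotated synthetic protein sequences
#'
#' Residues are drawn independently from a uniform base composition times a
#' per-class bias, lengths uniformly from the configured range. Positives
#' carry saliva evidence and family ids disjoint from the negatives'
#' families, so the training-set rules are exercised realistically.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return Annotated protein tibble with a `label` column (+1/-1).
#' @export
generate_sequences <- function(spec = synth_spec(), seed = 1) {
  withr::with_seed(seed, {
    pos <- .random_proteins(spec$n_pos, "SP", "FP", spec$n_families, spec,
                            .class_weights(spec$pos_bias))
    neg <- .random_proteins(spec$n_neg, "SN", "FN", spec$n_families, spec,
                            .class_weights(spec$neg_bias))
  })
  dplyr::bind_rows(dplyr::mutate(pos, label = 1),
                   dplyr::mutate(neg, label = -1))
}

#' Generate a labeled synthetic feature set
#'
#' Composes [generate_sequences()] and [featurize()]: the planted class
#' signal reaches the features only through the biased residue composition,
#' so descriptor computation, selection and classification are tested end to
#' end with no direct label leakage.
#'
#' @inheritParams generate_sequences
#' @param config A [descriptor_config()].
#' @return List with elements `proteins`, `features` (feature tibble) and
#'   `labels` (+1/-1 vector).
#' @export
generate_labeled_features <- function(spec = synth_spec(), seed = 1,
                                      config = descriptor_config()) {
  proteins <- generate_sequences(spec, seed)
  features <- featurize(proteins[, c("id", "sequence")], config)
  list(proteins = proteins, features = features, labels = proteins$label)
}

#' Generate a paired case/control expression cohort
#'
#' Control values are log-normal (meanlog 7, sdlog 1); case values are the
#' paired control times the gene's true fold change times `exp(noise)` with
#' `noise ~ Normal(0, noise_sd)`. `n_de` genes are planted as differential,
#' half up-regulated at `true_fc` and half down-regulated at its reciprocal;
#' the rest have true fold change 1.
#'
#' @inheritParams generate_sequences
#' @param gene_ids Optional character vector of gene ids (default
#'   `G0001...`); its length overrides `spec$n_genes`.
#' @return List with `expression` (tibble: `gene_id`, `case_*`,
#'   `control_*`) and `truth` (tibble: `gene_id`, `true_fc`, `de`).
#' @export
generate_expression <- function(spec = synth_spec(), seed = 1,
                                gene_ids = NULL) {
  n_genes <- if (is.null(gene_ids)) spec$n_genes else length(gene_ids)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(n_genes))
  m <- spec$m_pairs
  n_de <- min(spec$n_de, n_genes)
  withr::with_seed(seed, {
    true_fc <- rep(1, n_genes)
    if (n_de > 0) {
      de_idx <- sample.int(n_genes, n_de)
      n_up <- ceiling(n_de / 2)
      true_fc[de_idx[seq_len(n_up)]] <- spec$true_fc
      if (n_de > n_up) {
        true_fc[de_idx[(n_up + 1):n_de]] <- 1 / spec$true_fc
      }
    }
    control <- matrix(stats::rlnorm(n_genes * m, meanlog = 7, sdlog = 1),
                      n_genes, m)
    noise <- matrix(stats::rnorm(n_genes * m, 0, spec$noise_sd), n_genes, m)
    case <- control * true_fc * exp(noise)
  })
  mat <- cbind(case, control)
  colnames(mat) <- c(paste0("case_", seq_len(m)), paste0("control_", seq_len(m)))
  expr <- tibble::as_tibble(mat)
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), expr)
  truth <- tibble::tibble(gene_id = gene_ids, true_fc = true_fc,
                          de = true_fc != 1)
  list(expression = expr, truth = truth)
}
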