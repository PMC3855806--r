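# Training-set construction: expand the seed positives within protein
# families at low sequence identity, and draw negatives from families with
# no saliva evidence and solid plasma-proteome support.

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0, gap open -10,
#' gap extend -0.5; identity is the fraction of alignment columns with
#' identical residues, in percent.
#'
#' @param seq_a,seq_b Protein sequences.
#' @return Identity percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) < 1 || nchar(seq_b) < 1) stop("empty sequence", call. = FALSE)
  mat <- diag(1, 20)
  rownames(mat) <- colnames(mat) <- AA_ALPHABET
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5)
  columns <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / columns
}

#' Training-set construction parameters
#'
#' @param max_per_family Additional family members kept per seed family
#'   (default 5).
#' @param max_identity_pct Identity ceiling for positive expansion, percent
#'   (default 30).
#' @param min_peptides Minimum plasma-proteome peptide count for negatives
#'   (default 5).
#' @param negatives_per_family Members kept per clean family (default 5).
#' @return A list of class `trainset_spec`.
#' @export
trainset_spec <- function(max_per_family = 5, max_identity_pct = 30,
                          min_peptides = 5, negatives_per_family = 5) {
  stopifnot(max_per_family > 0, max_identity_pct > 0, max_identity_pct <= 100,
            min_peptides > 0, negatives_per_family > 0)
  structure(list(max_per_family = max_per_family,
                 max_identity_pct = max_identity_pct,
                 min_peptides = min_peptides,
                 negatives_per_family = negatives_per_family),
            class = "trainset_spec")
}

#' Expand a positive seed set within protein families
#'
#' For each family represented among the seeds, pool members of that family
#' whose identity to every seed of the family is below `max_identity_pct` are
#' candidates; the `max_per_family` candidates with the lowest maximum
#' identity to the family's seeds (most distant first, ties by accession) are
#' added. The result is the union of seeds and additions, deduplicated by id.
#'
#' @param seeds,pool Annotated protein tibbles (columns `id`, `sequence`,
#'   `family_ids` list column).
#' @param spec A [trainset_spec()].
#' @return Protein tibble of the expanded positive set.
#' @export
expand_positives <- function(seeds, pool, spec = trainset_spec()) {
  no_fam <- purrr::map_lgl(seeds$family_ids, function(f) length(f) == 0)
  if (any(no_fam)) {
    warning("seed(s) without family annotation kept but not expanded: ",
            paste(seeds$id[no_fam], collapse = ", "), call. = FALSE)
  }
  fams <- sort(unique(unlist(seeds$family_ids)))
  picked <- list()
  for (fam in fams) {
    fam_seeds <- seeds[purrr::map_lgl(seeds$family_ids, function(f) fam %in% f), ]
    cand <- pool[purrr::map_lgl(pool$family_ids, function(f) fam %in% f), ]
    cand <- cand[!cand$id %in% seeds$id, ]
    if (nrow(cand) == 0) next
    max_ident <- purrr::map_dbl(cand$sequence, function(s) {
      max(purrr::map_dbl(fam_seeds$sequence, pairwise_identity, seq_b = s))
    })
    keep <- max_ident < spec$max_identity_pct
    cand <- cand[keep, ]
    if (nrow(cand) == 0) next
    ord <- order(max_ident[keep], cand$id)
    picked[[fam]] <- cand[head(ord, spec$max_per_family), ]
  }
  out <- dplyr::bind_rows(seeds, dplyr::bind_rows(picked))
  dplyr::distinct(out, .data$id, .keep_all = TRUE)
}

#' Select negative training proteins from saliva-free families
#'
#' Drops every family that contains a protein with saliva evidence (by flag or
#' id list); a protein belonging to several families is excluded if any of
#' them is contaminated. Among the remaining families, members with
#' `peptide_count >= min_peptides` are eligible and the first
#' `negatives_per_family` by accession order are kept per family.
#'
#' @param pool Annotated protein tibble (`id`, `sequence`, `family_ids`,
#'   `saliva_evidence`, `peptide_count`).
#' @param saliva_ids Character vector of ids with known saliva evidence.
#' @param spec A [trainset_spec()].
#' @return Protein tibble of selected negatives (possibly empty, with a
#'   warning).
#' @export
select_negatives <- function(pool, saliva_ids = character(0),
                             spec = trainset_spec()) {
  salivary <- pool$saliva_evidence | pool$id %in% saliva_ids
  contaminated <- sort(unique(unlist(pool$family_ids[salivary])))
  clean <- purrr::map_lgl(pool$family_ids, function(f) {
    length(f) > 0 && !any(f %in% contaminated)
  })
  eligible <- pool[clean & !salivary & pool$peptide_count >= spec$min_peptides, ]
  picked <- list()
  fams <- sort(unique(unlist(eligible$family_ids)))
  for (fam in fams) {
    memb <- eligible[purrr::map_lgl(eligible$family_ids,
                                    function(f) fam %in% f), ]
    memb <- memb[order(memb$id), ]
    picked[[fam]] <- head(memb, spec$negatives_per_family)
  }
  out <- dplyr::distinct(dplyr::bind_rows(picked), .data$id, .keep_all = TRUE)
  if (nrow(out) == 0) {
    warning("no eligible negative proteins found", call. = FALSE)
    out <- pool[0, ]
  }
  out
}

#' Build a labeled training set
#'
#' Convenience wrapper: expands positives, selects negatives, asserts the two
#' sets are disjoint and returns a single tibble with a `label` column (+1
#' positives, -1 negatives).
#'
#' @inheritParams expand_positives
#' @inheritParams select_negatives
#' @return Protein tibble with a `label` column.
#' @export
build_trainset <- function(seeds, pool, saliva_ids = character(0),
                           spec = trainset_spec()) {
  pos <- expand_positives(seeds, pool, spec)
  neg <- select_negatives(pool, saliva_ids = unique(c(saliva_ids, pos$id)),
                          spec = spec)
  neg <- neg[!neg$id %in% pos$id, ]
  dplyr::bind_rows(dplyr::mutate(pos, label = 1),
                   dplyr::mutate(neg, label = -1))
}
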