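# Sequence-derived descriptors: composition, autocorrelation over
# physicochemical scales, CTD, physicochemical summaries, disorder,
# secondary-structure content, radius and the twin-arginine motif.

.seq_index <- function(sequence) {
  idx <- match(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) stop("sequence contains non-canonical residues", call. = FALSE)
  idx
}

#' Amino-acid composition
#'
#' @param sequence Protein sequence (canonical 20-letter alphabet).
#' @return Named numeric vector of 20 residue fractions summing to 1.
#' @examples
#' aa_composition("AAC")  # A = 2/3, C = 1/3
#' @export
aa_composition <- function(sequence) {
  if (nchar(sequence) < 1) stop("empty sequence", call. = FALSE)
  idx <- .seq_index(sequence)
  setNames(tabulate(idx, nbins = 20) / length(idx), AA_ALPHABET)
}

#' Dipeptide composition
#'
#' Fractions of the 400 ordered residue pairs among the `L - 1` adjacent
#' positions of the sequence.
#'
#' @inheritParams aa_composition
#' @return Named numeric vector of 400 fractions summing to 1, names like
#'   `"AC"`.
#' @export
dipeptide_composition <- function(sequence) {
  if (nchar(sequence) < 2) stop("dipeptide composition needs length >= 2", call. = FALSE)
  idx <- .seq_index(sequence)
  L <- length(idx)
  pair <- (idx[-L] - 1L) * 20L + idx[-1L]
  counts <- tabulate(pair, nbins = 400)
  nm <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  setNames(counts / (L - 1), nm)
}

#' Sequence autocorrelation of a physicochemical property
#'
#' Computes the normalized Moreau-Broto, Moran or Geary autocorrelation of a
#' per-residue property at positional lag `d`. The property scale should be
#' standardized over the 20 residues (see [standardize_scale()]). When every
#' residue of the sequence carries the same property value the Moran and
#' Geary statistics are undefined and are returned as 0.
#'
#' @inheritParams aa_composition
#' @param scale Named numeric vector over the 20 canonical residues.
#' @param method One of `"moreau_broto"`, `"moran"`, `"geary"`.
#' @param lag Positional lag `d`, `1 <= d <= L - 1`.
#' @return A single numeric value.
#' @export
autocorrelation <- function(sequence, scale,
                            method = c("moreau_broto", "moran", "geary"),
                            lag = 1) {
  method <- match.arg(method)
  idx <- .seq_index(sequence)
  L <- length(idx)
  if (lag < 1 || lag > L - 1) {
    stop(sprintf("lag %d out of range for sequence of length %d", lag, L),
         call. = FALSE)
  }
  P <- unname(scale[AA_ALPHABET][idx])
  i <- seq_len(L - lag)
  if (method == "moreau_broto") {
    return(sum(P[i] * P[i + lag]) / (L - lag))
  }
  Pbar <- mean(P)
  ss <- sum((P - Pbar)^2)
  if (ss == 0) return(0)
  if (method == "moran") {
    num <- sum((P[i] - Pbar) * (P[i + lag] - Pbar)) / (L - lag)
    num / (ss / L)
  } else {
    num <- sum((P[i] - P[i + lag])^2) / (2 * (L - lag))
    num / (ss / (L - 1))
  }
}

#' Composition-transition-distribution (CTD) descriptors
#'
#' For a 3-class partition of the amino-acid alphabet, computes 3 class
#' composition fractions, 3 transition fractions among unordered class pairs
#' (denominator `L - 1`) and 15 distribution values: for each class, the
#' 1-based positions of its first, 25%, 50%, 75% and last occurrence divided
#' by `L`. The k% occurrence index is `ceiling(k/100 * n_c)` with a minimum of
#' 1; a class absent from the sequence contributes 0 for its five slots.
#'
#' @inheritParams aa_composition
#' @param grouping List of three character vectors partitioning the alphabet
#'   (see [default_groupings()]).
#' @return Named numeric vector of 21 values.
#' @export
ctd <- function(sequence, grouping) {
  if (nchar(sequence) < 1) stop("empty sequence", call. = FALSE)
  idx <- .seq_index(sequence)
  L <- length(idx)
  cls_of <- integer(20)
  for (g in 1:3) cls_of[match(grouping[[g]], AA_ALPHABET)] <- g
  cls <- cls_of[idx]
  comp <- tabulate(cls, nbins = 3) / L
  trans <- c(0, 0, 0)
  if (L >= 2) {
    a <- cls[-L]; b <- cls[-1]
    pair <- pmin(a, b) * 10 + pmax(a, b)
    trans <- c(sum(pair == 12), sum(pair == 13), sum(pair == 23)) / (L - 1)
  }
  distr <- numeric(15)
  for (g in 1:3) {
    pos <- which(cls == g)
    n_c <- length(pos)
    if (n_c > 0) {
      ks <- c(1, pmax(1, ceiling(c(0.25, 0.5, 0.75) * n_c)), n_c)
      distr[(g - 1) * 5 + 1:5] <- pos[ks] / L
    }
  }
  setNames(c(comp, trans, distr),
           c(paste0("comp.g", 1:3),
             c("trans.g12", "trans.g13", "trans.g23"),
             paste0("dist.g", rep(1:3, each = 5), ".",
                    rep(c("first", "p25", "p50", "p75", "p100"), 3))))
}

#' Physicochemical summary descriptors
#'
#' Means of raw (unstandardized) property scales plus simple charge, size and
#' isoelectric-point summaries: mean Kyte-Doolittle hydropathy, net charge at
#' neutral pH (`#K,R + 0.1 #H - #D,E`), mean Grantham polarity, mean
#' normalized van der Waals volume, mean polarizability, isoelectric point
#' (Henderson-Hasselbalch estimate), molecular weight (Da) and chain length.
#'
#' @inheritParams aa_composition
#' @return Named numeric vector of 8 values.
#' @export
physico_summary <- function(sequence) {
  idx <- .seq_index(sequence)
  chars <- AA_ALPHABET[idx]
  counts <- tabulate(idx, nbins = 20)
  names(counts) <- AA_ALPHABET
  net_charge <- counts["K"] + counts["R"] + 0.1 * counts["H"] -
    counts["D"] - counts["E"]
  c(mean_hydrophobicity = mean(KD_HYDROPHOBICITY[idx]),
    net_charge = unname(net_charge),
    mean_polarity = mean(POLARITY[idx]),
    mean_vdw_volume = mean(VDW_VOLUME[idx]),
    mean_polarizability = mean(POLARIZABILITY[idx]),
    isoelectric_point = seqinr::computePI(chars),
    molecular_weight = sum(RESIDUE_MASS[idx]) + 18.01524,
    length = length(idx))
}

#' Disorder profile from a windowed fold index
#'
#' Per-residue fold index `FI = 2.785 <H> - |<q>| - 1.151` over a centered
#' window (truncated at the chain ends), where `<H>` is the windowed mean
#' Kyte-Doolittle hydropathy rescaled to `[0, 1]` and `<q>` the windowed mean
#' net charge per residue (K/R +1, D/E -1). Residues with `FI < 0` are called
#' disordered.
#'
#' @inheritParams aa_composition
#' @param window Odd window width (default 21).
#' @return Named numeric vector: `mean_fold_index`, `disordered_fraction`.
#' @export
disorder_profile <- function(sequence, window = 21) {
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  idx <- .seq_index(sequence)
  L <- length(idx)
  H <- (KD_HYDROPHOBICITY[idx] + 4.5) / 9
  q <- RESIDUE_CHARGE[idx]
  h <- (window - 1) / 2
  csH <- cumsum(c(0, H)); csq <- cumsum(c(0, q))
  lo <- pmax(1, seq_len(L) - h); hi <- pmin(L, seq_len(L) + h)
  n <- hi - lo + 1
  Hw <- (csH[hi + 1] - csH[lo]) / n
  qw <- (csq[hi + 1] - csq[lo]) / n
  FI <- 2.785 * Hw - abs(qw) - 1.151
  c(mean_fold_index = mean(FI), disordered_fraction = mean(FI < 0))
}

.ss_class <- local({
  # per-residue class by maximal Chou-Fasman propensity; ties go to coil
  cls <- apply(CHOU_FASMAN, 2, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1) 3L else top
  })
  as.integer(cls)
})

#' Secondary-structure composition
#'
#' Assigns each residue to the conformational class (helix/sheet/coil) with
#' its highest Chou-Fasman propensity (ties to coil) and returns the three
#' class fractions.
#'
#' @inheritParams aa_composition
#' @return Named numeric vector `helix`, `sheet`, `coil`, summing to 1.
#' @export
ss_composition <- function(sequence) {
  idx <- .seq_index(sequence)
  cls <- .ss_class[idx]
  setNames(tabulate(cls, nbins = 3) / length(idx), c("helix", "sheet", "coil"))
}

#' Radius estimate from chain length
#'
#' Empirical compact-globule scaling `R = coef * L^exponent` (Angstrom), used
#' as a structure-free proxy for the radius of gyration: diffusion through
#' gland epithelium is expected to fall with molecular radius.
#'
#' @param length Chain length in residues.
#' @param coef,exponent Scaling-law parameters (defaults 2.2 and 0.38).
#' @return Radius in Angstrom.
#' @export
radius_estimate <- function(length, coef = 2.2, exponent = 0.38) {
  if (any(length < 1)) stop("length must be >= 1", call. = FALSE)
  coef * length^exponent
}

#' Twin-arginine (TAT) signal motif
#'
#' `TRUE` iff the pattern `[S|T]-R-R-x-F-L-K` occurs within the first 35
#' residues of the sequence.
#'
#' @inheritParams aa_composition
#' @return Logical scalar.
#' @export
tat_motif <- function(sequence) {
  grepl("[ST]RR.FLK", substr(toupper(sequence), 1, 35))
}

#' Heuristic N-terminal signal-peptide flag
#'
#' External signal-peptide predictions are consumed as annotation columns
#' when available; this fallback flags sequences whose mean Kyte-Doolittle
#' hydropathy over residues 1-25 exceeds a threshold.
#'
#' @inheritParams aa_composition
#' @param threshold Mean-hydropathy cutoff (default 1.6).
#' @return Logical scalar.
#' @export
signal_peptide_heuristic <- function(sequence, threshold = 1.6) {
  idx <- .seq_index(substr(sequence, 1, 25))
  mean(KD_HYDROPHOBICITY[idx]) > threshold
}

#' Descriptor configuration
#'
#' Controls which descriptor blocks [featurize()] computes and with which
#' scales, groupings and autocorrelation lags. The default configuration
#' produces a 1,302-dimensional feature vector: amino-acid composition (20) +
#' dipeptide composition (400) + 3 autocorrelation methods x 8 scales x 30
#' lags (720) + 7 CTD groupings x 21 (147) + physicochemical summary (8) +
#' disorder (2) + secondary structure (3) + radius (1) + TAT motif (1).
#'
#' @param blocks Character vector of enabled blocks; any subset of
#'   `c("aac", "dpc", "autocorr", "ctd", "physico", "disorder", "ss",
#'   "radius", "tat")`.
#' @param d_max Maximum autocorrelation lag (default 30).
#' @param scales Named list of standardized property scales (default
#'   [default_scales()]).
#' @param groupings Named list of 3-class groupings (default
#'   [default_groupings()]).
#' @param disorder_window Window for [disorder_profile()].
#' @param radius_coef,radius_exponent Passed to [radius_estimate()].
#' @return An object of class `descriptor_config`.
#' @export
descriptor_config <- function(blocks = c("aac", "dpc", "autocorr", "ctd",
                                         "physico", "disorder", "ss",
                                         "radius", "tat"),
                              d_max = 30,
                              scales = default_scales(),
                              groupings = default_groupings(),
                              disorder_window = 21,
                              radius_coef = 2.2, radius_exponent = 0.38) {
  stopifnot(d_max >= 1)
  structure(list(blocks = blocks, d_max = d_max, scales = scales,
                 groupings = groupings, disorder_window = disorder_window,
                 radius_coef = radius_coef, radius_exponent = radius_exponent),
            class = "descriptor_config")
}

#' Dimension of the feature vector a configuration produces
#'
#' @param config A [descriptor_config()].
#' @return Integer number of feature columns (excluding the id column).
#' @export
descriptor_dim <- function(config = descriptor_config()) {
  b <- config$blocks
  sum(c(aac = 20, dpc = 400,
        autocorr = 3 * length(config$scales) * config$d_max,
        ctd = 21 * length(config$groupings),
        physico = 8, disorder = 2, ss = 3, radius = 1, tat = 1)[b])
}

.featurize_one <- function(sequence, config) {
  L <- nchar(sequence)
  out <- list()
  b <- config$blocks
  if ("aac" %in% b) out$aac <- setNames(aa_composition(sequence),
                                        paste0("aac.", AA_ALPHABET))
  if ("dpc" %in% b) {
    v <- dipeptide_composition(sequence)
    out$dpc <- setNames(v, paste0("dpc.", names(v)))
  }
  if ("autocorr" %in% b) {
    feasible <- min(config$d_max, L - 1)
    ac <- numeric(0)
    for (m in c("moreau_broto", "moran", "geary")) {
      for (sn in names(config$scales)) {
        vals <- numeric(config$d_max)
        for (d in seq_len(feasible)) {
          vals[d] <- autocorrelation(sequence, config$scales[[sn]], m, d)
        }
        names(vals) <- sprintf("%s.%s.lag%02d", m, sn, seq_len(config$d_max))
        ac <- c(ac, vals)
      }
    }
    out$autocorr <- ac
    attr(out, "truncated") <- feasible < config$d_max
  }
  if ("ctd" %in% b) {
    cd <- purrr::imap(config$groupings, function(g, nm) {
      v <- ctd(sequence, g)
      setNames(v, paste0("ctd.", nm, ".", names(v)))
    })
    out$ctd <- unlist(unname(cd))
  }
  if ("physico" %in% b) {
    v <- physico_summary(sequence)
    out$physico <- setNames(v, paste0("physico.", names(v)))
  }
  if ("disorder" %in% b) {
    v <- disorder_profile(sequence, config$disorder_window)
    out$disorder <- setNames(v, paste0("disorder.", names(v)))
  }
  if ("ss" %in% b) {
    v <- ss_composition(sequence)
    out$ss <- setNames(v, paste0("ss.", names(v)))
  }
  if ("radius" %in% b) {
    out$radius <- c(radius.estimate = radius_estimate(
      L, config$radius_coef, config$radius_exponent))
  }
  if ("tat" %in% b) out$tat <- c(tat.motif = as.numeric(tat_motif(sequence)))
  out
}

#' Compute the per-protein feature matrix
#'
#' Applies every enabled descriptor block to each protein and binds the
#' results into a feature tibble: one row per input protein (input order
#' preserved), an `id` column, then one numeric column per feature element
#' with stable self-describing names (`block.scale.lag` etc.). For sequences
#' shorter than `d_max + 1`, autocorrelation entries at infeasible lags are 0
#' and a warning names the affected records.
#'
#' @param proteins Tibble with `id` and `sequence` columns (see
#'   [read_fasta()]).
#' @param config A [descriptor_config()].
#' @param extra_features Optional tibble keyed by `id` whose remaining numeric
#'   columns (e.g. externally predicted signal-peptide or transmembrane
#'   flags) are appended to the matrix.
#' @return A feature tibble.
#' @export
featurize <- function(proteins, config = descriptor_config(),
                      extra_features = NULL) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  rows <- vector("list", nrow(proteins))
  truncated <- character(0)
  for (i in seq_len(nrow(proteins))) {
    res <- tryCatch(.featurize_one(proteins$sequence[i], config),
                    error = function(e) {
                      stop(sprintf("featurize failed for record '%s': %s",
                                   proteins$id[i], conditionMessage(e)),
                           call. = FALSE)
                    })
    if (isTRUE(attr(res, "truncated"))) truncated <- c(truncated, proteins$id[i])
    rows[[i]] <- unlist(unname(res))
  }
  if (length(truncated) > 0) {
    warning("autocorrelation lags beyond sequence length set to 0 for: ",
            paste(truncated, collapse = ", "), call. = FALSE)
  }
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(id = proteins$id), out)
  if (!is.null(extra_features)) {
    out <- dplyr::left_join(out, extra_features, by = "id")
  }
  if (any(!is.finite(as.matrix(out[, -1])))) {
    stop("non-finite feature values produced", call. = FALSE)
  }
  out
}
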