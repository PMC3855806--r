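# Amino-acid property tables used by the descriptor suite.
# All scales are keyed by the 20 canonical residues in alphabetical
# one-letter order; values are from the standard published tables.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.scale <- function(...) {
  v <- c(...)
  stopifnot(identical(sort(names(v)), AA_ALPHABET))
  v[AA_ALPHABET]
}

# Kyte & Doolittle hydropathy
KD_HYDROPHOBICITY <- .scale(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Hopp & Woods hydrophilicity
HYDROPHILICITY <- .scale(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
  G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
  P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)

# Bhaskaran & Ponnuswamy average flexibility index
FLEXIBILITY <- .scale(
  A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346, Q = 0.493,
  E = 0.497, G = 0.544, H = 0.323, I = 0.462, L = 0.365, K = 0.466,
  M = 0.295, F = 0.314, P = 0.509, S = 0.507, T = 0.444, W = 0.305,
  Y = 0.420, V = 0.386)

# Grantham polarity
POLARITY <- .scale(
  A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5, E = 12.3,
  G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3, M = 5.7, F = 5.2,
  P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9)

# Charton & Charton polarizability
POLARIZABILITY <- .scale(
  A = 0.046, R = 0.291, N = 0.134, D = 0.105, C = 0.128, Q = 0.180,
  E = 0.151, G = 0.000, H = 0.230, I = 0.186, L = 0.186, K = 0.219,
  M = 0.221, F = 0.290, P = 0.131, S = 0.062, T = 0.108, W = 0.409,
  Y = 0.298, V = 0.140)

# Normalized van der Waals volume (Fauchere et al.)
VDW_VOLUME <- .scale(
  A = 1.00, R = 6.13, N = 2.95, D = 2.78, C = 2.43, Q = 3.95, E = 3.78,
  G = 0.00, H = 4.66, I = 4.00, L = 4.00, K = 4.77, M = 4.43, F = 5.89,
  P = 2.72, S = 1.60, T = 2.60, W = 8.08, Y = 6.47, V = 3.00)

# Charton steric parameter (graph-theoretical index)
STERIC <- .scale(
  A = 0.52, R = 0.68, N = 0.76, D = 0.76, C = 0.62, Q = 0.68, E = 0.68,
  G = 0.00, H = 0.70, I = 1.02, L = 0.98, K = 0.68, M = 0.78, F = 0.70,
  P = 0.36, S = 0.53, T = 0.50, W = 0.70, Y = 0.70, V = 0.76)

# Zimmerman isoelectric point
ISOELECTRIC <- .scale(
  A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.05, Q = 5.65, E = 3.22,
  G = 5.97, H = 7.59, I = 6.02, L = 5.98, K = 9.74, M = 5.74, F = 5.48,
  P = 6.30, S = 5.68, T = 5.66, W = 5.89, Y = 5.66, V = 5.96)

# Average residue masses (Da); water added once per chain for protein MW.
RESIDUE_MASS <- .scale(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Standardize a property scale over the 20 amino acids
#'
#' Centers and scales a 20-value amino-acid property vector so that the mean
#' over the 20 residues is 0 and the population standard deviation is 1, the
#' convention used before computing autocorrelation descriptors.
#'
#' @param raw Named numeric vector over the 20 canonical residues.
#' @return Named numeric vector, same names, mean 0 and population sd 1.
#' @examples
#' s <- standardize_scale(c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
#'   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
#'   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3,
#'   V = 4.2))
#' mean(s)  # ~0
#' @export
standardize_scale <- function(raw) {
  if (length(raw) != 20L || is.null(names(raw)) ||
      !setequal(names(raw), AA_ALPHABET)) {
    stop("a property scale must be a named vector over the 20 canonical amino acids")
  }
  raw <- raw[AA_ALPHABET]
  mu <- mean(raw)
  sigma <- sqrt(mean((raw - mu)^2))  # population sd
  if (sigma == 0) stop("degenerate scale: all 20 values identical")
  (raw - mu) / sigma
}

#' Default autocorrelation property scales
#'
#' The eight physicochemical scales used by default for the Moreau-Broto,
#' Moran and Geary autocorrelation descriptors: Kyte-Doolittle hydropathy,
#' Hopp-Woods hydrophilicity, Bhaskaran-Ponnuswamy flexibility, Grantham
#' polarity, Charton-Charton polarizability, normalized van der Waals volume,
#' Charton steric parameter and Zimmerman isoelectric point.
#'
#' @param standardized If `TRUE` (default) each scale is centered/scaled to
#'   mean 0 and population sd 1 over the 20 residues.
#' @return Named list of eight named numeric vectors.
#' @export
default_scales <- function(standardized = TRUE) {
  raw <- list(
    hydrophobicity = KD_HYDROPHOBICITY,
    hydrophilicity = HYDROPHILICITY,
    flexibility    = FLEXIBILITY,
    polarity       = POLARITY,
    polarizability = POLARIZABILITY,
    vdw_volume     = VDW_VOLUME,
    steric         = STERIC,
    isoelectric    = ISOELECTRIC)
  if (standardized) lapply(raw, standardize_scale) else raw
}

# Three-class residue partitions for the CTD descriptors
# (standard Dubchak-style groupings).
.grouping <- function(g1, g2, g3) {
  g <- list(strsplit(g1, "")[[1]], strsplit(g2, "")[[1]], strsplit(g3, "")[[1]])
  stopifnot(setequal(unlist(g), AA_ALPHABET), length(unlist(g)) == 20L)
  g
}

#' Default CTD grouping schemes
#'
#' Seven standard 3-class partitions of the amino-acid alphabet used by the
#' composition-transition-distribution descriptors: hydrophobicity, normalized
#' van der Waals volume, polarity, polarizability, charge, secondary-structure
#' propensity and solvent accessibility.
#'
#' @return Named list; each element is a list of three character vectors that
#'   partition the 20 canonical residues.
#' @export
default_groupings <- function() {
  list(
    hydrophobicity = .grouping("RKEDQN", "GASTPHY", "CLVIMFW"),
    vdw_volume     = .grouping("GASCTPD", "NVEQIL", "MHKFRYW"),
    polarity       = .grouping("LIFWCMVY", "PATGS", "HQRKNED"),
    polarizability = .grouping("GASDT", "CPNVEQIL", "KMHFRYW"),
    charge         = .grouping("KR", "ANCQGHILMFPSTWYV", "DE"),
    sec_struct     = .grouping("EALMQKRH", "VIYCWFT", "GNPSD"),
    solvent_access = .grouping("ALFCGIVW", "RKQEND", "MSPTHY"))
}

# Chou-Fasman conformational propensities (helix, sheet, turn/coil).
CHOU_FASMAN <- local({
  m <- rbind(
    helix = .scale(A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70,
                   Q = 1.11, E = 1.51, G = 0.57, H = 1.00, I = 1.08,
                   L = 1.21, K = 1.16, M = 1.45, F = 1.13, P = 0.57,
                   S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06),
    sheet = .scale(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
                   Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
                   L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
                   S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70),
    coil  = .scale(A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19,
                   Q = 0.98, E = 0.74, G = 1.56, H = 0.95, I = 0.47,
                   L = 0.59, K = 1.01, M = 0.60, F = 0.60, P = 1.52,
                   S = 1.43, T = 0.96, W = 0.96, Y = 1.14, V = 0.50))
  m
})

# Per-residue formal charge at neutral pH used by the disorder profile
# (FoldIndex convention: K/R +1, D/E -1, others 0).
RESIDUE_CHARGE <- setNames(numeric(20), AA_ALPHABET)
RESIDUE_CHARGE[c("K", "R")] <- 1
RESIDUE_CHARGE[c("D", "E")] <- -1
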