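# Reading/writing the plain-text formats the pipeline touches: FASTA for
# protein sequences, TSV for annotations and every tabular output.

.validate_sequence <- function(seq, id, relaxed = FALSE) {
  seq <- toupper(seq)
  if (relaxed) {
    seq <- gsub(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), "", seq)
  }
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("record '%s' contains non-canonical residue(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (nchar(seq) < 1) {
    stop(sprintf("record '%s' has an empty sequence after validation", id),
         call. = FALSE)
  }
  seq
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a protein tibble. The
#' header token before the first whitespace becomes the record id; sequences
#' are uppercased. Residues outside the 20-letter canonical alphabet are an
#' error by default because every descriptor scale is defined only on the
#' canonical residues; `relaxed = TRUE` strips them instead.
#'
#' @param path Path to a FASTA file.
#' @param relaxed Strip non-canonical residues (B, Z, X, U, O, ...) instead of
#'   failing. Default `FALSE` (reject).
#' @return A tibble with columns `id` and `sequence`, one row per record.
#' @export
read_fasta <- function(path, relaxed = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file is empty: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- purrr::map2_chr(as.character(set), ids, .validate_sequence,
                          relaxed = relaxed)
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write a protein tibble to FASTA
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  lines <- purrr::map2(proteins$id, proteins$sequence, function(id, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a per-protein annotation table
#'
#' The annotation TSV abstracts over the external evidence sources the
#' training-set rules need: protein-family membership, known-in-saliva flags
#' and plasma-proteome peptide counts. Required header columns: `id`,
#' `family_ids` (semicolon-separated, may be empty), `saliva_evidence` (0/1)
#' and `peptide_count`. Missing optional values default to no families /
#' `FALSE` / 0.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `family_ids` (list column of character
#'   vectors), `saliva_evidence` (logical), `peptide_count` (integer).
#' @export
read_annotations <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"id" %in% names(raw)) {
    stop("annotation table must have an 'id' column", call. = FALSE)
  }
  for (col in c("family_ids", "saliva_evidence", "peptide_count")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  parse_row <- function(val, line, what, f) {
    out <- tryCatch(f(val), error = function(e) {
      stop(sprintf("malformed %s at line %d: '%s'", what, line, val),
           call. = FALSE)
    })
    out
  }
  n <- nrow(raw)
  fams <- purrr::map(seq_len(n), function(i) {
    v <- raw$family_ids[i]
    if (is.na(v) || v == "") character(0) else strsplit(v, ";", fixed = TRUE)[[1]]
  })
  sal <- purrr::map_lgl(seq_len(n), function(i) {
    v <- raw$saliva_evidence[i]
    if (is.na(v) || v == "") return(FALSE)
    if (!v %in% c("0", "1")) {
      stop(sprintf("malformed saliva_evidence at line %d: '%s'", i + 1L, v),
           call. = FALSE)
    }
    v == "1"
  })
  pep <- purrr::map_int(seq_len(n), function(i) {
    v <- raw$peptide_count[i]
    if (is.na(v) || v == "") return(0L)
    x <- suppressWarnings(as.integer(v))
    if (is.na(x) || x < 0) {
      stop(sprintf("malformed peptide_count at line %d: '%s'", i + 1L, v),
           call. = FALSE)
    }
    x
  })
  tibble::tibble(id = raw$id, family_ids = fams,
                 saliva_evidence = sal, peptide_count = pep)
}

#' Write a rectangular table as TSV
#'
#' UTF-8, header row, newline-terminated; numeric columns are rendered with at
#' least six significant digits so round-tripped feature matrices keep their
#' precision.
#'
#' @param rows A data frame (or tibble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("rows must be a data frame", call. = FALSE)
  out <- as.data.frame(rows)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 10, format = "g")
    if (is.list(out[[j]])) out[[j]] <- purrr::map_chr(out[[j]], paste, collapse = ";")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with columns typed by `readr` defaults.
#' @export
read_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  show_col_types = FALSE)
}

#' Attach annotations to a protein tibble
#'
#' Left-joins an annotation tibble (see [read_annotations()]) onto a protein
#' tibble by `id`, filling unannotated proteins with defaults.
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param annotations Tibble from [read_annotations()].
#' @return The protein tibble with `family_ids`, `saliva_evidence`,
#'   `peptide_count` columns.
#' @export
annotate_proteins <- function(proteins, annotations) {
  out <- dplyr::left_join(proteins, annotations, by = "id")
  out$family_ids <- purrr::map(out$family_ids, function(f) {
    if (is.null(f) || all(is.na(f))) character(0) else f
  })
  out$saliva_evidence <- dplyr::coalesce(out$saliva_evidence, FALSE)
  out$peptide_count <- dplyr::coalesce(out$peptide_count, 0L)
  out
}
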