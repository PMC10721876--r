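# Sequence and pair-table input: FASTA peptides and labeled pair lists.

#' Read peptides from a FASTA file
#'
#' Parses a FASTA file into a list of validated [peptide()] objects, order
#' preserved.  Sequences are uppercased; the identifier is the first
#' whitespace-delimited token of the header line.  Records with duplicate
#' identifiers or non-canonical residues (including B, J, O, U, X, Z and gap
#' characters) are rejected.
#'
#' @param path Path to a FASTA file.
#' @return List of `peptide` objects.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "NFGAIL"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("malformed FASTA in '", path, "': no records", call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop_validation(
      "duplicate sequence id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  seqs <- as.character(set)
  mapply(peptide, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# Closed label vocabulary for pair records (AmyloGraph/AmyLoad-style roles).
PAIR_LABELS <- c(
  "interact_faster", "interact_slower", "non_interacting",
  "amyloid", "non_amyloid", "unknown"
)

# Labels counted as the positive (interacting) class.  The method does not
# distinguish faster- from slower-aggregation interactions; both are
# positives.
POSITIVE_LABELS <- c("interact_faster", "interact_slower", "amyloid")
NEGATIVE_LABELS <- c("non_interacting", "non_amyloid")

#' Read a labeled peptide-pair table
#'
#' Reads a TSV with header columns `id_a`, `seq_a`, `id_b`, `seq_b`, `label`
#' into a list of pair records.  Labels must come from the closed vocabulary
#' `interact_faster`, `interact_slower`, `non_interacting`, `amyloid`,
#' `non_amyloid`, `unknown`; sequences are validated against the canonical
#' alphabet.
#'
#' @param path Path to a tab-separated file.
#' @return List of records, each a list with `pep_a`, `pep_b` ([peptide()]
#'   objects) and `label`.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) {
    stop("pair table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("id_a", "seq_a", "id_b", "seq_b", "label")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("pair table '", path, "' missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$label), PAIR_LABELS)
  if (length(bad)) {
    stop_validation(
      "unknown pair label(s): ", paste(bad, collapse = ", "),
      " (allowed: ", paste(PAIR_LABELS, collapse = ", "), ")"
    )
  }
  lapply(seq_len(nrow(df)), function(i) {
    list(
      pep_a = peptide(df$id_a[i], df$seq_a[i]),
      pep_b = peptide(df$id_b[i], df$seq_b[i]),
      label = df$label[i]
    )
  })
}

#' Write a labeled peptide-pair table
#'
#' Inverse of [read_pair_table()]; used by the fixture generator.
#'
#' @param records List of pair records (`pep_a`, `pep_b`, `label`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(records, path) {
  header <- "id_a\tseq_a\tid_b\tseq_b\tlabel"
  rows <- vapply(records, function(r) {
    paste(r$pep_a$id, r$pep_a$seq, r$pep_b$id, r$pep_b$seq, r$label,
          sep = "\t")
  }, "")
  atomic_write_lines(c(header, rows), path)
}
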