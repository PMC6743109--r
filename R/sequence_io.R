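# FASTA input/output and sequence records.
#
# A corpus is held as a plain data.frame ("seq_records") with one row per
# sequence: id, sequence (A/C/G/T plus any retained IUPAC ambiguity codes),
# label (0 = lncRNA, 1 = mRNA, NA = unknown) and length in nt.  Ambiguous
# bases are retained in the record; k-mer windows touching them are skipped
# at counting time, never imputed.

LABEL_LNCRNA <- 0L
LABEL_MRNA <- 1L

#' Build a sequence-record table
#'
#' Constructs the labeled corpus container used throughout the package.
#' Sequences are sanitized (uppercased, RNA `U` mapped to `T`); ambiguous
#' characters (anything outside A/C/G/T) are retained and counted per
#' record.
#'
#' @param id character vector of sequence identifiers.
#' @param sequence character vector of nucleotide sequences.
#' @param label class labels: `0` (lncRNA), `1` (mRNA) or `NA` (unknown).
#'   Recycled to the number of sequences.
#' @return A `data.frame` of class `"seq_records"` with columns `id`,
#'   `sequence`, `label`, `length` and `ambiguous` (count of non-ACGT
#'   characters).
#' @export
seq_records <- function(id, sequence, label = NA_integer_) {
  stopifnot(length(id) == length(sequence))
  s <- sanitize_sequence(sequence)
  label <- as.integer(rep_len(label, length(sequence)))
  bad <- !is.na(label) & !label %in% c(LABEL_LNCRNA, LABEL_MRNA)
  if (any(bad)) {
    stop("labels must be 0 (lncRNA), 1 (mRNA) or NA, got: ",
         paste(unique(label[bad]), collapse = ", "))
  }
  out <- data.frame(
    id = as.character(id),
    sequence = s$sequence,
    label = label,
    length = nchar(s$sequence),
    ambiguous = s$n_ambiguous,
    stringsAsFactors = FALSE
  )
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Sanitize raw nucleotide text
#'
#' Uppercases, strips whitespace and maps RNA `U` to `T`.  Characters other
#' than A/C/G/T (e.g. `N` or other IUPAC codes) are retained and counted,
#' so that downstream k-mer counting can skip the windows containing them
#' rather than fabricating frequencies.
#'
#' @param x character vector of raw sequences.
#' @return list with components `sequence` (cleaned character vector) and
#'   `n_ambiguous` (integer vector of retained non-ACGT characters).
#' @examples
#' sanitize_sequence("acgu")$sequence        # "ACGT"
#' sanitize_sequence("ACNGT")$n_ambiguous    # 1
#' @export
sanitize_sequence <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", as.character(x)))
  x <- chartr("U", "T", x)
  n_amb <- nchar(gsub("[ACGT]", "", x))
  list(sequence = x, n_ambiguous = as.integer(n_amb))
}

#' Read sequences from a FASTA file
#'
#' @param path path to a FASTA file (multi-line sequences allowed).
#' @param label class label attached to every record in the file
#'   (`0` = lncRNA, `1` = mRNA, `NA` = unknown).  One FASTA per class is
#'   the expected layout.
#' @return a [seq_records] table, one row per FASTA entry; ids are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_fasta_header(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(seq_records(character(0), character(0), integer(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  seq_records(ids, as.character(set), label = label)
}

# Fail with the offending line number when sequence data precedes the first
# '>' header (readBStringSet's own message does not name the line).
check_fasta_header <- function(path) {
  lines <- readLines(path, n = 1000L, warn = FALSE)
  for (i in seq_along(lines)) {
    if (grepl("^\\s*$", lines[i])) next
    if (!startsWith(lines[i], ">")) {
      stop("malformed FASTA in ", path, ": line ", i,
           " contains sequence data before any '>' header")
    }
    break
  }
  invisible(TRUE)
}

#' Write sequence records to FASTA
#'
#' @param records a [seq_records] table.
#' @param path output path.
#' @param width line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write the id/label mapping alongside a FASTA
#'
#' @param records a [seq_records] table.
#' @param path output TSV path (columns `id`, `label`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(records, path) {
  utils::write.table(records[, c("id", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter records by sequence length
#'
#' Keeps records with `min_nt <= length <= max_nt` (both bounds inclusive),
#' preserving order.  The defaults mirror the corpus design this method was
#' developed for: lncRNA 250--3500 nt, mRNA 200--4000 nt, applied by the
#' caller per class.
#'
#' @param records a [seq_records] table.
#' @param min_nt,max_nt inclusive length bounds in nt.
#' @return the filtered [seq_records] table.
#' @export
filter_by_length <- function(records, min_nt = 250, max_nt = 3500) {
  if (min_nt > max_nt) stop("min_nt (", min_nt, ") exceeds max_nt (", max_nt, ")")
  keep <- records$length >= min_nt & records$length <= max_nt
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Human-readable class name for a numeric label
#'
#' @param label integer label vector (0/1/NA).
#' @return character vector: `"lncRNA"`, `"mRNA"` or `"unknown"`.
#' @export
label_name <- function(label) {
  out <- rep("unknown", length(label))
  out[!is.na(label) & label == LABEL_LNCRNA] <- "lncRNA"
  out[!is.na(label) & label == LABEL_MRNA] <- "mRNA"
  out
}

#' @export
print.seq_records <- function(x, ...) {
  cat("seq_records: ", nrow(x), " sequences (",
      sum(!is.na(x$label) & x$label == LABEL_LNCRNA), " lncRNA, ",
      sum(!is.na(x$label) & x$label == LABEL_MRNA), " mRNA, ",
      sum(is.na(x$label)), " unknown); lengths ",
      if (nrow(x)) paste0(min(x$length), "-", max(x$length)) else "-",
      " nt\n", sep = "")
  invisible(x)
}
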