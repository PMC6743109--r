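# Canonical k-mer vocabularies, sliding-window counting and the 2-D
# frequency-matrix layout consumed by the convolutional classifier.
#
# The vocabulary order is a base-4 positional system with digit order
# A < T < C < G, i.e. for k = 3 it runs AAA, AAT, AAC, AAG, ATA, ... and
# ends GGA, GGT, GGC, GGG.  This is NOT alphabetical order; counts obtained
# from Biostrings (alphabetical ACGT) are re-ordered through a permutation.

KMER_BASES <- c("A", "T", "C", "G")

#' Enumerate all k-mers of one length in canonical order
#'
#' @param k window length (>= 1).
#' @return character vector of the `4^k` k-mers in base-4 positional order
#'   with digit order A < T < C < G.
#' @examples
#' enumerate_kmers(1)      # "A" "T" "C" "G"
#' head(enumerate_kmers(3), 4)  # "AAA" "AAT" "AAC" "AAG"
#' @export
enumerate_kmers <- function(k) {
  k <- check_k(k)
  digits <- rev(expand.grid(rep(list(KMER_BASES), k), stringsAsFactors = FALSE))
  do.call(paste0, digits)
}

check_k <- function(k) {
  if (length(k) != 1 || !is.finite(k) || k < 1 || k != round(k)) {
    stop("k must be a single integer >= 1, got ", deparse(k))
  }
  as.integer(k)
}

#' Build a (possibly combined) k-mer vocabulary
#'
#' For several window lengths the per-k blocks are concatenated in
#' ascending k, so the combined 1+2+3 vocabulary has 4 + 16 + 64 = 84
#' entries.
#'
#' @param ks integer vector of window lengths.
#' @return an object of class `"kmer_vocab"`: list with `ks`, `kmers`
#'   (character vector), `k_of` (window length of each entry) and `size`.
#' @export
kmer_vocabulary <- function(ks) {
  ks <- sort(unique(vapply(ks, check_k, integer(1))))
  kmers <- unlist(lapply(ks, enumerate_kmers), use.names = FALSE)
  structure(
    list(ks = ks, kmers = kmers,
         k_of = rep(ks, 4L^ks), size = length(kmers)),
    class = "kmer_vocab"
  )
}

#' Restrict a vocabulary to a subset of k-mers
#'
#' Canonical order is preserved regardless of the order of `keep`, so the
#' downstream matrix layout stays deterministic.
#'
#' @param vocab a [kmer_vocabulary].
#' @param keep character vector of k-mers to retain.
#' @return a `"kmer_vocab"` containing the retained entries.
#' @export
subset_vocabulary <- function(vocab, keep) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  miss <- setdiff(keep, vocab$kmers)
  if (length(miss)) stop("k-mers not in vocabulary: ", paste(head(miss, 5), collapse = ", "))
  sel <- vocab$kmers %in% keep
  structure(
    list(ks = unique(vocab$k_of[sel]), kmers = vocab$kmers[sel],
         k_of = vocab$k_of[sel], size = sum(sel)),
    class = "kmer_vocab"
  )
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat("kmer_vocab: ", x$size, " k-mers (k = ",
      paste(x$ks, collapse = ","), ")\n", sep = "")
  invisible(x)
}

# Permutation taking Biostrings' alphabetical ACGT k-mer order into the
# canonical A,T,C,G digit order; memoised per k.
.kmer_perm_cache <- new.env(parent = emptyenv())
kmer_perm <- function(k) {
  key <- as.character(k)
  if (is.null(.kmer_perm_cache[[key]])) {
    canonical <- enumerate_kmers(k)
    alphabetical <- sort(canonical)
    .kmer_perm_cache[[key]] <- match(canonical, alphabetical)
  }
  .kmer_perm_cache[[key]]
}

#' Count sliding-window k-mers in one sequence
#'
#' Overlapping windows at stride 1; a clean sequence of length m yields
#' `m - k + 1` windows.  Windows containing any non-ACGT character are
#' skipped (they contribute to no count and not to the total).
#'
#' @param sequence a single nucleotide string, or a one-row [seq_records].
#' @param k window length.
#' @return named integer vector over [enumerate_kmers]`(k)` with attribute
#'   `"total"` = number of counted windows.
#' @export
count_kmers <- function(sequence, k) {
  k <- check_k(k)
  sequence <- as_single_sequence(sequence)
  kmers <- enumerate_kmers(k)
  if (nchar(sequence) < k) {
    counts <- stats::setNames(integer(4L^k), kmers)
    attr(counts, "total") <- 0L
    return(counts)
  }
  raw <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = k, step = 1L)
  counts <- as.integer(raw)[kmer_perm(k)]
  names(counts) <- kmers
  attr(counts, "total") <- sum(counts)
  counts
}

as_single_sequence <- function(x) {
  if (inherits(x, "seq_records") || is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    return(x$sequence)
  }
  stopifnot(is.character(x), length(x) == 1)
  x
}

#' Per-sequence normalized k-mer frequency vector
#'
#' Each per-k block is the sliding-window counts divided by that k's total
#' number of counted windows, so every block sums to 1 on a clean sequence.
#' Combined-k vectors are deliberately NOT renormalized to a global sum of
#' 1: normalization is per k, and a 1+2+3 vector sums to 3.
#'
#' When `vocab` is a screened (subset) vocabulary, counting and
#' normalization still run over the full `4^k` vocabulary of each k and the
#' screened entries are then extracted, so a retained k-mer keeps the same
#' frequency it had before screening.
#'
#' @param sequence a nucleotide string or one-row [seq_records].
#' @param ks window lengths (ignored when `vocab` is given).
#' @param vocab optional [kmer_vocabulary], possibly screened.
#' @return numeric vector named by k-mer, with attributes `per_k_sums`
#'   (named by k) and `flagged` (TRUE when some k had no valid window).
#' @export
frequency_vector <- function(sequence, ks = c(1, 2, 3), vocab = NULL) {
  if (is.null(vocab)) vocab <- kmer_vocabulary(ks)
  stopifnot(inherits(vocab, "kmer_vocab"))
  sequence <- as_single_sequence(sequence)
  blocks <- lapply(vocab$ks, function(k) {
    counts <- count_kmers(sequence, k)
    total <- attr(counts, "total")
    if (total == 0) as.numeric(counts) else as.numeric(counts) / total
  })
  full <- unlist(blocks, use.names = FALSE)
  names(full) <- unlist(lapply(vocab$ks, enumerate_kmers), use.names = FALSE)
  out <- full[vocab$kmers]
  sums <- vapply(vocab$ks, function(k) sum(out[vocab$k_of == k]), numeric(1))
  attr(out, "per_k_sums") <- stats::setNames(sums, vocab$ks)
  attr(out, "flagged") <- any(vapply(blocks, function(b) sum(b) == 0, logical(1)))
  out
}

#' Feature table for a corpus
#'
#' @param records a [seq_records] table.
#' @param ks window lengths.
#' @param vocab optional (screened) [kmer_vocabulary].
#' @return numeric matrix, one row per record (rownames = ids), one column
#'   per k-mer; attributes `labels` and `vocab`.
#' @export
frequency_table <- function(records, ks = c(1, 2, 3), vocab = NULL) {
  if (is.null(vocab)) vocab <- kmer_vocabulary(ks)
  if (nrow(records) == 0) stop("no records")
  rows <- lapply(records$sequence, frequency_vector, vocab = vocab)
  m <- do.call(rbind, rows)
  rownames(m) <- records$id
  attr(m, "labels") <- records$label
  attr(m, "vocab") <- vocab
  m
}

#' Write a feature table as TSV
#'
#' Columns: `id`, `label`, then one column per k-mer in vocabulary order.
#'
#' @param features matrix from [frequency_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  df <- data.frame(id = rownames(features),
                   label = attr(features, "labels"),
                   features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shapes printed for the matrix layouts actually used by the method; keys
# are vocabulary sizes.  Some entries are not the most-square factor pair
# (e.g. 260 -> 10 x 26), so the registry takes precedence over the rule.
SHAPE_REGISTRY <- list(
  `64` = c(8, 8), `256` = c(16, 16), `1024` = c(32, 32), `4096` = c(64, 64),
  `68` = c(17, 4), `260` = c(10, 26), `1028` = c(4, 257),
  `80` = c(8, 10), `272` = c(16, 17), `1040` = c(26, 40),
  `320` = c(16, 20), `1088` = c(32, 34), `1280` = c(32, 40),
  `84` = c(7, 12), `336` = c(12, 28), `1104` = c(24, 46),
  `115` = c(5, 23)
)

is_prime <- function(n) {
  if (n < 2) return(FALSE)
  if (n < 4) return(TRUE)
  if (n %% 2 == 0) return(FALSE)
  for (d in seq(3, floor(sqrt(n)), by = 2)) if (n %% d == 0) return(FALSE)
  TRUE
}

most_square_shape <- function(n) {
  r <- floor(sqrt(n))
  while (n %% r != 0) r <- r - 1
  c(r, n %/% r)
}

#' Matrix shape for a feature-vector length
#'
#' Looks up the registry of published layout shapes first; unregistered
#' sizes fall back to the most-square factor pair with `rows <= cols`
#' (minimal `cols - rows`).  A prime size greater than 3 is zero-padded to
#' the next size that factors, so the grid never degenerates to one row.
#'
#' @param n_features vocabulary size (>= 1).
#' @return integer vector `c(rows, cols)`; `rows * cols >= n_features`.
#' @examples
#' matrix_shape_for(256)  # 16 16
#' matrix_shape_for(84)   # 7 12
#' matrix_shape_for(12)   # 3 4
#' @export
matrix_shape_for <- function(n_features) {
  if (length(n_features) != 1 || !is.finite(n_features) || n_features < 1) {
    stop("n_features must be a single count >= 1")
  }
  n <- as.integer(n_features)
  hit <- SHAPE_REGISTRY[[as.character(n)]]
  if (!is.null(hit)) return(as.integer(hit))
  if (is_prime(n) && n > 3) n <- n + 1L
  as.integer(most_square_shape(n))
}

#' Lay a frequency vector out as a 2-D matrix
#'
#' Row-major fill in vocabulary order ("arranged horizontally"); trailing
#' cells beyond the vector length are exactly zero.
#'
#' @param vec numeric frequency vector.
#' @param shape integer `c(rows, cols)`; defaults to
#'   [matrix_shape_for]`(length(vec))`.
#' @return numeric `rows x cols` matrix with attribute `"source"` carrying
#'   any name the vector had.
#' @export
to_matrix <- function(vec, shape = matrix_shape_for(length(vec))) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  if (prod(shape) < length(vec)) {
    stop("shape ", shape[1], " x ", shape[2],
         " cannot hold ", length(vec), " values")
  }
  padded <- c(as.numeric(vec), numeric(prod(shape) - length(vec)))
  matrix(padded, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}

#' Stack a feature table into the 4-D array consumed by the network
#'
#' @param features matrix from [frequency_table] (rows = sequences).
#' @param shape `c(rows, cols)` grid shape.
#' @return array of dim `c(rows, cols, 1, n_sequences)`.
#' @export
to_matrix_array <- function(features, shape = matrix_shape_for(ncol(features))) {
  n <- nrow(features)
  out <- array(0, c(shape[1], shape[2], 1L, n))
  for (i in seq_len(n)) out[, , 1L, i] <- to_matrix(features[i, ], shape)
  out
}

#' Mean per-k-mer frequency over a corpus
#'
#' Arithmetic mean over records of each k-mer's per-sequence frequency (the
#' mean-of-frequencies summary behind composition line graphs), not the
#' pooled corpus-level distribution used for screening.
#'
#' @param records a [seq_records] table (nonempty).
#' @param k window length.
#' @return named numeric vector over the canonical vocabulary.
#' @export
mean_frequencies <- function(records, k) {
  if (nrow(records) == 0) stop("mean_frequencies needs at least one record")
  vocab <- kmer_vocabulary(k)
  colMeans(frequency_table(records, vocab = vocab))
}
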