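# Relative-entropy (Kullback-Leibler) screening of k-mer vocabularies.
#
# The corpus-level distribution of each class is the pooled count of every
# k-mer across all sequences of that class, normalized once (this is not
# the mean of per-sequence frequencies).  The divergence between the two
# class distributions, D(p, q) = sum_i p(i) ln(p(i)/q(i)), decomposes into
# one signed term per k-mer; sorting those terms in descending order and
# keeping the shortest prefix whose cumulative share of D reaches R_target
# (default 98%) yields the screened vocabulary.

#' Pooled corpus-level k-mer distribution of one class
#'
#' Pools raw sliding-window counts across all records, adds a pseudocount
#' to every cell, and normalizes once.  The pseudocount (default 1)
#' guards the divergence against zero cells in the reference distribution,
#' which are common for large k.
#'
#' @param records a [seq_records] table (all of one class).
#' @param ks window length(s); for combined ks the pooled counts of all
#'   blocks are normalized together so `probs` still sums to 1.
#' @param pseudocount added to every vocabulary cell before normalizing.
#' @param class_label optional label (0/1) recorded in the result.
#' @return object of class `"class_distribution"`: list with `vocab`,
#'   `probs` (named, sums to 1), `counts` (raw pooled counts),
#'   `n_sequences`, `class_label`.
#' @export
class_distribution <- function(records, ks = 5, pseudocount = 1,
                               class_label = NA_integer_) {
  if (nrow(records) == 0) stop("class_distribution needs at least one record")
  vocab <- kmer_vocabulary(ks)
  counts <- numeric(vocab$size)
  for (i in seq_len(nrow(records))) {
    counts <- counts + unlist(
      lapply(vocab$ks, function(k) as.numeric(count_kmers(records$sequence[i], k))),
      use.names = FALSE)
  }
  names(counts) <- vocab$kmers
  if (sum(counts) == 0 && pseudocount == 0) {
    stop("zero total k-mer count and no pseudocount; distribution undefined")
  }
  sm <- counts + pseudocount
  structure(
    list(vocab = vocab, probs = sm / sum(sm), counts = counts,
         n_sequences = nrow(records), class_label = class_label),
    class = "class_distribution"
  )
}

#' @export
print.class_distribution <- function(x, ...) {
  cat("class_distribution (", label_name(x$class_label), "): ",
      x$vocab$size, " k-mers pooled over ", x$n_sequences, " sequences\n",
      sep = "")
  invisible(x)
}

# Accept either a class_distribution or a bare (named) probability vector.
dist_probs <- function(x) {
  if (inherits(x, "class_distribution")) return(x$probs)
  stopifnot(is.numeric(x), all(x >= 0))
  x
}

check_same_support <- function(p, q) {
  if (length(p) != length(q)) stop("distributions have different vocabulary sizes")
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    stop("distributions are over different vocabularies")
  }
}

#' Per-k-mer divergence terms
#'
#' The signed contribution of each k-mer to the relative entropy,
#' `d = p(i) * ln(p(i) / q(i))`, with the `0 * ln 0 = 0` convention.  `p`
#' is the reference (lncRNA) distribution.
#'
#' @param p,q class distributions ([class_distribution] or bare probability
#'   vectors over the same vocabulary); `q` must be strictly positive
#'   wherever `p` is (guaranteed by the pseudocount).
#' @return named numeric vector of signed terms; `sum()` of it is the
#'   relative entropy.
#' @export
per_kmer_divergence <- function(p, q) {
  pp <- dist_probs(p); qq <- dist_probs(q)
  check_same_support(pp, qq)
  d <- numeric(length(pp))
  pos <- pp > 0
  if (any(pos & qq == 0)) stop("q has zero mass where p is positive; use a pseudocount")
  d[pos] <- pp[pos] * log(pp[pos] / qq[pos])
  names(d) <- names(pp)
  d
}

#' Relative entropy between two class distributions
#'
#' `D(p, q) = sum_i p(i) ln(p(i)/q(i))` (natural log).  Zero iff the
#' distributions coincide, and always nonnegative.
#'
#' @inheritParams per_kmer_divergence
#' @return a single nonnegative number.
#' @export
relative_entropy <- function(p, q) {
  sum(per_kmer_divergence(p, q))
}

#' Screen k-mers by descending divergence contribution
#'
#' Sorts the per-k-mer divergence terms in descending order (ties broken by
#' canonical vocabulary position), accumulates their share of the total
#' relative entropy, and keeps the shortest prefix whose cumulative ratio R
#' reaches `R_target`.  Negative terms take part in the running sum, so the
#' cumulative ratio can exceed 1 before settling back; the FIRST crossing
#' of `R_target` is taken.
#'
#' @inheritParams per_kmer_divergence
#' @param R_target cumulative information ratio in (0, 1], default 0.98.
#' @return object of class `"screening_result"`: `d_terms` (vocabulary
#'   order), `order` (permutation, descending d), `D_total`, `R_curve`
#'   (after each rank), `cutoff_rank`, `kept` (screened [kmer_vocabulary]
#'   when `p` carries one, else the kept k-mer names), `R_target`.
#' @export
select_kmers <- function(p, q, R_target = 0.98) {
  if (!(R_target > 0 && R_target <= 1)) stop("R_target must be in (0, 1]")
  d <- per_kmer_divergence(p, q)
  D <- sum(d)
  nm <- names(d)
  if (is.null(nm)) nm <- as.character(seq_along(d))
  if (D <= 0) {
    warning("total relative entropy is ", signif(D, 3),
            "; screening undefined, keeping every k-mer")
    ord <- seq_along(d)
    cutoff <- length(d)
    R_curve <- rep(NA_real_, length(d))
  } else {
    ord <- order(d, decreasing = TRUE)  # stable: ties keep vocabulary order
    R_curve <- unname(cumsum(d[ord]) / D)
    cutoff <- unname(which(R_curve >= R_target)[1])
    if (is.na(cutoff)) cutoff <- length(d)
  }
  kept_names <- sort_to_vocab(nm[ord[seq_len(cutoff)]], nm)
  kept <- if (inherits(p, "class_distribution")) {
    subset_vocabulary(p$vocab, kept_names)
  } else kept_names
  structure(
    list(d_terms = d, order = ord, D_total = D, R_curve = R_curve,
         cutoff_rank = cutoff, kept = kept, R_target = R_target),
    class = "screening_result"
  )
}

sort_to_vocab <- function(x, vocab_names) x[order(match(x, vocab_names))]

#' @export
print.screening_result <- function(x, ...) {
  cat("screening_result: kept ", x$cutoff_rank, " of ", length(x$d_terms),
      " k-mers (R >= ", x$R_target, ", D = ", signif(x$D_total, 4), ")\n",
      sep = "")
  invisible(x)
}

#' Write a screening report as TSV
#'
#' One row per rank: `rank`, `kmer`, `d`, `cumulative_R`, `kept`.
#'
#' @param screening a [select_kmers] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(screening, path) {
  nm <- names(screening$d_terms)
  if (is.null(nm)) nm <- as.character(seq_along(screening$d_terms))
  df <- data.frame(
    rank = seq_along(screening$order),
    kmer = nm[screening$order],
    d = screening$d_terms[screening$order],
    cumulative_R = screening$R_curve,
    kept = seq_along(screening$order) <= screening$cutoff_rank
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a kept vocabulary as a plain text file (one k-mer per line)
#'
#' @param vocab a [kmer_vocabulary] (e.g. the `kept` slot of a screening).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  kmers <- if (inherits(vocab, "kmer_vocab")) vocab$kmers else as.character(vocab)
  writeLines(kmers, path)
  invisible(path)
}

#' Read a vocabulary file written by [write_vocabulary]
#'
#' @param path text file with one k-mer per line.
#' @return a screened [kmer_vocabulary].
#' @export
read_vocabulary <- function(path) {
  kmers <- readLines(path)
  kmers <- kmers[nzchar(kmers)]
  full <- kmer_vocabulary(unique(nchar(kmers)))
  subset_vocabulary(full, kmers)
}
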