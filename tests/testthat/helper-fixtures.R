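# Shared fixtures: built in code, nothing read from disk.

# The 23-nt sequence whose 21 overlapping 3-mer windows are the sliding
# window illustration (GCC and CCA three times, CAG twice).
fig_sequence <- function() "GCCAACGCCAGGCCGACCAGTTC"

# The 21 windows of fig_sequence(), in order; overlapping them is an
# independent reconstruction of the sequence.
fig_windows <- function() {
  c("GCC", "CCA", "CAA", "AAC", "ACG", "CGC", "GCC", "CCA", "CAG", "AGG",
    "GGC", "GCC", "CCG", "CGA", "GAC", "ACC", "CCA", "CAG", "AGT", "GTT",
    "TTC")
}

random_clean_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Independent sliding-window counting oracle: plain substring loop,
# skipping windows that contain non-ACGT characters.
oracle_count_kmers <- function(sequence, k) {
  vocab <- enumerate_kmers(k)
  counts <- stats::setNames(integer(length(vocab)), vocab)
  m <- nchar(sequence)
  if (m >= k) {
    for (i in 1:(m - k + 1)) {
      w <- substr(sequence, i, i + k - 1)
      if (grepl("^[ACGT]+$", w)) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# O(n^2) concordant-pair AUC oracle (ties count one half).  Positive class
# is lncRNA (label 0); higher score means more positive.
oracle_pair_auc <- function(truth, scores) {
  pos <- which(truth == 0)
  neg <- which(truth == 1)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# Two-symbol toy distributions for the screening arithmetic.
toy_p <- function() c(s1 = 0.5, s2 = 0.5)
toy_q <- function() c(s1 = 0.25, s2 = 0.75)

# Small fast corpus: full composition contrast but short sequences, so
# featurization stays cheap in unit tests.
small_corpus <- function(n_per_class = 60, divergence = 1, seed = 5) {
  simulate_corpus(n_per_class, divergence = divergence,
                  length_range = list(lncRNA = c(200, 400),
                                      mRNA = c(200, 400)),
                  seed = seed)
}

# Run the package CLI script in a child R process with the test library
# visible; returns list(status, stdout lines).
run_cli <- function(args, workdir) {
  script <- system.file("scripts", "kmercnn.R", package = "kmerCNN")
  stopifnot(nzchar(script))
  out_file <- tempfile()
  status <- withr::with_dir(workdir, system2(
    file.path(R.home("bin"), "Rscript"), c(script, args),
    stdout = out_file, stderr = out_file,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = status, output = readLines(out_file, warn = FALSE))
}
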