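test_that("vocabulary enumeration follows the A,T,C,G digit order", {
  expect_equal(enumerate_kmers(1), c("A", "T", "C", "G"))
  k3 <- enumerate_kmers(3)
  expect_length(k3, 64)
  expect_equal(k3[1:4], c("AAA", "AAT", "AAC", "AAG"))
  expect_equal(k3[5:8], c("ATA", "ATT", "ATC", "ATG"))
  expect_equal(k3[61:64], c("GGA", "GGT", "GGC", "GGG"))
  expect_length(enumerate_kmers(2), 16)
  expect_error(enumerate_kmers(0), "k must be")
})

test_that("vocabulary index is the base-4 integer with digits A,T,C,G", {
  # independent oracle: sort all k-mers by their base-4 value under the
  # digit map A=0, T=1, C=2, G=3
  digit <- c(A = 0, T = 1, C = 2, G = 3)
  for (k in 1:3) {
    kmers <- enumerate_kmers(k)
    value <- vapply(strsplit(kmers, ""), function(ch) {
      sum(digit[ch] * 4^((k - 1):0))
    }, numeric(1))
    expect_equal(value, seq_along(kmers) - 1)
    expect_false(anyDuplicated(kmers) > 0)
  }
})

test_that("combined vocabularies concatenate ascending k blocks", {
  v <- kmer_vocabulary(c(3, 1, 2))
  expect_equal(v$ks, 1:3)
  expect_equal(v$size, 84)
  expect_equal(v$kmers[1:4], c("A", "T", "C", "G"))
  expect_equal(v$k_of, rep(1:3, c(4, 16, 64)))
})

test_that("sliding-window counting matches the worked 3-mer example", {
  counts <- count_kmers(fig_sequence(), 3)
  expect_equal(attr(counts, "total"), 21L)
  expect_equal(unname(counts[c("GCC", "CCA", "CAG", "GTT")]), c(3L, 3L, 2L, 1L))
  # every window of the printed list is recovered
  expect_equal(counts[counts > 0], table(fig_windows())[names(counts[counts > 0])],
               ignore_attr = TRUE)
})

test_that("counting matches an independent substring oracle with m-k+1 windows", {
  set.seed(101)
  for (i in 1:25) {
    k <- sample(1:4, 1)
    m <- sample(k:60, 1)
    s <- random_clean_sequence(m)
    counts <- count_kmers(s, k)
    expect_equal(as.integer(counts), as.integer(oracle_count_kmers(s, k)))
    expect_equal(sum(counts), m - k + 1)
  }
})

test_that("windows containing ambiguous bases are skipped, not imputed", {
  counts <- count_kmers("ACNGT", 2)
  expect_equal(unname(counts[c("AC", "GT")]), c(1L, 1L))
  expect_equal(attr(counts, "total"), 2L)
  expect_equal(as.integer(count_kmers("ACNGT", 2)),
               as.integer(oracle_count_kmers("ACNGT", 2)))
  # k longer than the sequence: all-zero with zero total
  short <- count_kmers("ACG", 5)
  expect_true(all(short == 0L))
  expect_equal(attr(short, "total"), 0L)
})

test_that("frequency vectors normalize per k block", {
  v <- frequency_vector(fig_sequence(), ks = 3)
  expect_equal(as.numeric(v["GCC"]), 3 / 21)
  expect_equal(sum(v), 1, tolerance = 1e-12)

  v123 <- frequency_vector(fig_sequence(), ks = 1:3)
  expect_length(v123, 84)
  expect_equal(unname(attr(v123, "per_k_sums")), c(1, 1, 1), tolerance = 1e-12)
  expect_false(attr(v123, "flagged"))

  va <- frequency_vector("AAAA", ks = 1)
  expect_equal(as.numeric(va), c(1, 0, 0, 0))

  # degenerate input is flagged rather than an error
  v0 <- frequency_vector("AC", ks = 3)
  expect_true(all(v0 == 0))
  expect_true(attr(v0, "flagged"))
})

test_that("screened vocabularies keep pre-screening frequencies", {
  full <- kmer_vocabulary(3)
  kept <- subset_vocabulary(full, c("GCC", "CCA", "CAG"))
  v <- frequency_vector(fig_sequence(), vocab = kept)
  expect_equal(names(v), c("CAG", "CCA", "GCC"))  # canonical order restored
  expect_equal(as.numeric(v), c(2, 3, 3) / 21)
  expect_error(subset_vocabulary(full, "AAAAA"), "not in vocabulary")
})

test_that("matrix shapes follow the registry then the most-square rule", {
  expect_equal(matrix_shape_for(64), c(8L, 8L))
  expect_equal(matrix_shape_for(256), c(16L, 16L))
  expect_equal(matrix_shape_for(84), c(7L, 12L))
  expect_equal(matrix_shape_for(115), c(5L, 23L))
  expect_equal(matrix_shape_for(68), c(17L, 4L))
  # unregistered: brute-force most-square pair with rows <= cols
  expect_equal(matrix_shape_for(12), c(3L, 4L))
  expect_equal(matrix_shape_for(36), c(6L, 6L))
  expect_equal(matrix_shape_for(30), c(5L, 6L))
  # primes > 3 are padded to the next factorable size
  expect_equal(matrix_shape_for(13), c(2L, 7L))
  expect_equal(matrix_shape_for(3), c(1L, 3L))
  expect_error(matrix_shape_for(0), "n_features")
})

test_that("matrix layout is row-major with exact zero padding", {
  vec <- frequency_vector(fig_sequence(), ks = 1:3)
  m <- to_matrix(vec, c(7, 12))
  expect_equal(m[1, ], unname(vec[1:12]))
  expect_equal(sum(m), sum(vec))  # conservation: three blocks summing to 1
  expect_equal(sum(m), 3, tolerance = 1e-12)

  m2 <- to_matrix(c(1, 2, 3), c(2, 2))
  expect_identical(m2[2, 2], 0)
  expect_error(to_matrix(1:5, c(2, 2)), "cannot hold")

  # flatten (row-major) inverts the layout
  set.seed(1)
  v <- runif(30)
  expect_equal(as.vector(t(to_matrix(v, c(5, 6)))), v)
})

test_that("mean frequencies are per-sequence means and match the chain oracle", {
  rec2 <- seq_records(c("a", "b"), c("AA", "CC"))
  expect_equal(unname(mean_frequencies(rec2, 1)), c(0.5, 0, 0.5, 0))

  twin <- seq_records(c("a", "b"), rep(fig_sequence(), 2))
  expect_equal(mean_frequencies(twin, 3),
               frequency_vector(fig_sequence(), ks = 3),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(mean_frequencies(seq_records(character(0), character(0)), 1),
               "at least one")

  # Monte-Carlo oracle: means of long Markov sequences converge to the
  # chain-implied window probabilities
  prof <- default_profiles()$lncRNA
  rec <- simulate_corpus(100, divergence = 0,
                         length_range = list(lncRNA = c(900, 1100),
                                             mRNA = c(900, 1100)),
                         seed = 31)
  rec <- rec[rec$label == 0, ]
  ft <- frequency_table(rec, ks = 2)
  means <- colMeans(ft)
  se <- apply(ft, 2, stats::sd) / sqrt(nrow(ft))
  for (km in c("AA", "CG", "GC", "TT")) {
    expect_lt(abs(means[km] - kmer_window_probability(prof, km)),
              3 * se[km] + 1e-4)
  }
})
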