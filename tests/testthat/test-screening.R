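test_that("class distributions pool corpus counts, then normalize once", {
  rec <- seq_records("a", "AAAA", label = 0L)
  d <- class_distribution(rec, ks = 1, pseudocount = 0)
  expect_s3_class(d, "class_distribution")
  expect_equal(unname(d$probs), c(1, 0, 0, 0))
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)

  rec2 <- seq_records(c("a", "b"), c("AA", "TT"))
  d2 <- class_distribution(rec2, ks = 1, pseudocount = 0)
  expect_equal(unname(d2$probs), c(0.5, 0.5, 0, 0))

  # pooling weights sequences by their window counts (corpus-level, not
  # mean-of-frequencies): 6 A-windows from "AAAAAA" + 1 T-window from "TT"
  rec3 <- seq_records(c("a", "b"), c("AAAAAA", "TT"))
  d3 <- class_distribution(rec3, ks = 1, pseudocount = 0)
  expect_equal(unname(d3$probs), c(6 / 8, 2 / 8, 0, 0))

  expect_error(class_distribution(rec2[0, ], ks = 1), "at least one")
})

test_that("pseudocount smoothing keeps all cells strictly positive", {
  rec <- seq_records("a", "AAAA", label = 0L)
  d <- class_distribution(rec, ks = 1, pseudocount = 1)
  expect_true(all(d$probs > 0))
  expect_equal(unname(d$probs), c(5, 1, 1, 1) / 8)
})

test_that("pooled distribution converges to the chain window probabilities", {
  prof <- default_profiles()
  rec <- simulate_corpus(200, length_range = list(lncRNA = c(400, 600),
                                                  mRNA = c(400, 600)),
                         seed = 17)
  d0 <- class_distribution(rec[rec$label == 0, ], ks = 2, pseudocount = 0)
  # corpus-level pooling averages ~100k windows; 3 SE of a binomial
  # proportion at that depth is ~0.005
  for (km in c("AT", "CG", "GG")) {
    p_hat <- d0$probs[km]
    p_true <- kmer_window_probability(prof$lncRNA, km)
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 1e5) + 1e-3)
  }
})

test_that("relative entropy matches hand arithmetic and KL properties", {
  expect_equal(relative_entropy(toy_p(), toy_p()), 0)
  # 0.5 ln 2 + 0.5 ln(2/3)
  expect_equal(relative_entropy(toy_p(), toy_q()),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(relative_entropy(toy_p(), toy_q()), 0.14384, tolerance = 1e-5)

  d <- per_kmer_divergence(toy_p(), toy_q())
  expect_equal(unname(d), c(0.34657, -0.20273), tolerance = 1e-4)
  expect_equal(sum(d), relative_entropy(toy_p(), toy_q()))

  expect_error(relative_entropy(c(0.5, 0.5), c(0.2, 0.3, 0.5)),
               "different vocabulary sizes")
  expect_error(per_kmer_divergence(c(0.5, 0.5), c(1, 0)), "zero mass")
})

test_that("divergence is nonnegative and decomposes exactly (property)", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(2:64, 1)
    p <- stats::runif(n); p <- p / sum(p)
    q <- stats::runif(n) + 1e-3; q <- q / sum(q)
    d <- per_kmer_divergence(p, q)
    expect_gte(sum(d), 0)                       # Gibbs' inequality
    expect_identical(sum(d), relative_entropy(p, q))  # exact by construction
  }
  # zero term convention: p(i) = 0 contributes 0
  expect_equal(unname(per_kmer_divergence(c(0, 1), c(0.5, 0.5))[1]), 0)
})

test_that("screening keeps the minimal prefix reaching the target ratio", {
  sel <- select_kmers(toy_p(), toy_q(), R_target = 0.98)
  # the first term alone exceeds 0.98 D because the second is negative
  expect_equal(sel$cutoff_rank, 1L)
  expect_equal(sel$kept, "s1")
  expect_gte(sel$R_curve[1], 0.98)
  expect_equal(sel$R_curve[2], 1, tolerance = 1e-12)

  # all-positive divergence terms with R_target = 1 keep everything
  p <- c(a = 0.7, b = 0.2, c = 0.1)
  q <- c(a = 0.2, b = 0.1, c = 0.7)
  sel1 <- select_kmers(p, q, R_target = 1)
  expect_equal(sel1$cutoff_rank,
               unname(which(cumsum(sort(per_kmer_divergence(p, q),
                                        decreasing = TRUE)) /
                              relative_entropy(p, q) >= 1)[1]))
  expect_error(select_kmers(p, q, R_target = 0), "R_target")
})

test_that("identical classes make screening degenerate with a warning", {
  expect_warning(sel <- select_kmers(toy_p(), toy_p()), "keeping every")
  expect_equal(sel$cutoff_rank, 2L)
  expect_equal(sel$kept, c("s1", "s2"))
})

test_that("a planted divergent block occupies the top ranks", {
  set.seed(41)
  vocab <- kmer_vocabulary(3)
  base <- stats::runif(64, 0.5, 1.5)
  p_raw <- base
  planted <- c("GCC", "CCA", "CAG", "AGG")
  ip <- match(planted, vocab$kmers)
  p_raw[ip] <- p_raw[ip] * 6  # one strongly enriched block in class p
  p <- stats::setNames(p_raw / sum(p_raw), vocab$kmers)
  q <- stats::setNames(base / sum(base), vocab$kmers)
  sel <- select_kmers(p, q, R_target = 0.98)
  expect_setequal(names(sel$d_terms)[sel$order[1:4]], planted)
  # re-screening the kept subset (same underlying masses) is stable: the
  # planted block stays on top and nothing outside the kept set appears
  kept1 <- names(sel$d_terms)[sel$order[seq_len(sel$cutoff_rank)]]
  sel2 <- select_kmers(p[kept1], q[kept1], R_target = 0.98)
  kept2 <- names(sel2$d_terms)[sel2$order[seq_len(sel2$cutoff_rank)]]
  expect_true(all(kept2 %in% kept1))
  top2 <- names(sel2$d_terms)[sel2$order[seq_len(min(4, length(kept1)))]]
  expect_true(all(top2 %in% planted))
})

test_that("screening result round-trips through report and vocabulary files", {
  rec0 <- small_corpus(20, seed = 7)
  p <- class_distribution(rec0[rec0$label == 0, ], ks = 2, class_label = 0L)
  q <- class_distribution(rec0[rec0$label == 1, ], ks = 2, class_label = 1L)
  sel <- select_kmers(p, q)
  expect_s3_class(sel$kept, "kmer_vocab")
  expect_lte(sel$kept$size, 16)
  # kept vocabulary preserves canonical order
  expect_equal(sel$kept$kmers,
               intersect(kmer_vocabulary(2)$kmers, sel$kept$kmers))

  rep_path <- withr::local_tempfile(fileext = ".tsv")
  write_screening_report(sel, rep_path)
  tab <- utils::read.delim(rep_path)
  expect_equal(nrow(tab), 16)
  expect_equal(sum(tab$kept), sel$cutoff_rank)
  expect_equal(tab$d, sort(sel$d_terms, decreasing = TRUE),
               ignore_attr = TRUE, tolerance = 1e-9)

  voc_path <- withr::local_tempfile(fileext = ".txt")
  write_vocabulary(sel$kept, voc_path)
  expect_equal(read_vocabulary(voc_path)$kmers, sel$kept$kmers)
})
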