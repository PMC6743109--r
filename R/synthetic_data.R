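# Synthetic two-class sequence corpora from first-order Markov chains.
#
# The default profiles emulate the composition contrast the classifier
# exploits in real transcriptomes: an AT-leaning lncRNA-like class and a
# GC-leaning mRNA-like class, both with the CpG (C->G) step suppressed as
# in vertebrate sequence.  First-order chains are deliberate: they create
# the 1/2/3-mer contrasts the method uses while staying analytically
# tractable, so chain-implied window probabilities serve as exact oracles
# for the counting and screening stages.

#' Default lncRNA-like and mRNA-like Markov profiles
#'
#' Each profile is a list with `init` (initial base distribution) and
#' `trans` (4 x 4 row-stochastic transition matrix), both over A, T, C, G.
#' Target compositions: lncRNA-like about 27/26/23/23 % A/T/C/G, mRNA-like
#' about 24/22/27/27 %; the C->G transition is reduced to a quarter of its
#' compositional value in both classes.
#'
#' @return list with elements `lncRNA` and `mRNA`.
#' @export
default_profiles <- function() {
  comp_lnc <- c(A = 254, T = 240, C = 217, G = 216) / 927
  comp_m <- c(A = 364, T = 343, C = 420, G = 422) / 1549
  list(lncRNA = markov_profile(comp_lnc, cg_factor = 0.25),
       mRNA = markov_profile(comp_m, cg_factor = 0.25))
}

#' Build a Markov profile from a base composition
#'
#' Rows of the transition matrix start proportional to the composition
#' (an i.i.d. chain), then the C->G entry is multiplied by `cg_factor`
#' and row C renormalized, producing CpG suppression.
#'
#' @param composition named nonnegative vector over A, T, C, G.
#' @param cg_factor multiplier on the C->G transition (1 = no suppression).
#' @return list with `init` and row-stochastic `trans`.
#' @export
markov_profile <- function(composition, cg_factor = 1) {
  stopifnot(setequal(names(composition), c("A", "T", "C", "G")),
            all(composition >= 0), sum(composition) > 0, cg_factor >= 0)
  comp <- composition[c("A", "T", "C", "G")] / sum(composition)
  trans <- matrix(rep(comp, each = 4), 4, 4,
                  dimnames = list(names(comp), names(comp)))
  trans["C", "G"] <- trans["C", "G"] * cg_factor
  trans["C", ] <- trans["C", ] / sum(trans["C", ])
  list(init = comp, trans = trans)
}

check_profile <- function(profile) {
  stopifnot(is.list(profile), !is.null(profile$init), !is.null(profile$trans))
  if (any(abs(rowSums(profile$trans) - 1) > 1e-8) || any(profile$trans < 0)) {
    stop("transition rows must be nonnegative and sum to 1")
  }
  if (abs(sum(profile$init) - 1) > 1e-8 || any(profile$init < 0)) {
    stop("initial distribution must be nonnegative and sum to 1")
  }
  invisible(profile)
}

#' Mix two Markov profiles
#'
#' Convex combination `knob * b + (1 - knob) * a` of both the initial and
#' transition tables; `knob = 0` reproduces `a` exactly, so two classes
#' generated from `a` and `mix_profiles(a, b, 0)` are statistically
#' identical.
#'
#' @param a,b Markov profiles.
#' @param knob mixing weight in \[0, 1\].
#' @return a Markov profile.
#' @export
mix_profiles <- function(a, b, knob) {
  stopifnot(knob >= 0, knob <= 1)
  check_profile(a); check_profile(b)
  list(init = (1 - knob) * a$init + knob * b$init,
       trans = (1 - knob) * a$trans + knob * b$trans)
}

#' Generate a labeled two-class corpus
#'
#' Class 0 (lncRNA-like) is drawn from `profiles$lncRNA`; class 1
#' (mRNA-like) from `mix_profiles(profiles$lncRNA, profiles$mRNA,
#' divergence)`, so `divergence = 1` gives the full contrast and
#' `divergence = 0` two statistically identical classes.  Lengths are
#' uniform on the per-class ranges (defaults 250-3500 nt for the
#' lncRNA-like class, 200-4000 nt for the mRNA-like class).
#'
#' @param n_per_class sequences per class.
#' @param profiles list with `lncRNA` and `mRNA` Markov profiles.
#' @param divergence contrast knob in \[0, 1\].
#' @param length_range list with per-class `c(min, max)` nt.
#' @param seed RNG seed; the corpus is a deterministic function of the
#'   arguments.
#' @return a labeled [seq_records] table of `2 * n_per_class` rows.
#' @export
simulate_corpus <- function(n_per_class, profiles = default_profiles(),
                            divergence = 1,
                            length_range = list(lncRNA = c(250, 3500),
                                                mRNA = c(200, 4000)),
                            seed = 1L) {
  stopifnot(n_per_class >= 1)
  check_profile(profiles$lncRNA); check_profile(profiles$mRNA)
  set.seed(seed)
  p0 <- profiles$lncRNA
  p1 <- mix_profiles(profiles$lncRNA, profiles$mRNA, divergence)
  len0 <- sample(length_range$lncRNA[1]:length_range$lncRNA[2],
                 n_per_class, replace = TRUE)
  len1 <- sample(length_range$mRNA[1]:length_range$mRNA[2],
                 n_per_class, replace = TRUE)
  seqs0 <- markov_sequences(p0, len0)
  seqs1 <- markov_sequences(p1, len1)
  seq_records(
    id = c(sprintf("lnc_%04d", seq_len(n_per_class)),
           sprintf("mrna_%04d", seq_len(n_per_class))),
    sequence = c(seqs0, seqs1),
    label = rep(c(LABEL_LNCRNA, LABEL_MRNA), each = n_per_class))
}

# Draw n sequences of the given lengths from one chain.  Vectorized across
# sequences: one inverse-CDF step per position over all sequences at once.
markov_sequences <- function(profile, lengths) {
  bases <- c("A", "T", "C", "G")
  trans <- profile$trans[bases, bases]
  cum <- t(apply(trans, 1, cumsum))
  n <- length(lengths)
  maxlen <- max(lengths)
  state <- matrix(0L, n, maxlen)
  ci <- cumsum(profile$init[bases])
  u <- stats::runif(n)
  state[, 1] <- 1L + (u > ci[1]) + (u > ci[2]) + (u > ci[3])
  for (t in seq_len(maxlen - 1L) + 1L) {
    u <- stats::runif(n)
    s <- state[, t - 1L]
    state[, t] <- 1L + (u > cum[s, 1]) + (u > cum[s, 2]) + (u > cum[s, 3])
  }
  vapply(seq_len(n), function(i) {
    paste(bases[state[i, seq_len(lengths[i])]], collapse = "")
  }, character(1))
}

#' Stationary distribution of a transition matrix
#'
#' @param trans row-stochastic matrix.
#' @return named probability vector solving `pi = pi %*% trans`.
#' @export
stationary_distribution <- function(trans) {
  e <- eigen(t(trans))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(trans))
}

#' Chain-implied probability of a k-mer window
#'
#' The probability that a stationary window of the chain spells `kmer`:
#' `pi(x1) * prod trans(x_i, x_{i+1})`.  This is the analytic limit of the
#' empirical k-mer frequency on long sequences, used as a Monte-Carlo
#' oracle by the test suite.
#'
#' @param profile a Markov profile.
#' @param kmer k-mer string over A/C/G/T.
#' @return probability.
#' @export
kmer_window_probability <- function(profile, kmer) {
  chars <- strsplit(kmer, "")[[1]]
  stopifnot(all(chars %in% c("A", "C", "G", "T")))
  pi0 <- stationary_distribution(profile$trans)
  p <- pi0[chars[1]]
  for (i in seq_along(chars)[-1]) {
    p <- p * profile$trans[chars[i - 1], chars[i]]
  }
  unname(p)
}
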