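#' Kullback-Leibler divergence between compositions
#'
#' `sum(p * log(p/q))` with natural logarithms; terms with `p_i = 0`
#' contribute 0 (the `0 * log 0 := 0` convention). Under the multinomial
#' word-count model this is, up to the factor `L` (total word count), the
#' exact negative log-likelihood of observing composition `p` when words are
#' drawn from pool `q`, which is why it serves as the assignment cost of the
#' EM clustering.
#'
#' @param p,q Non-negative numeric vectors on the simplex (summing to 1).
#' @return A single non-negative number.
#' @examples
#' kl_divergence(c(.5, .5, 0, 0), rep(.25, 4)) # log 2
#' @export
kl_divergence <- function(p, q) {
  check_same_length(p, q)
  pos <- p > 0
  if (any(pos & q == 0)) {
    rlang::abort(sprintf(
      "infinite divergence: q is zero at word index %d where p > 0.",
      which(pos & q == 0)[1L]
    ))
  }
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Symmetrized Kullback-Leibler distance
#'
#' `sum((p - q) * log(p/q))`, identically equal to
#' `kl_divergence(p, q) + kl_divergence(q, p)`. Requires mutual support:
#' a component where exactly one of `p`, `q` vanishes makes the distance
#' infinite and is an error.
#'
#' @inheritParams kl_divergence
#' @return A single non-negative number, symmetric in its arguments.
#' @export
sym_kl_distance <- function(p, q) {
  check_same_length(p, q)
  one_sided <- xor(p == 0, q == 0)
  if (any(one_sided)) {
    rlang::abort(sprintf(
      "infinite divergence: one-sided zero support at word index %d.",
      which(one_sided)[1L]
    ))
  }
  both <- p > 0 & q > 0
  sum((p[both] - q[both]) * log(p[both] / q[both]))
}

#' Euclidean (L2) distance
#'
#' @inheritParams kl_divergence
#' @return A single non-negative number.
#' @export
l2_distance <- function(p, q) {
  check_same_length(p, q)
  sqrt(sum((p - q)^2))
}

#' d2 dissimilarity (one minus cosine)
#'
#' `1 - cos(theta)` for the angle between the two vectors. Scale-invariant,
#' hence insensitive to read length; lies in `[0, 1]` for non-negative
#' inputs.
#'
#' @param c,q Numeric vectors with nonzero norm (counts or frequencies).
#' @return A single number in `[0, 2]` (in `[0, 1]` for non-negative inputs).
#' @export
d2_distance <- function(c, q) {
  check_same_length(c, q)
  nc <- sqrt(sum(c^2)); nq <- sqrt(sum(q^2))
  if (nc == 0 || nq == 0) rlang::abort("d2 distance undefined for a zero-norm vector.")
  1 - sum(c * q) / (nc * nq)
}

#' Expected word frequencies under a zero-order Markov model
#'
#' The expected frequency of an n-mer is the product of the frequencies of
#' its individual bases. Used as the null composition `Q` by the d2* and
#' chi-squared dissimilarities.
#'
#' @param base_freqs Length-4 numeric vector of `A, C, G, T` frequencies on
#'   the simplex.
#' @param n Word length.
#' @return Named numeric vector of length `4^n` (lexicographic word order),
#'   summing to 1.
#' @examples
#' zero_order_expected_frequencies(rep(.25, 4), 2)
#' @export
zero_order_expected_frequencies <- function(base_freqs, n) {
  if (length(base_freqs) != 4L) rlang::abort("`base_freqs` must have length 4 (A, C, G, T).")
  if (any(base_freqs < 0)) rlang::abort("base frequencies must be non-negative.")
  f <- stats::setNames(as.numeric(base_freqs), c("A", "C", "G", "T"))
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), n)
  q <- vapply(
    strsplit(words, "", fixed = TRUE),
    function(ch) prod(f[ch]),
    numeric(1)
  )
  stats::setNames(q, words)
}

#' Standardize a count vector against expected frequencies
#'
#' Component-wise `(x_i - Q_i * S) / sqrt(Q_i * S)` with `S = sum(x)`: the
#' Poisson-motivated z-like score of observed versus expected counts.
#' Components with `Q_i = 0` and `x_i = 0` are set to 0.
#'
#' @param x Non-negative numeric count vector with positive sum.
#' @param Q Expected frequency vector (see
#'   [zero_order_expected_frequencies()]).
#' @return Numeric vector of the same length (entries may be negative).
#' @export
standardize <- function(x, Q) {
  check_same_length(x, Q)
  S <- sum(x)
  if (S <= 0) rlang::abort("cannot standardize an all-zero count vector.")
  if (any(Q == 0 & x > 0)) {
    rlang::abort(sprintf(
      "expected frequency is zero at word index %d where counts are positive.",
      which(Q == 0 & x > 0)[1L]
    ))
  }
  out <- numeric(length(x))
  pos <- Q > 0
  out[pos] <- (x[pos] - Q[pos] * S) / sqrt(Q[pos] * S)
  out
}

#' d2* dissimilarity between a sequence and a cluster
#'
#' Both the sequence count vector `c` and the cluster's pooled count vector
#' `x` are standardized against the same cluster-derived zero-order
#' expectation `Q` (see [standardize()]); the dissimilarity is
#' `(1 - cos(angle)) / 2` between the standardized vectors, so it lies in
#' `[0, 1]` even though standardized entries may be negative.
#'
#' @param c Sequence word counts.
#' @param x Cluster pooled word counts.
#' @param Q Expected frequencies from the cluster's base composition.
#' @return A single number in `[0, 1]`.
#' @export
d2star_distance <- function(c, x, Q) {
  ct <- standardize(c, Q)
  xt <- standardize(x, Q)
  nc <- sqrt(sum(ct^2)); nx <- sqrt(sum(xt^2))
  if (nc == 0 || nx == 0) rlang::abort("degenerate standardization: zero-norm standardized vector.")
  (1 - sum(ct * xt) / (nc * nx)) / 2
}

#' Chi-squared dissimilarity between counts and an expected composition
#'
#' `sum((c_i - Q_i L)^2 / (Q_i L))` with `L = sum(c)`: the Pearson statistic
#' of the observed word counts against the zero-order expectation `Q`.
#'
#' @param c Non-negative count vector with positive sum.
#' @param Q Expected frequency vector with `Q_i > 0` wherever `c_i > 0`.
#' @return A single non-negative number.
#' @export
chi2_distance <- function(c, Q) {
  check_same_length(c, Q)
  L <- sum(c)
  if (L <= 0) rlang::abort("chi-squared distance undefined for an all-zero count vector.")
  if (any(Q == 0 & c > 0)) {
    rlang::abort("expected frequency is zero at a word with positive counts.")
  }
  pos <- Q > 0
  sum((c[pos] - Q[pos] * L)^2 / (Q[pos] * L))
}

#' Gaussian-limit negative log-likelihood of word counts
#'
#' `sum((c_i - L q_i)^2 / (2 L q_i))`: the multivariate-normal limit of the
#' multinomial log-likelihood, valid when the composition `c/L` is close to
#' `q`. Provided as a limit-check oracle for `L * kl_divergence(c/L, q)`,
#' which it matches to first order in the perturbation.
#'
#' @param c Non-negative count vector.
#' @param q Simplex frequency vector with `q_i > 0` wherever `c_i > 0`.
#' @return A single non-negative number.
#' @export
gaussian_limit_neg_log_likelihood <- function(c, q) {
  check_same_length(c, q)
  if (any(q == 0 & c > 0)) {
    rlang::abort("infinite likelihood penalty: q is zero at a word with positive counts.")
  }
  L <- sum(c)
  pos <- q > 0
  sum((c[pos] - L * q[pos])^2 / (2 * L * q[pos]))
}

check_same_length <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort(sprintf("dimension mismatch: %d vs %d.", length(a), length(b)))
  }
  invisible(TRUE)
}
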