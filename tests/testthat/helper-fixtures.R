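# Shared fixtures: all data is generated in code, seeded for determinism.

# two-source read set with a controllable GC split
two_source_reads <- function(num_reads = 100, read_length = 100,
                             gc = c(0.3, 0.7), error_rate = 0, seed = 1) {
  src <- generate_sources(2, c(500, 1000), gc = gc, seed = seed)
  simulate_reads(src, num_reads, read_length, error_rate, seed = seed + 1)
}

# homopolymer-ish reads with disjoint composition (pure A vs pure T)
pure_base_reads <- function(copies = 10, len = 200) {
  tibble::tibble(
    read_id = c(paste0("a", seq_len(copies)), paste0("t", seq_len(copies))),
    seq = c(rep(strrep("A", len), copies), rep(strrep("T", len), copies)),
    source = rep(c("geneA", "geneT"), each = copies)
  )
}

# minimal soft partition wrapping a given membership matrix
fake_soft_partition <- function(Z) {
  if (is.null(rownames(Z))) rownames(Z) <- paste0("r", seq_len(nrow(Z)))
  structure(
    list(
      method = "soft_em", k = ncol(Z), spec = kmer_spec(1), pseudocount = 1,
      seed = 0L, read_id = rownames(Z), memberships = Z,
      centroids = matrix(1 / 4, ncol(Z), 4),
      expected_log_likelihood = 0, trace = 0, iterations = 1L, converged = TRUE,
      dropped = character()
    ),
    class = c("af_soft_partition", "af_partition")
  )
}

# random simplex vector (for property loops)
runif_simplex <- function(m) {
  x <- stats::runif(m)
  x / sum(x)
}

# independent hard-EM distortion: plain loops, no shared code with the
# clustering engine beyond k-mer counting of the input
brute_distortion <- function(C, z, K, pseudocount = 1) {
  D <- 0
  Q <- matrix(0, K, ncol(C))
  for (a in seq_len(K)) {
    pooled <- colSums(C[z == a, , drop = FALSE]) + pseudocount
    Q[a, ] <- pooled / sum(pooled)
  }
  for (r in seq_len(nrow(C))) {
    L <- sum(C[r, ])
    p <- C[r, ] / L
    for (i in seq_along(p)) {
      if (p[i] > 0) D <- D + L * p[i] * log(p[i] / Q[z[r], i])
    }
  }
  unname(D)
}

# global minimum distortion over all non-empty 2-cluster assignments
enumerate_min_distortion <- function(C, pseudocount = 1) {
  N <- nrow(C)
  best <- Inf
  for (code in seq_len(2^N - 2)) {
    z <- as.integer(intToBits(code))[seq_len(N)] + 1L
    if (length(unique(z)) < 2) next
    best <- min(best, brute_distortion(C, z, 2, pseudocount))
  }
  best
}

# the fixture on which the d2* centroid iteration provably cycles with
# period 2 (found by exhaustive search over initial assignments)
cycling_reads <- function() {
  tibble::tibble(
    read_id = paste0("r", 1:6),
    seq = c("TACGACAATGCA", "CGTAGTCTCGAT", "ACGTCATTGGTA",
            "CGAACAGTTCGT", "ATTCCCCATGTC", "TGGACCGACGTT")
  )
}
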