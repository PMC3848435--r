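test_that("hard EM separates disjoint compositions perfectly", {
  reads <- pure_base_reads(copies = 100, len = 200)
  fit <- af_cluster(reads, 2, method = "em", n = 1, seed = 1)
  expect_true(fit$converged)
  rr <- recall_rate(fit, reads)
  expect_equal(rr$recall, c(1, 1))
  # the two clusters are the two genes
  expect_equal(length(unique(fit$cluster[1:100])), 1)
  expect_equal(length(unique(fit$cluster[101:200])), 1)
})

test_that("single-cluster distortion equals the summed length-weighted KL", {
  reads <- two_source_reads(20, 100, seed = 5)
  fit <- af_cluster(reads, 1, method = "em", n = 2, seed = 2)
  C <- count_kmers(reads, kmer_spec(2))
  expect_equal(fit$distortion, brute_distortion(C, rep(1L, nrow(C)), 1), tolerance = 1e-10)
  # Eq-9-style identity: centroid is pooled pseudocounted counts, normalized
  pooled <- colSums(C) + 1
  expect_equal(unname(fit$centroids[1, ]), unname(pooled / sum(pooled)))
})

test_that("centroid update equals independently pooled member counts", {
  reads <- two_source_reads(60, 80, seed = 9)
  fit <- af_cluster(reads, 3, method = "em", n = 1, seed = 4)
  C <- count_kmers(reads, kmer_spec(1))
  for (a in 1:3) {
    pooled <- colSums(C[fit$cluster == a, , drop = FALSE]) + fit$pseudocount
    expect_equal(unname(fit$centroids[a, ]), unname(pooled / sum(pooled)))
  }
})

test_that("clustering is deterministic given a seed and restarts keep the best run", {
  reads <- two_source_reads(80, 60, gc = c(0.4, 0.6), seed = 3)
  f1 <- af_cluster(reads, 2, seed = 7)
  f2 <- af_cluster(reads, 2, seed = 7)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(f1$centroids, f2$centroids)

  singles <- vapply(0:4, function(r) af_cluster(reads, 2, seed = 7 + r)$distortion, 0)
  multi <- af_cluster(reads, 2, seed = 7, restarts = 5)
  expect_equal(multi$distortion, min(singles))
  expect_lte(multi$distortion, min(singles) + 1e-12)
})

test_that("hard EM distortion is non-increasing along the trace", {
  withr::with_seed(31, {
    for (rep in 1:15) {
      reads <- two_source_reads(60, 50, gc = sort(runif(2, 0.3, 0.7)),
                                seed = sample.int(1e6, 1))
      fit <- af_cluster(reads, sample(2:4, 1), n = sample(1:2, 1),
                        seed = sample.int(1e6, 1))
      expect_true(all(diff(fit$trace) <= 1e-9))
    }
  })
})

test_that("converged hard EM reaches the enumerated optimum on tiny instances", {
  withr::with_seed(32, {
    hits <- 0
    for (rep in 1:8) {
      reads <- two_source_reads(8, 60, gc = c(0.3, 0.7), seed = sample.int(1e6, 1))
      C <- count_kmers(reads, kmer_spec(1))
      best <- enumerate_min_distortion(C)
      fit <- af_cluster(reads, 2, n = 1, seed = sample.int(1e6, 1), restarts = 5)
      expect_gte(fit$distortion, best - 1e-8)
      if (abs(fit$distortion - best) < 1e-8) hits <- hits + 1
    }
    expect_gte(hits, 7) # well-separated sources: the optimum is found
  })
})

test_that("a converged hard partition is a fixed point of one more round", {
  reads <- two_source_reads(30, 60, gc = c(0.35, 0.65), seed = 41)
  fit <- af_cluster(reads, 2, n = 1, seed = 6)
  expect_true(fit$converged)
  C <- count_kmers(reads, kmer_spec(1))
  z <- fit$cluster
  # one more M + E round by independent arithmetic
  Q <- rbind(colSums(C[z == 1, , drop = FALSE]) + 1, colSums(C[z == 2, , drop = FALSE]) + 1)
  Q <- Q / rowSums(Q)
  cost <- sapply(1:2, function(a) {
    apply(C, 1, function(cc) {
      p <- cc / sum(cc)
      sum(cc[p > 0] * log(p[p > 0] / Q[a, p > 0]))
    })
  })
  expect_equal(max.col(-cost, ties.method = "first"), z)
})

test_that("small random perturbations of converged centroids never help", {
  reads <- two_source_reads(40, 80, seed = 51)
  fit <- af_cluster(reads, 2, n = 1, seed = 8)
  base <- distortion(fit, reads)
  C <- count_kmers(reads, kmer_spec(1))
  withr::with_seed(52, {
    for (rep in 1:10) {
      Qp <- fit$centroids * (1 + runif(length(fit$centroids), -0.02, 0.02))
      Qp <- Qp / rowSums(Qp)
      pert <- sum(vapply(seq_len(nrow(C)), function(r) {
        cc <- C[r, ]; p <- cc / sum(cc); a <- fit$cluster[r]
        sum(cc[p > 0] * log(p[p > 0] / Qp[a, p > 0]))
      }, 0))
      expect_gte(pert, base - 1e-9)
    }
  })
})

test_that("distortion recomputation is additive over clusters and matches manual sums", {
  reads <- two_source_reads(30, 60, seed = 61)
  fit <- af_cluster(reads, 2, n = 1, seed = 9)
  C <- count_kmers(reads, kmer_spec(1))
  manual <- brute_distortion(C, fit$cluster, 2)
  expect_equal(distortion(fit, reads), manual, tolerance = 1e-10)
  expect_equal(fit$distortion, manual, tolerance = 1e-10)
  # additivity: per-cluster contributions sum to the total
  parts <- vapply(1:2, function(a) {
    keep <- fit$cluster == a
    sum(vapply(which(keep), function(r) {
      cc <- C[r, ]; p <- cc / sum(cc)
      sum(cc[p > 0] * log(p[p > 0] / fit$centroids[a, p > 0]))
    }, 0))
  }, 0)
  expect_equal(sum(parts), manual, tolerance = 1e-10)
})

test_that("d2 centroid of axis-parallel reads is the unit axis vector", {
  reads <- tibble::tibble(read_id = paste0("r", 1:5), seq = strrep("A", c(20, 40, 60, 80, 100)))
  fit <- af_cluster(reads, 1, method = "d2", n = 1, seed = 1)
  expect_equal(unname(fit$centroids[1, ]), c(1, 0, 0, 0))
  expect_equal(fit$distortion, 0)
})

test_that("d2 centroid update is the renormalized sum of member unit vectors", {
  reads <- two_source_reads(30, 50, seed = 71)
  fit <- af_cluster(reads, 2, method = "d2", n = 1, seed = 3)
  U <- count_kmers(reads, kmer_spec(1))
  U <- U / sqrt(rowSums(U^2))
  for (a in 1:2) {
    v <- colSums(U[fit$cluster == a, , drop = FALSE])
    expect_equal(unname(fit$centroids[a, ]), unname(v / sqrt(sum(v^2))))
  }
})

test_that("l2 clustering of two point masses puts centroids on the points", {
  reads <- tibble::tibble(
    read_id = paste0("r", 1:6),
    seq = c(rep(strrep("A", 50), 3), rep(strrep("C", 50), 3))
  )
  fit <- af_cluster(reads, 2, method = "l2", n = 1, seed = 2)
  expect_equal(fit$distortion, 0)
  rows <- fit$centroids[order(fit$centroids[, 1], decreasing = TRUE), ]
  expect_equal(unname(rows[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(rows[2, ]), c(0, 1, 0, 0))
})

test_that("whitened k-means agrees with an independent Lloyd implementation", {
  reads <- two_source_reads(120, 80, gc = c(0.35, 0.65), seed = 81)
  fit <- af_cluster(reads, 2, method = "kmeans", n = 2, seed = 5)
  expect_true(all(diff(fit$trace) <= 1e-9)) # Lloyd monotonicity
  # independent check: stats::kmeans on the same whitened matrix
  P <- to_frequencies(count_kmers(reads, kmer_spec(2)), "simplex")
  W <- whiten_columns(P)$whitened
  ref <- stats::kmeans(W, centers = 2, nstart = 10)
  agree <- max(
    mean(fit$cluster == ref$cluster),
    mean(fit$cluster == (3 - ref$cluster))
  )
  expect_gte(agree, 0.99)
  rr <- recall_rate(fit, reads)
  expect_equal(mean(rr$recall), 1)
})

test_that("soft EM memberships are proper probabilities", {
  reads <- two_source_reads(60, 60, gc = c(0.4, 0.6), seed = 91)
  soft <- af_cluster(reads, 3, method = "soft_em", seed = 4)
  expect_equal(unname(rowSums(soft$memberships)), rep(1, nrow(soft$memberships)),
               tolerance = 1e-9)
  expect_true(all(soft$memberships >= 0 & soft$memberships <= 1))
  # the marginal log-likelihood is the EM objective that never decreases
  expect_true(all(diff(soft$log_likelihood_trace) >= -1e-9))
})

test_that("identical reads give uniform memberships over identical centroids", {
  reads <- tibble::tibble(read_id = paste0("r", 1:10), seq = rep("ACGTACGTACGTACGT", 10))
  soft <- af_cluster(reads, 2, method = "soft_em", seed = 1)
  expect_equal(unname(soft$memberships), matrix(0.5, 10, 2), tolerance = 1e-9)
})

test_that("hardened soft EM agrees with hard EM on separated sources", {
  reads <- two_source_reads(200, 100, gc = c(0.3, 0.7), seed = 101)
  soft <- af_cluster(reads, 2, method = "soft_em", seed = 11)
  hard <- af_cluster(reads, 2, method = "em", seed = 11)
  expect_gte(max(soft$memberships[1, ]), 0.99) # memberships saturate
  hz <- unname(harden(soft))
  agree <- max(mean(hz == hard$cluster), mean(hz == (3 - hard$cluster)))
  expect_gte(agree, 0.99)
})

test_that("weighted soft centroid equals independently pooled weighted counts", {
  reads <- two_source_reads(40, 60, gc = c(0.4, 0.6), seed = 111)
  soft <- af_cluster(reads, 2, method = "soft_em", seed = 13)
  C <- count_kmers(reads, kmer_spec(2))
  Z <- soft$memberships
  for (a in 1:2) {
    pooled <- colSums(Z[, a] * C) + soft$pseudocount
    expect_equal(unname(soft$centroids[a, ]), unname(pooled / sum(pooled)),
                 tolerance = 1e-10)
  }
})

test_that("empty-cluster policies fail or reseed as configured", {
  # two point-mass groups cannot feed three centroids
  reads <- tibble::tibble(
    read_id = paste0("r", 1:8),
    seq = c(rep(strrep("A", 30), 4), rep(strrep("T", 30), 4))
  )
  failed <- FALSE
  for (s in 1:20) {
    out <- tryCatch(
      af_cluster(reads, 3, n = 1, seed = s, empty_cluster = "fail"),
      error = function(e) e
    )
    if (inherits(out, "error")) failed <- TRUE
  }
  expect_true(failed)
  # with reseeding every seed yields a valid 3-cluster partition
  for (s in 1:5) {
    fit <- suppressMessages(af_cluster(reads, 3, n = 1, seed = s))
    expect_setequal(unique(fit$cluster), 1:3)
  }
})

test_that("engines without a convergence guarantee stop at max_iter on a cycling instance", {
  expect_warning(
    fit <- af_cluster(cycling_reads(), 2, method = "d2star", n = 1, seed = 1, max_iter = 25),
    "did not converge"
  )
  expect_false(fit$converged)
  expect_equal(fit$iterations, 25)
})

test_that("reads without countable words are dropped with a warning", {
  reads <- tibble::tibble(read_id = c("ok", "bad"), seq = c("ACGTACGT", "NNNN"))
  expect_warning(fit <- af_cluster(reads, 1, n = 2, seed = 1), "zero word count")
  expect_equal(fit$read_id, "ok")
  expect_equal(fit$dropped, "bad")
  expect_error(suppressWarnings(af_cluster(reads, 2, n = 2, seed = 1)), "at least k")
})
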