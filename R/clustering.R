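#' Centroid-based alignment-free clustering of reads
#'
#' Clusters nucleotide reads by their n-mer composition using one of eight
#' centroid-based engines:
#'
#' * `"em"` — hard expectation maximization under the multinomial model.
#'   The assignment step sends each read to the centroid minimizing
#'   `L_a * KL(p_a | q_alpha)` (the exact negative log-likelihood of its word
#'   counts); the update step pools member word counts, adds the pseudocount,
#'   and renormalizes. The distortion `sum_a L_a KL(p_a | q_{z_a})` is
#'   non-increasing, so the iteration converges.
#' * `"soft_em"` — soft EM: each read carries a membership probability per
#'   cluster, computed in the log domain with max-subtraction (the
#'   probability-domain weights `exp(-L_a KL)` underflow for long reads);
#'   centroids are membership-weighted pooled counts. Equal cluster priors.
#' * `"kmeans"` — L2 Lloyd iteration after whitening each word-frequency
#'   coordinate by its across-dataset standard deviation.
#' * `"l2"`, `"d2"`, `"d2star"`, `"chi2"`, `"symkl"` — centroid iteration
#'   under the corresponding dissimilarity. `"l2"` and `"symkl"` operate on
#'   per-read simplex frequencies, `"d2"` on unit-norm vectors (the update is
#'   the renormalized vector sum of members), and `"d2star"`/`"chi2"`
#'   compare raw read counts against each cluster's zero-order Markov
#'   expectation recomputed from the pooled single-nucleotide frequencies of
#'   its members. The last three have no convergence guarantee and may stop
#'   at `max_iter` with `converged = FALSE`.
#'
#' Reads whose total word count is zero after counting are dropped with a
#' warning (their composition is undefined).
#'
#' @param reads A data frame with columns `read_id` and `seq`, a named
#'   character vector, or a `DNAStringSet`.
#' @param k Number of clusters.
#' @param method Clustering engine, see above.
#' @param n,mode,stack_revcomp Word-counting settings, see [kmer_spec()].
#' @param pseudocount Constant added to pooled centroid counts before
#'   normalization (keeps KL finite). For `method = "symkl"` it is also added
#'   to per-read counts, since the symmetrized divergence is infinite
#'   whenever a read lacks a word the centroid has.
#' @param max_iter Maximum number of iterations.
#' @param tol Soft-EM stopping threshold on `max(abs(delta Z))`.
#' @param restarts Number of independent restarts; run `r` uses seed
#'   `seed + r - 1` and the best result (minimal distortion, or maximal
#'   expected log-likelihood for soft EM) is returned.
#' @param seed Integer seed for the random initialization (random assignment
#'   of reads to clusters followed by one update step). `NULL` draws one from
#'   the session RNG.
#' @param empty_cluster What to do when an assignment step empties a cluster:
#'   `"reseed"` (default) moves the read farthest from its centroid into the
#'   empty cluster and continues; `"fail"` raises an error.
#' @param l2_scheme Per-read normalization for `method = "l2"`: simplex
#'   frequencies (default) or unit-norm vectors.
#'
#' @return An object of class `af_hard_partition` (or `af_soft_partition`
#'   for `method = "soft_em"`), with [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()] methods. Key fields: `cluster` (hard) or
#'   `memberships` (soft, rows sum to 1), `centroids` (K x 4^n frequency
#'   matrix), `distortion` or `expected_log_likelihood`, `trace` (objective
#'   per iteration), `iterations`, `converged`. Soft fits also carry
#'   `log_likelihood_trace`, the per-iteration marginal log-likelihood of the
#'   word counts under equal cluster priors — the quantity EM provably never
#'   decreases (the expected complete-data log-likelihood in `trace` can dip
#'   when the E-step spreads memberships, and is reported for inspection, not
#'   as a convergence certificate).
#' @examples
#' reads <- simulate_reads(
#'   generate_sources(2, c(500, 600), gc = c(0.3, 0.7), seed = 1),
#'   num_reads = 60, read_length = 100, seed = 2
#' )
#' fit <- af_cluster(reads, k = 2, method = "em", n = 2, seed = 3)
#' glance(fit)
#' @export
af_cluster <- function(reads, k,
                       method = c("em", "soft_em", "kmeans", "l2", "d2",
                                  "d2star", "chi2", "symkl"),
                       n = 2, mode = c("overlapping", "nonoverlapping"),
                       stack_revcomp = FALSE,
                       pseudocount = 1, max_iter = 300, tol = 1e-6,
                       restarts = 1, seed = NULL,
                       empty_cluster = c("reseed", "fail"),
                       l2_scheme = c("simplex", "unit_norm")) {
  method <- match.arg(method)
  empty_cluster <- match.arg(empty_cluster)
  l2_scheme <- match.arg(l2_scheme)
  stopifnot(k >= 1, max_iter >= 1, tol > 0, restarts >= 1, pseudocount >= 0)
  reads <- as_reads(reads)
  spec <- kmer_spec(n, match.arg(mode), stack_revcomp)

  C <- count_kmers(reads, spec)
  L <- rowSums(C)
  dropped <- reads$read_id[L == 0]
  if (length(dropped) > 0) {
    rlang::warn(sprintf("dropping %d read(s) with zero word count.", length(dropped)))
    C <- C[L > 0, , drop = FALSE]
    reads <- reads[L > 0, ]
  }
  N <- nrow(C)
  if (N < k) rlang::abort(sprintf("need at least k = %d reads with words; have %d.", k, N))

  ctx <- list(
    C = C, L = rowSums(C), spec = spec, k = as.integer(k),
    pseudocount = pseudocount, max_iter = as.integer(max_iter), tol = tol,
    empty = empty_cluster, l2_scheme = l2_scheme
  )
  if (method %in% c("d2star", "chi2")) {
    ctx$C1 <- count_kmers(reads, kmer_spec(1, spec$mode, spec$stack_revcomp))
  }

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seeds <- seed + seq_len(restarts) - 1L

  runs <- purrr::map(seeds, function(s) {
    tryCatch(
      withr::with_seed(s, run_engine(method, ctx)),
      af_empty_cluster = function(e) e
    )
  })
  failed <- purrr::map_lgl(runs, ~ inherits(.x, "condition"))
  if (all(failed)) {
    rlang::abort(paste0(
      sprintf("all %d restart(s) failed: ", restarts),
      paste(unique(purrr::map_chr(runs, conditionMessage)), collapse = "; ")
    ))
  }
  ok <- which(!failed)
  score <- purrr::map_dbl(runs[ok], "objective")
  best <- if (method == "soft_em") ok[which.max(score)] else ok[which.min(score)]
  fit <- runs[[best]]

  out <- list(
    method = method, k = as.integer(k), spec = spec,
    pseudocount = pseudocount, l2_scheme = l2_scheme,
    seed = seeds[[best]], seeds = seeds,
    read_id = reads$read_id,
    centroids = fit$centroids,
    trace = fit$trace, iterations = fit$iterations, converged = fit$converged,
    dropped = dropped
  )
  if (method == "soft_em") {
    out$memberships <- fit$Z
    rownames(out$memberships) <- reads$read_id
    out$expected_log_likelihood <- fit$objective
    out$log_likelihood_trace <- fit$ll_trace
    class(out) <- c("af_soft_partition", "af_partition")
  } else {
    out$cluster <- fit$z
    out$distortion <- fit$objective
    if (method == "kmeans") out$whitening_scale <- fit$scale
    class(out) <- c("af_hard_partition", "af_partition")
  }
  out
}

run_engine <- function(method, ctx) {
  switch(method,
    em = run_hard_em(ctx),
    soft_em = run_soft_em(ctx),
    kmeans = run_kmeans(ctx),
    run_centroid_iterate(method, ctx)
  )
}

# --- shared pieces ----------------------------------------------------------

# random assignment guaranteed to touch every cluster (N >= K)
init_assignments <- function(N, K) {
  sample(rep_len(seq_len(K), N))
}

# K x M matrix of pooled member counts + pseudocount, rows normalized to the
# simplex (the hard-EM centroid update)
pool_simplex <- function(C, z, K, pseudocount) {
  M <- ncol(C)
  out <- matrix(0, K, M, dimnames = list(NULL, colnames(C)))
  for (a in seq_len(K)) {
    rows <- z == a
    if (any(rows)) out[a, ] <- colSums(C[rows, , drop = FALSE])
  }
  out <- out + pseudocount
  out / rowSums(out)
}

# sum_i c_i log p_i per row, with 0 log 0 = 0
row_count_entropy <- function(C) {
  Clog <- C
  pos <- C > 0
  Clog[pos] <- C[pos] * log(C[pos])
  Clog[!pos] <- 0
  rowSums(Clog) - rowSums(C) * log(rowSums(C))
}

xlogx <- function(m) {
  out <- m
  pos <- m > 0
  out[pos] <- m[pos] * log(m[pos])
  out[!pos] <- 0
  out
}

# move the read farthest from its centroid into each empty cluster
fix_empty_clusters <- function(z, cost, K, policy) {
  empty <- setdiff(seq_len(K), unique(z))
  for (a in empty) {
    if (policy == "fail") {
      rlang::abort("an empty cluster was formed.", class = "af_empty_cluster")
    }
    own <- cost[cbind(seq_along(z), z)]
    sizes <- tabulate(z, K)
    movable <- sizes[z] > 1L
    if (!any(movable)) break
    pick <- which(movable)[which.max(own[movable])]
    z[pick] <- a
    rlang::inform(sprintf("empty cluster %d reseeded with its farthest read.", a))
  }
  z
}

row_softmax <- function(G) {
  m <- G[cbind(seq_len(nrow(G)), max.col(G, ties.method = "first"))]
  W <- exp(G - m)
  W / rowSums(W)
}

# --- hard EM ----------------------------------------------------------------

run_hard_em <- function(ctx) {
  C <- ctx$C; K <- ctx$k; N <- nrow(C)
  S <- row_count_entropy(C)
  z <- init_assignments(N, K)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    Q <- pool_simplex(C, z, K, ctx$pseudocount)
    cost <- S - C %*% t(log(Q)) # N x K matrix of L_a * KL(p_a | q_alpha)
    z_new <- max.col(-cost, ties.method = "first")
    z_new <- fix_empty_clusters(z_new, cost, K, ctx$empty)
    trace <- c(trace, sum(cost[cbind(seq_len(N), z_new)]))
    if (identical(z_new, z)) {
      converged <- TRUE
      break
    }
    z <- z_new
    if (it >= ctx$max_iter) break
  }
  if (!converged) rlang::warn(sprintf("hard EM did not converge in %d iterations.", it))
  list(z = z, centroids = name_centroids(Q), objective = trace[length(trace)],
       trace = trace, iterations = it, converged = converged)
}

# --- soft EM ----------------------------------------------------------------

run_soft_em <- function(ctx) {
  C <- ctx$C; K <- ctx$k; N <- nrow(C)
  S <- row_count_entropy(C)
  z0 <- init_assignments(N, K)
  Q <- pool_simplex(C, z0, K, ctx$pseudocount)
  Z_prev <- NULL
  trace <- numeric(0)
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    G <- C %*% t(log(Q)) # log-domain weights up to a per-read constant
    mx <- G[cbind(seq_len(N), max.col(G, ties.method = "first"))]
    W <- exp(G - mx)
    Z <- W / rowSums(W)
    # marginal log-likelihood of the counts under equal cluster priors: the
    # quantity EM provably never decreases
    ll_trace <- c(ll_trace, sum(mx + log(rowSums(W))) - N * log(K) - sum(S))
    if (ctx$empty == "fail" && any(colSums(Z) < .Machine$double.eps * N)) {
      rlang::abort("a zero-weight cluster was formed.", class = "af_empty_cluster")
    }
    pooled <- t(Z) %*% C + ctx$pseudocount
    Q <- pooled / rowSums(pooled)
    # expected log-likelihood at (Z, updated Q); unlike the marginal, this
    # expectation can dip when the E-step spreads memberships
    trace <- c(trace, sum(Z * (C %*% t(log(Q)))) - sum(S))
    if (!is.null(Z_prev) && max(abs(Z - Z_prev)) < ctx$tol) {
      converged <- TRUE
      break
    }
    Z_prev <- Z
    if (it >= ctx$max_iter) break
  }
  if (!converged) rlang::warn(sprintf("soft EM did not converge in %d iterations.", it))
  list(Z = Z, centroids = name_centroids(Q), objective = trace[length(trace)],
       trace = trace, ll_trace = ll_trace, iterations = it, converged = converged)
}

# --- whitened k-means -------------------------------------------------------

run_kmeans <- function(ctx) {
  P <- to_frequencies(ctx$C, "simplex")
  w <- whiten_columns(P)
  fit <- lloyd_l2(w$whitened, ctx)
  centroids <- matrix(0, ctx$k, ncol(P), dimnames = list(NULL, colnames(P)))
  for (a in seq_len(ctx$k)) {
    rows <- fit$z == a
    if (any(rows)) centroids[a, ] <- colMeans(P[rows, , drop = FALSE])
  }
  list(z = fit$z, centroids = name_centroids(centroids), objective = fit$objective,
       trace = fit$trace, iterations = fit$iterations, converged = fit$converged,
       scale = w$scale)
}

# Lloyd iteration on row vectors: mean update, squared-Euclidean assignment
lloyd_l2 <- function(X, ctx) {
  K <- ctx$k; N <- nrow(X)
  z <- init_assignments(N, K)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    mu <- matrix(0, K, ncol(X))
    for (a in seq_len(K)) {
      rows <- z == a
      if (any(rows)) mu[a, ] <- colMeans(X[rows, , drop = FALSE])
    }
    cost <- sq_dist_matrix(X, mu)
    z_new <- max.col(-cost, ties.method = "first")
    z_new <- fix_empty_clusters(z_new, cost, K, ctx$empty)
    trace <- c(trace, sum(cost[cbind(seq_len(N), z_new)]))
    if (identical(z_new, z)) {
      converged <- TRUE
      break
    }
    z <- z_new
    if (it >= ctx$max_iter) break
  }
  if (!converged) rlang::warn(sprintf("k-means did not converge in %d iterations.", it))
  list(z = z, objective = trace[length(trace)], trace = trace,
       iterations = it, converged = converged)
}

# N x K matrix of squared Euclidean distances between rows of X and rows of mu
sq_dist_matrix <- function(X, mu) {
  d <- outer(rowSums(X^2), rep(1, nrow(mu))) - 2 * X %*% t(mu) +
    outer(rep(1, nrow(X)), rowSums(mu^2))
  pmax(d, 0)
}

# --- generic centroid iteration (l2, d2, d2star, chi2, symkl) ---------------

run_centroid_iterate <- function(method, ctx) {
  K <- ctx$k
  kernel <- centroid_kernel(method, ctx)
  N <- nrow(ctx$C)
  z <- init_assignments(N, K)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    state <- kernel$update(z)
    cost <- kernel$dist(state)
    z_new <- max.col(-cost, ties.method = "first")
    z_new <- fix_empty_clusters(z_new, cost, K, ctx$empty)
    trace <- c(trace, sum(cost[cbind(seq_len(N), z_new)]))
    if (identical(z_new, z)) {
      converged <- TRUE
      break
    }
    z <- z_new
    if (it >= ctx$max_iter) break
  }
  if (!converged) {
    rlang::warn(sprintf("%s centroid iteration did not converge in %d iterations.",
                        method, it))
  }
  list(z = z, centroids = name_centroids(kernel$centroids(state)),
       objective = trace[length(trace)], trace = trace,
       iterations = it, converged = converged)
}

# Each kernel provides update(z) -> state, dist(state) -> N x K cost matrix,
# centroids(state) -> K x M frequency matrix for reporting.
centroid_kernel <- function(method, ctx) {
  C <- ctx$C; K <- ctx$k
  switch(method,
    l2 = {
      P <- to_frequencies(C, ctx$l2_scheme)
      list(
        update = function(z) {
          mu <- matrix(0, K, ncol(P), dimnames = list(NULL, colnames(P)))
          for (a in seq_len(K)) {
            rows <- z == a
            if (any(rows)) mu[a, ] <- colMeans(P[rows, , drop = FALSE])
          }
          mu
        },
        dist = function(mu) sqrt(sq_dist_matrix(P, mu)),
        centroids = function(mu) mu
      )
    },
    d2 = {
      U <- to_frequencies(C, "unit_norm")
      list(
        update = function(z) {
          mu <- matrix(0, K, ncol(U), dimnames = list(NULL, colnames(U)))
          for (a in seq_len(K)) {
            rows <- z == a
            if (any(rows)) {
              v <- colSums(U[rows, , drop = FALSE])
              mu[a, ] <- v / sqrt(sum(v^2))
            }
          }
          mu
        },
        dist = function(mu) 1 - U %*% t(mu),
        centroids = function(mu) mu
      )
    },
    symkl = {
      # per-read pseudocount: the symmetrized divergence is infinite when a
      # read lacks a word the centroid carries
      P <- to_frequencies(C, "simplex", pseudocount = ctx$pseudocount)
      logP <- log(P)
      t1 <- rowSums(P * logP)
      list(
        update = function(z) pool_simplex(C, z, K, ctx$pseudocount),
        dist = function(Q) {
          logQ <- log(Q)
          sweep(t1 - P %*% t(logQ) - logP %*% t(Q), 2L, rowSums(Q * logQ), "+")
        },
        centroids = function(Q) Q
      )
    },
    d2star = {
      C1 <- ctx$C1; L <- ctx$L; n <- ctx$spec$n
      list(
        update = function(z) {
          lapply(seq_len(K), function(a) {
            rows <- z == a
            base <- colSums(C1[rows, , drop = FALSE]) + ctx$pseudocount
            Q <- zero_order_expected_frequencies(base / sum(base), n)
            x <- colSums(C[rows, , drop = FALSE])
            list(Q = Q, x = x, xt = standardize(x, Q))
          })
        },
        dist = function(state) {
          out <- matrix(0, nrow(C), K)
          for (a in seq_len(K)) {
            st <- state[[a]]
            E <- L %o% st$Q # expected counts per read
            Ct <- (C - E) / sqrt(E)
            num <- Ct %*% st$xt
            den <- sqrt(rowSums(Ct^2)) * sqrt(sum(st$xt^2))
            cosv <- ifelse(den > 0, num / den, 0) # degenerate -> distance 1/2
            out[, a] <- (1 - cosv) / 2
          }
          out
        },
        centroids = function(state) {
          t(vapply(state, function(st) st$x / sum(st$x), numeric(ncol(C))))
        }
      )
    },
    chi2 = {
      C1 <- ctx$C1; L <- ctx$L; n <- ctx$spec$n; C2 <- C^2
      list(
        update = function(z) {
          t(vapply(seq_len(K), function(a) {
            base <- colSums(C1[z == a, , drop = FALSE]) + ctx$pseudocount
            zero_order_expected_frequencies(base / sum(base), n)
          }, numeric(4L^n)))
        },
        dist = function(Q) sweep(C2 %*% t(1 / Q), 1L, L, "/") - L,
        centroids = function(Q) Q
      )
    },
    rlang::abort(sprintf("unknown method '%s'.", method))
  )
}

name_centroids <- function(Q) {
  rownames(Q) <- paste0("cluster_", seq_len(nrow(Q)))
  Q
}
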