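#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.af_hard_partition <- function(x, ...) {
  cat(sprintf(
    "<af_hard_partition> %s, k = %d, n = %d: %d reads, distortion %.6g, %d iteration(s)%s\n",
    x$method, x$k, x$spec$n, length(x$read_id), x$distortion, x$iterations,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' @export
print.af_soft_partition <- function(x, ...) {
  cat(sprintf(
    "<af_soft_partition> soft EM, k = %d, n = %d: %d reads, expected log-likelihood %.6g, %d iteration(s)%s\n",
    x$k, x$spec$n, nrow(x$memberships), x$expected_log_likelihood, x$iterations,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Tidy a hard partition into per-read assignments
#'
#' @param x An `af_hard_partition`.
#' @param ... Unused.
#' @return A tibble with columns `read_id` and `cluster`.
#' @export
tidy.af_hard_partition <- function(x, ...) {
  tibble::tibble(read_id = x$read_id, cluster = as.integer(x$cluster))
}

#' Tidy a soft partition into long per-read memberships
#'
#' @param x An `af_soft_partition`.
#' @param ... Unused.
#' @return A tibble with columns `read_id`, `cluster`, `membership`; for each
#'   read the memberships sum to 1.
#' @export
tidy.af_soft_partition <- function(x, ...) {
  Z <- x$memberships
  tibble::tibble(
    read_id = rep(rownames(Z), times = ncol(Z)),
    cluster = rep(seq_len(ncol(Z)), each = nrow(Z)),
    membership = as.vector(Z)
  ) |> dplyr::arrange(.data$read_id, .data$cluster)
}

#' One-row summary of a fitted partition
#'
#' @param x An `af_partition`.
#' @param ... Unused.
#' @return A one-row tibble with the method, cluster count, word size,
#'   number of reads, the final objective (distortion, or expected
#'   log-likelihood for soft EM), iterations, convergence flag and seed.
#' @export
glance.af_partition <- function(x, ...) {
  tibble::tibble(
    method = x$method, k = x$k, n = x$spec$n,
    n_reads = length(x$read_id),
    objective = if (x$method == "soft_em") x$expected_log_likelihood else x$distortion,
    iterations = x$iterations, converged = x$converged, seed = x$seed
  )
}

#' Harden a soft partition
#'
#' Assigns each read to its maximum-membership cluster (ties broken by the
#' lowest cluster index).
#'
#' @param x An `af_soft_partition`.
#' @return An integer vector of cluster labels named by read id.
#' @export
harden <- function(x) {
  stopifnot(inherits(x, "af_soft_partition"))
  stats::setNames(max.col(x$memberships, ties.method = "first"),
                  rownames(x$memberships))
}

#' Distortion of a hard partition
#'
#' Returns the fitted distortion, or recomputes it from the reads when they
#' are supplied: `sum_a L_a KL(p_a | q_{z_a})` for the EM method, the sum of
#' per-read d2 dissimilarities for d2, within-cluster squared Euclidean
#' distance in whitened space for k-means, and the sum of per-read kernel
#' distances otherwise (with cluster expectations rebuilt from the
#' assignments for d2*/chi-squared).
#'
#' @param x An `af_hard_partition`.
#' @param reads Optionally, the reads the partition was fitted on.
#' @return A single non-negative number.
#' @export
distortion <- function(x, reads = NULL) {
  stopifnot(inherits(x, "af_hard_partition"))
  if (is.null(reads)) return(x$distortion)
  reads <- as_reads(reads)
  reads <- reads[match(x$read_id, reads$read_id), ]
  if (anyNA(reads$seq)) rlang::abort("reads do not cover every read_id in the partition.")
  C <- count_kmers(reads, x$spec)
  z <- x$cluster
  N <- nrow(C)
  ctx <- list(
    C = C, L = rowSums(C), spec = x$spec, k = x$k,
    pseudocount = x$pseudocount, empty = "reseed",
    l2_scheme = if (is.null(x$l2_scheme)) "simplex" else x$l2_scheme
  )
  cost <- switch(x$method,
    em = {
      S <- row_count_entropy(C)
      S - C %*% t(log(x$centroids))
    },
    kmeans = {
      W <- sweep(to_frequencies(C, "simplex"), 2L, x$whitening_scale, "/")
      mu <- sweep(x$centroids, 2L, x$whitening_scale, "/")
      sq_dist_matrix(W, mu)
    },
    {
      if (x$method %in% c("d2star", "chi2")) {
        ctx$C1 <- count_kmers(reads, kmer_spec(1, x$spec$mode, x$spec$stack_revcomp))
      }
      kernel <- centroid_kernel(x$method, ctx)
      kernel$dist(kernel$update(z))
    }
  )
  sum(cost[cbind(seq_len(N), z)])
}

#' Plot a fitted partition
#'
#' For a hard partition, a principal-component scatter of the per-read word
#' frequencies colored by cluster when `reads` are supplied, otherwise a bar
#' chart of cluster sizes. For a soft partition, a membership heatmap with
#' reads ordered by their dominant cluster.
#'
#' @param object An `af_partition`.
#' @param reads Optionally, the reads the partition was fitted on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.af_hard_partition <- function(object, reads = NULL, ...) {
  if (is.null(reads)) {
    d <- dplyr::count(tidy(object), .data$cluster)
    return(
      ggplot2::ggplot(d, ggplot2::aes(factor(.data$cluster), .data$n)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "cluster", y = "reads", title = sprintf("%s partition", object$method))
    )
  }
  reads <- as_reads(reads)
  reads <- reads[match(object$read_id, reads$read_id), ]
  P <- to_frequencies(count_kmers(reads, object$spec), "simplex")
  pc <- stats::prcomp(P, center = TRUE, scale. = FALSE)
  d <- tibble::tibble(
    PC1 = pc$x[, 1], PC2 = pc$x[, min(2L, ncol(pc$x))],
    cluster = factor(object$cluster)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = sprintf("%s partition of word compositions", object$method))
}

#' @rdname autoplot.af_hard_partition
#' @export
autoplot.af_soft_partition <- function(object, ...) {
  d <- tidy(object)
  ord <- names(sort(harden(object)))
  d$read_id <- factor(d$read_id, levels = ord)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$cluster), .data$read_id,
                                  fill = .data$membership)) +
    ggplot2::geom_tile() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "cluster", y = "read", fill = "Z",
                  title = "soft EM membership probabilities")
}
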