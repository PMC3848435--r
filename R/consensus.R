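#' Bootstrap consensus clustering
#'
#' Runs the configured centroid clustering `runs` times, each time on a
#' random subsample of the reads (drawn without replacement), and records
#' for every read pair how often it was co-sampled and how often it was
#' placed in the same cluster. The co-clustering distance is
#' `D_ij = 1 - together_ij / cosampled_ij`, a number in `[0, 1]`; an
#' average-linkage hierarchical tree is built on `D` and cut into `k` groups
#' for the consensus partition. Pairs never co-sampled get `D_ij = 1` with a
#' warning (conservative: never-observed pairs are treated as never
#' co-clustering). Consensus damps the dependence of a single centroid run
#' on its random initialization, at `O(N^2 log N)` cost.
#'
#' @inheritParams af_cluster
#' @param runs Number of bootstrap clustering runs (at least 2); run `r`
#'   subsamples and clusters with seed `seed + r - 1`.
#' @param subsample_fraction Fraction of reads drawn into each bootstrap
#'   dataset, in `(0, 1]`.
#' @param ... Further arguments passed to [af_cluster()] (`method`, `n`,
#'   `pseudocount`, ...). Soft EM is not a valid base method here.
#' @return An object of class `af_consensus` with fields `D` (the N x N
#'   co-clustering distance matrix), `together` and `cosampled` (integer
#'   count matrices), `tree` (an [stats::hclust] average-linkage tree),
#'   `cluster` (the consensus partition at `k`) and `read_id`.
#' @examples
#' reads <- simulate_reads(
#'   generate_sources(2, c(500, 600), gc = c(0.3, 0.7), seed = 1),
#'   num_reads = 40, read_length = 100, seed = 2
#' )
#' cons <- consensus_cluster(reads, k = 2, runs = 5, seed = 3, n = 1)
#' table(cons$cluster)
#' @export
consensus_cluster <- function(reads, k, runs = 20, subsample_fraction = 0.8,
                              seed = NULL, ...) {
  stopifnot(runs >= 2, subsample_fraction > 0, subsample_fraction <= 1)
  reads <- as_reads(reads)
  N <- nrow(reads)
  m <- floor(N * subsample_fraction)
  if (m < k) rlang::abort("subsample is smaller than the number of clusters.")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  together <- matrix(0L, N, N)
  cosampled <- matrix(0L, N, N)
  for (r in seq_len(runs)) {
    run_seed <- seed + r - 1L
    idx <- sort(withr::with_seed(run_seed, sample.int(N, m)))
    fit <- af_cluster(reads[idx, ], k = k, seed = run_seed, ...)
    if (!inherits(fit, "af_hard_partition")) {
      rlang::abort("consensus clustering needs a hard base method.")
    }
    # reads dropped for zero word count are absent from the fit
    kept <- match(fit$read_id, reads$read_id)
    cosampled[kept, kept] <- cosampled[kept, kept] + 1L
    for (a in seq_len(k)) {
      members <- kept[fit$cluster == a]
      together[members, members] <- together[members, members] + 1L
    }
  }

  D <- matrix(1, N, N)
  seen <- cosampled > 0
  D[seen] <- 1 - together[seen] / cosampled[seen]
  diag(D) <- 0
  if (any(!seen[upper.tri(seen)])) {
    rlang::warn(sprintf(
      "%d read pair(s) were never co-sampled; their consensus distance is set to 1.",
      sum(!seen[upper.tri(seen)])
    ))
  }
  dimnames(D) <- list(reads$read_id, reads$read_id)
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  cluster <- stats::cutree(tree, k = k)

  structure(
    list(D = D, together = together, cosampled = cosampled, tree = tree,
         cluster = unname(cluster), read_id = reads$read_id, k = as.integer(k),
         runs = as.integer(runs), subsample_fraction = subsample_fraction,
         seed = seed),
    class = "af_consensus"
  )
}

#' @export
print.af_consensus <- function(x, ...) {
  cat(sprintf(
    "<af_consensus> %d reads, %d runs at fraction %.2f, cut into k = %d groups\n",
    length(x$read_id), x$runs, x$subsample_fraction, x$k
  ))
  invisible(x)
}

#' @export
tidy.af_consensus <- function(x, ...) {
  tibble::tibble(read_id = x$read_id, cluster = as.integer(x$cluster))
}

#' @export
glance.af_consensus <- function(x, ...) {
  off <- x$D[upper.tri(x$D)]
  tibble::tibble(
    k = x$k, runs = x$runs, n_reads = length(x$read_id),
    subsample_fraction = x$subsample_fraction,
    mean_distance = mean(off), binary = all(off %in% c(0, 1)), seed = x$seed
  )
}

#' @export
autoplot.af_consensus <- function(object, ...) {
  ord <- object$tree$order
  d <- tibble::tibble(
    i = rep(seq_along(ord), times = length(ord)),
    j = rep(seq_along(ord), each = length(ord)),
    distance = as.vector(object$D[ord, ord])
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$i, .data$j, fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey10", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "D",
                  title = "consensus co-clustering distance (tree order)")
}

#' Write the consensus tree in Newick format
#'
#' @param x An `af_consensus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_consensus_tree <- function(x, path) {
  stopifnot(inherits(x, "af_consensus"))
  rlang::check_installed("ape")
  phy <- ape::as.phylo(x$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write the consensus distance matrix as TSV
#'
#' @param x An `af_consensus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_consensus_matrix <- function(x, path) {
  stopifnot(inherits(x, "af_consensus"))
  utils::write.table(x$D, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
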