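#' Per-gene recall rate of a hard partition
#'
#' For each gene (true read origin), the recall rate is the largest fraction
#' of its reads that land in a single cluster. A recall of 1 means the
#' clustering did not fragment the gene at all; for `K` clusters a gene
#' split uniformly scores `1/K`.
#'
#' @param x An `af_hard_partition`, a data frame with columns `read_id` and
#'   `cluster`, or a named integer vector (e.g. from [harden()]).
#' @param labels A data frame mapping `read_id` to its true origin in a
#'   column named `gene` or `source`.
#' @return A tibble with columns `gene`, `n_reads`, `top_cluster`, `recall`,
#'   one row per gene with at least one assigned read. Genes with no
#'   assigned reads are omitted with a warning.
#' @examples
#' asg <- tibble::tibble(read_id = as.character(1:10),
#'                       cluster = c(rep(1, 4), rep(2, 3), 2, 3, 4))
#' lab <- tibble::tibble(read_id = as.character(1:10), gene = "G")
#' recall_rate(asg, lab)
#' @export
recall_rate <- function(x, labels) {
  asg <- as_assignments(x)
  labels <- as_labels(labels)
  missing_genes <- setdiff(labels$gene, labels$gene[labels$read_id %in% asg$read_id])
  if (length(missing_genes) > 0) {
    rlang::warn(sprintf("omitting %d gene(s) with no assigned reads.",
                        length(missing_genes)))
  }
  dplyr::inner_join(asg, labels, by = "read_id") |>
    dplyr::count(.data$gene, .data$cluster, name = "in_cluster") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_reads = sum(.data$in_cluster),
      top_cluster = .data$cluster[which.max(.data$in_cluster)],
      recall = max(.data$in_cluster) / sum(.data$in_cluster)
    )
}

#' Threshold assignment of a soft partition
#'
#' A read belongs to every cluster whose membership probability is at least
#' `epsilon`; the resulting cluster sets may overlap or be empty. At
#' `epsilon = 0` every read belongs to every cluster; above the maximum
#' membership no read belongs to any.
#'
#' @param soft An `af_soft_partition`.
#' @param epsilon Confidence threshold in `[0, 1]`.
#' @return A tibble with columns `read_id`, `cluster`, `membership`, one row
#'   per retained (read, cluster) pair.
#' @export
threshold_assign <- function(soft, epsilon) {
  stopifnot(inherits(soft, "af_soft_partition"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 || epsilon > 1) {
    rlang::abort("`epsilon` must be a single number in [0, 1].")
  }
  tidy(soft) |> dplyr::filter(.data$membership >= epsilon)
}

#' True- and false-positive rates of thresholded soft assignments
#'
#' For a gene `G` at threshold `epsilon`, the "correct" cluster is the one
#' embracing the largest part of G's reads under that threshold's
#' assignment (ties broken by the lowest cluster index). TPR is the fraction
#' of G's reads assigned to the correct cluster; FPR is the fraction
#' assigned to at least one other cluster. Because assignments overlap, a
#' read can count toward both.
#'
#' @param soft An `af_soft_partition`.
#' @param labels Read origins, see [recall_rate()].
#' @param gene The gene to evaluate.
#' @param epsilon Threshold(s) in `[0, 1]`; vectorized.
#' @return A tibble with columns `epsilon`, `correct_cluster`, `tpr`, `fpr`.
#' @export
threshold_rates <- function(soft, labels, gene, epsilon) {
  stopifnot(inherits(soft, "af_soft_partition"))
  if (any(epsilon < 0 | epsilon > 1)) rlang::abort("`epsilon` values must lie in [0, 1].")
  labels <- as_labels(labels)
  ids <- labels$read_id[labels$gene == gene]
  Zg <- soft$memberships[rownames(soft$memberships) %in% ids, , drop = FALSE]
  if (nrow(Zg) == 0) rlang::abort(sprintf("gene '%s' has no reads in the partition.", gene))
  purrr::map_dfr(epsilon, function(e) {
    A <- Zg >= e
    correct <- which.max(colSums(A)) # ties -> lowest index
    tibble::tibble(
      epsilon = e,
      correct_cluster = as.integer(correct),
      tpr = mean(A[, correct]),
      fpr = mean(rowSums(A[, -correct, drop = FALSE]) > 0)
    )
  })
}

#' ROC curve of soft-EM assignment for one gene
#'
#' Sweeps the confidence threshold `epsilon` over all distinct membership
#' values (plus 0 and 1), computing [threshold_rates()] at each, and closes
#' the curve with its limiting points `(FPR, TPR) = (1, 1)` (as
#' `epsilon -> 0`) and `(0, 0)` (as `epsilon -> 1`). The area under the
#' curve is computed by the trapezoid rule over FPR-sorted points. This is
#' not a classical ROC because thresholded clusters overlap: a read can
#' produce a true and a false positive simultaneously.
#'
#' @inheritParams threshold_rates
#' @param thresholds Optional numeric grid of thresholds; the default is the
#'   exact sweep over all distinct membership values.
#' @return An object of class `af_roc` with fields `points` (tibble
#'   `epsilon`, `fpr`, `tpr`), `auc` and `gene`; `tidy()` returns the
#'   points, `glance()` the AUC.
#' @export
roc_curve <- function(soft, labels, gene, thresholds = NULL) {
  stopifnot(inherits(soft, "af_soft_partition"))
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(0, as.vector(soft$memberships), 1)))
  }
  if (length(thresholds) == 0) rlang::abort("empty threshold grid.")
  pts <- threshold_rates(soft, labels, gene, thresholds)
  pts <- dplyr::bind_rows(
    pts[, c("epsilon", "fpr", "tpr")],
    tibble::tibble(epsilon = c(0, 1), fpr = c(1, 0), tpr = c(1, 0))
  ) |>
    dplyr::distinct(.data$epsilon, .data$fpr, .data$tpr) |>
    dplyr::arrange(.data$epsilon)
  ord <- dplyr::arrange(pts, .data$fpr, .data$tpr)
  auc <- sum(diff(ord$fpr) * (utils::head(ord$tpr, -1) + utils::tail(ord$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, gene = gene), class = "af_roc")
}

#' @export
print.af_roc <- function(x, ...) {
  cat(sprintf("<af_roc> gene %s: %d threshold points, AUC = %.4f\n",
              x$gene, nrow(x$points), x$auc))
  invisible(x)
}

#' @export
tidy.af_roc <- function(x, ...) x$points

#' @export
glance.af_roc <- function(x, ...) {
  tibble::tibble(gene = x$gene, auc = x$auc, n_points = nrow(x$points))
}

#' @export
autoplot.af_roc <- function(object, ...) {
  ord <- dplyr::arrange(object$points, .data$fpr, .data$tpr)
  ggplot2::ggplot(ord, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("threshold-sweep ROC, gene %s (AUC %.3f)",
                                  object$gene, object$auc))
}

# --- internal ---------------------------------------------------------------

as_assignments <- function(x) {
  if (inherits(x, "af_hard_partition")) return(tidy(x))
  if (is.data.frame(x)) {
    if (!all(c("read_id", "cluster") %in% names(x))) {
      rlang::abort("assignments data frame needs columns `read_id` and `cluster`.")
    }
    return(tibble::tibble(read_id = as.character(x$read_id),
                          cluster = as.integer(x$cluster)))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(tibble::tibble(read_id = names(x), cluster = as.integer(x)))
  }
  rlang::abort("cannot interpret assignments; supply a partition, data frame, or named vector.")
}

as_labels <- function(labels) {
  if (!is.data.frame(labels) || !"read_id" %in% names(labels)) {
    rlang::abort("labels must be a data frame with a `read_id` column.")
  }
  gene_col <- intersect(c("gene", "source"), names(labels))[1]
  if (is.na(gene_col)) {
    rlang::abort("labels must have a `gene` or `source` column.")
  }
  tibble::tibble(read_id = as.character(labels$read_id),
                 gene = as.character(labels[[gene_col]]))
}
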