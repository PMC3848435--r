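#' Read sequences from FASTA or FASTQ
#'
#' Format is auto-detected from the first character of the file (`>` FASTA,
#' `@` FASTQ) unless given explicitly; gzip-compressed files are handled
#' transparently by extension. Sequences are uppercased; FASTQ qualities are
#' ignored. Read ids are the first whitespace-delimited token of each
#' header.
#'
#' @param path Path to a FASTA or FASTQ file (optionally `.gz`).
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return A tibble with columns `read_id` and `seq`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- readLines(con, n = 1L)
    if (length(first) == 0) rlang::abort(sprintf("empty file: %s", path))
    format <- if (startsWith(first, ">")) "fasta"
      else if (startsWith(first, "@")) "fastq"
      else rlang::abort(sprintf("cannot detect format of %s (first character %s).",
                                path, substr(first, 1, 1)))
  }
  if (format == "fastq") {
    con2 <- gzfile(path, "rt")
    nl <- 0L
    repeat {
      chunk <- readLines(con2, n = 65536L)
      if (length(chunk) == 0) break
      nl <- nl + length(chunk)
    }
    close(con2)
    if (nl %% 4L != 0L) {
      rlang::abort(sprintf(
        "malformed fastq in %s: %d lines; record %d is truncated.",
        path, nl, nl %/% 4L + 1L
      ))
    }
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      rlang::abort(sprintf("malformed %s in %s: %s", format, path, conditionMessage(e)))
    }
  )
  if (length(x) == 0) rlang::abort(sprintf("no records in %s.", path))
  ids <- sub("\\s.*$", "", names(x))
  tibble::tibble(read_id = unname(ids), seq = unname(toupper(as.character(x))))
}

#' Write reads as FASTA
#'
#' @param reads A data frame with columns `read_id` and `seq`.
#' @param path Output path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  reads <- as_reads(reads)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Write a fitted partition to a directory
#'
#' Writes three plain-text files: `assignments.tsv` (read id and cluster;
#' for a soft partition additionally one membership column per cluster),
#' `centroids.tsv` (cluster and the `4^n` centroid frequencies in
#' lexicographic word order), and `run_info.txt` (key-value metadata: seed,
#' method, objective, iterations, convergence).
#'
#' @param x An `af_partition`.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_partition <- function(x, out_dir) {
  stopifnot(inherits(x, "af_partition"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) rlang::abort(sprintf("cannot create directory %s.", out_dir))

  if (inherits(x, "af_soft_partition")) {
    Z <- x$memberships
    asg <- tibble::tibble(read_id = rownames(Z), cluster = unname(harden(x)))
    asg <- dplyr::bind_cols(
      asg,
      tibble::as_tibble(Z, .name_repair = ~ paste0("membership_", seq_len(ncol(Z))))
    )
    objective <- c(expected_log_likelihood = x$expected_log_likelihood)
  } else {
    asg <- tidy(x)
    objective <- c(distortion = x$distortion)
  }
  utils::write.table(asg, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cen <- data.frame(cluster = seq_len(nrow(x$centroids)), x$centroids,
                    check.names = FALSE)
  utils::write.table(format(cen, digits = 17, scientific = TRUE, trim = TRUE),
                     file.path(out_dir, "centroids.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  info <- c(
    method = x$method, k = x$k, n = x$spec$n, mode = x$spec$mode,
    stack_revcomp = x$spec$stack_revcomp, pseudocount = x$pseudocount,
    seed = x$seed, objective,
    iterations = x$iterations, converged = x$converged,
    n_reads = length(x$read_id), n_dropped = length(x$dropped)
  )
  writeLines(paste(names(info), unname(info), sep = "\t"),
             file.path(out_dir, "run_info.txt"))
  invisible(out_dir)
}

#' Read centroid frequencies back from a partition directory
#'
#' @param out_dir Directory written by [write_partition()].
#' @return Numeric matrix of centroid frequencies (clusters x words).
#' @export
read_centroids <- function(out_dir) {
  d <- utils::read.table(file.path(out_dir, "centroids.tsv"),
                         sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- paste0("cluster_", d$cluster)
  m
}

#' Split reads into per-cluster FASTA files
#'
#' For a hard partition each read goes to exactly one `cluster_<i>.fasta`;
#' for a soft partition a read goes to every cluster whose membership is at
#' least `epsilon` (possibly none, possibly several), which is the form in
#' which overlapping clusters feed a per-cluster assembly.
#'
#' @param reads The reads the partition was fitted on (`read_id`, `seq`).
#' @param x An `af_partition`.
#' @param out_dir Output directory, created if needed.
#' @param epsilon Membership threshold for soft partitions.
#' @return Character vector of the files written, invisibly.
#' @export
split_reads_by_cluster <- function(reads, x, out_dir, epsilon = 0.05) {
  stopifnot(inherits(x, "af_partition"))
  reads <- as_reads(reads)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  members <- if (inherits(x, "af_soft_partition")) {
    sel <- threshold_assign(x, epsilon)
    if (nrow(sel) == 0) {
      rlang::warn("epsilon exceeds every membership; all cluster files are empty.")
    }
    lapply(seq_len(x$k), function(a) sel$read_id[sel$cluster == a])
  } else {
    lapply(seq_len(x$k), function(a) x$read_id[x$cluster == a])
  }
  paths <- file.path(out_dir, sprintf("cluster_%d.fasta", seq_len(x$k)))
  for (a in seq_len(x$k)) {
    sub <- reads[reads$read_id %in% members[[a]], ]
    if (nrow(sub) > 0) {
      write_fasta(sub, paths[a])
    } else {
      file.create(paths[a])
    }
  }
  invisible(paths)
}

#' Write per-gene recall rates as TSV
#'
#' @param recall A tibble from [recall_rate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recall <- function(recall, path) {
  utils::write.table(recall, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROC points as CSV
#'
#' @param roc An `af_roc` from [roc_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "af_roc"))
  utils::write.csv(roc$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
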