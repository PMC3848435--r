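#' Word-counting specification
#'
#' Defines how nucleotide sequences are turned into n-mer count vectors. The
#' vector dimension is always `4^n`, with words indexed in lexicographic order
#' over the alphabet `A < C < G < T` (so for `n = 2` the order is
#' `AA, AC, AG, AT, CA, ...`). Windows containing a non-ACGT character are
#' skipped, not randomised, so counting is deterministic.
#'
#' @param n Word length, an integer between 1 and 8. Short reads call for
#'   small `n`: word counts are only informative while the total word count
#'   per read is large compared with `4^n`.
#' @param mode `"overlapping"` counts every window with step 1;
#'   `"nonoverlapping"` advances by `n` (useful for codon-usage comparisons of
#'   coding sequence).
#' @param stack_revcomp If `TRUE`, each sequence and its reverse complement
#'   are counted as two separate strings (no chimeric windows across a
#'   junction) and the counts summed; use when reads come from both strands
#'   and no reading frame is known.
#'
#' @return An object of class `kmer_spec`.
#' @examples
#' kmer_spec(2)
#' kmer_spec(1, stack_revcomp = TRUE)
#' @export
kmer_spec <- function(n = 2, mode = c("overlapping", "nonoverlapping"),
                      stack_revcomp = FALSE) {
  mode <- match.arg(mode)
  if (length(n) != 1L || !is.finite(n) || n != as.integer(n) || n < 1 || n > 8) {
    rlang::abort("`n` must be a single integer between 1 and 8.")
  }
  structure(
    list(n = as.integer(n), mode = mode, stack_revcomp = isTRUE(stack_revcomp)),
    class = "kmer_spec"
  )
}

#' @export
print.kmer_spec <- function(x, ...) {
  cat(sprintf(
    "<kmer_spec> n = %d (%d words), %s%s\n",
    x$n, 4L^x$n, x$mode, if (x$stack_revcomp) ", stacked with reverse complement" else ""
  ))
  invisible(x)
}

#' All words of a specification, in index order
#'
#' @param spec A [kmer_spec()].
#' @return Character vector of the `4^n` words in lexicographic `A<C<G<T` order.
#' @export
kmer_names <- function(spec) {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), spec$n)
}

#' Count words in nucleotide sequences
#'
#' Returns the n-mer count matrix for a set of sequences under a
#' [kmer_spec()]. The total word count `L` of a sequence is the number of
#' counted window positions (`len - n + 1` for overlapping counting of a
#' clean sequence), not its length; windows containing a non-ACGT character
#' are skipped and do not contribute to `L`.
#'
#' @param sequences A character vector (possibly named), a
#'   [Biostrings::DNAStringSet], or a data frame with columns `read_id` and
#'   `seq`.
#' @param spec A [kmer_spec()].
#' @return An integer matrix with one row per sequence (rownames = ids when
#'   available) and `4^n` columns named by word.
#' @examples
#' count_kmers(c(r1 = "ACGT", r2 = "AAAA"), kmer_spec(1))
#' @export
count_kmers <- function(sequences, spec = kmer_spec()) {
  stopifnot(inherits(spec, "kmer_spec"))
  x <- as_dna(sequences)
  step <- if (spec$mode == "overlapping") 1L else spec$n
  counts <- Biostrings::oligonucleotideFrequency(x, width = spec$n, step = step)
  if (spec$stack_revcomp) {
    counts <- counts + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(x), width = spec$n, step = step
    )
  }
  counts <- matrix(as.integer(counts), nrow = length(x),
                   dimnames = list(names(x), colnames(counts)))
  counts
}

#' Tidy word counts
#'
#' Data-frame-first wrapper around [count_kmers()]: takes a tibble of reads,
#' returns one row per read with the total word count and one column per word.
#'
#' @param reads A data frame with columns `read_id` and `seq`.
#' @param spec A [kmer_spec()].
#' @return A tibble with columns `read_id`, `L`, then the `4^n` word counts.
#' @export
kmer_counts <- function(reads, spec = kmer_spec()) {
  reads <- as_reads(reads)
  m <- count_kmers(reads, spec)
  dplyr::bind_cols(
    tibble::tibble(read_id = reads$read_id, L = as.integer(rowSums(m))),
    tibble::as_tibble(m)
  )
}

#' Normalize count vectors to frequencies
#'
#' Adds a pseudocount to every component and normalizes. Two schemes are
#' supported: `"simplex"` (components sum to 1; the composition `p_i = c_i/L`
#' used by the multinomial/KL model) and `"unit_norm"` (Euclidean norm 1; the
#' convention of the d2 cosine geometry).
#'
#' @param counts A numeric vector, or a matrix whose rows are count vectors.
#' @param scheme `"simplex"` or `"unit_norm"`.
#' @param pseudocount Non-negative constant added to every component before
#'   normalizing. A pseudocount keeps centroid frequencies strictly positive,
#'   which keeps the KL divergence finite.
#' @return A numeric vector or matrix of the same shape.
#' @examples
#' to_frequencies(c(3, 1, 0, 0))
#' to_frequencies(c(3, 4), scheme = "unit_norm")
#' @export
to_frequencies <- function(counts, scheme = c("simplex", "unit_norm"),
                           pseudocount = 0) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount >= 0)
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, nrow = 1L) else as.matrix(counts)
  if (any(m < 0)) rlang::abort("counts must be non-negative.")
  m <- m + pseudocount
  denom <- switch(scheme,
    simplex = rowSums(m),
    unit_norm = sqrt(rowSums(m^2))
  )
  if (any(denom == 0)) {
    rlang::abort("degenerate composition: all-zero vector with pseudocount 0.")
  }
  out <- m / denom
  if (vec) {
    out <- drop(out)
    names(out) <- names(counts)
  } else {
    dimnames(out) <- dimnames(counts)
  }
  out
}

#' Whiten columns of a frequency matrix
#'
#' Divides each coordinate by that coordinate's sample standard deviation
#' computed across all rows. This is the preprocessing that turns plain L2
#' centroid clustering into the k-means algorithm. Columns with zero standard
#' deviation are left unscaled.
#'
#' @param rows A numeric matrix with at least two rows.
#' @return A list with `whitened` (the scaled matrix) and `scale` (the
#'   per-column divisors actually applied).
#' @export
whiten_columns <- function(rows) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2L) rlang::abort("whitening needs at least 2 rows.")
  s <- apply(rows, 2L, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(whitened = sweep(rows, 2L, s, "/"), scale = s)
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# --- internal coercions -----------------------------------------------------

# Accepts character vector / DNAStringSet / data frame; returns tibble with
# read_id + seq (uppercased).
as_reads <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("read_id", "seq") %in% names(x))) {
      rlang::abort("reads data frame must have columns `read_id` and `seq`.")
    }
    tibble::tibble(read_id = as.character(x$read_id), seq = toupper(x$seq))
  } else if (inherits(x, "DNAStringSet")) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("read_", seq_along(x))
    tibble::tibble(read_id = ids, seq = toupper(as.character(x)))
  } else if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("read_", seq_along(x))
    tibble::tibble(read_id = unname(ids), seq = unname(toupper(x)))
  } else {
    rlang::abort("cannot interpret `reads`; supply a character vector, DNAStringSet, or data frame.")
  }
}

as_dna <- function(x) {
  r <- as_reads(x)
  out <- Biostrings::DNAStringSet(r$seq)
  names(out) <- r$read_id
  out
}
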