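#' Generate source sequences from zero-order composition models
#'
#' Each source sequence is drawn i.i.d. base by base from its own
#' single-nucleotide frequency vector, giving a family of "genes" whose
#' pairwise composition divergence is fully controlled. Source lengths are
#' drawn uniformly from `length_range` (default 500-10000 bp, the typical
#' span of the mRNA references such simulations emulate).
#'
#' The per-source composition can be given explicitly (`compositions`), as a
#' GC content per source (`gc`; bases within the GC and AT pairs are split
#' evenly), or left at the default dial: GC contents evenly spaced on
#' `[0.35, 0.65]`, a realistic spread for transcripts while keeping the
#' clustering problem non-trivial.
#'
#' @param num_sources Number of source sequences.
#' @param length_range Length-2 integer vector `(min, max)` bp.
#' @param compositions Optional `num_sources x 4` matrix of `A, C, G, T`
#'   frequencies (rows on the simplex).
#' @param gc Optional numeric vector of per-source GC contents in `[0, 1]`.
#' @param seed Integer seed; the same seed reproduces the same sources.
#' @return A tibble with columns `source_id`, `seq`, `length`, `gc`.
#' @examples
#' generate_sources(2, c(500, 1000), gc = c(0.3, 0.7), seed = 1)
#' @export
generate_sources <- function(num_sources, length_range = c(500, 10000),
                             compositions = NULL, gc = NULL, seed = NULL) {
  stopifnot(num_sources >= 1, length(length_range) == 2L)
  if (length_range[1] > length_range[2]) {
    rlang::abort("length_range: minimum exceeds maximum.")
  }
  if (is.null(compositions)) {
    if (is.null(gc)) {
      gc <- if (num_sources == 1L) 0.5 else seq(0.35, 0.65, length.out = num_sources)
    }
    stopifnot(length(gc) == num_sources, all(gc >= 0), all(gc <= 1))
    compositions <- cbind(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  }
  compositions <- as.matrix(compositions)
  stopifnot(nrow(compositions) == num_sources, ncol(compositions) == 4L)
  if (any(compositions < 0) || any(abs(rowSums(compositions) - 1) > 1e-8)) {
    rlang::abort("composition rows must be frequencies on the simplex.")
  }
  gen <- function() {
    lens <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, num_sources, replace = TRUE)
    seqs <- vapply(seq_len(num_sources), function(s) {
      paste(sample(c("A", "C", "G", "T"), lens[s], replace = TRUE,
                   prob = compositions[s, ]), collapse = "")
    }, character(1))
    tibble::tibble(
      source_id = sprintf("source_%d", seq_len(num_sources)),
      seq = seqs,
      length = lens,
      gc = compositions[, 2] + compositions[, 3]
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate substitution-error reads from source sequences
#'
#' Emulates a shotgun read simulator restricted to substitution errors (no
#' indels): for each read a source is chosen with probability proportional to
#' its length, a start position uniformly over the valid range, a strand
#' uniformly when `both_strands = TRUE`, and each base is substituted with
#' probability `error_rate` by a uniformly chosen different base. The true
#' source of every read is retained as its label.
#'
#' @param sources A data frame from [generate_sources()] (columns
#'   `source_id`, `seq`), or any data frame with those columns.
#' @param num_reads Number of reads to simulate.
#' @param read_length Read length in bp; must not exceed the shortest source.
#' @param error_rate Per-base substitution probability (0-0.05 typical).
#' @param both_strands Draw reads from both strands (reverse complement with
#'   probability 1/2)?
#' @param seed Integer seed.
#' @return A tibble with columns `read_id` (`sourceID_index`), `seq`,
#'   `source`, `start`, `strand`.
#' @examples
#' src <- generate_sources(2, c(500, 600), seed = 1)
#' simulate_reads(src, num_reads = 10, read_length = 100, seed = 2)
#' @export
simulate_reads <- function(sources, num_reads, read_length, error_rate = 0,
                           both_strands = TRUE, seed = NULL) {
  stopifnot(is.data.frame(sources), all(c("source_id", "seq") %in% names(sources)))
  stopifnot(num_reads >= 0, read_length >= 1, error_rate >= 0, error_rate < 1)
  lens <- nchar(sources$seq)
  if (read_length > min(lens)) {
    rlang::abort("read_length exceeds the shortest source sequence.")
  }
  if (num_reads == 0) {
    return(tibble::tibble(read_id = character(), seq = character(),
                          source = character(), start = integer(),
                          strand = character()))
  }
  gen <- function() {
    src <- sample.int(nrow(sources), num_reads, replace = TRUE, prob = lens)
    start <- vapply(src, function(s) sample.int(lens[s] - read_length + 1L, 1L),
                    integer(1))
    seqs <- substring(sources$seq[src], start, start + read_length - 1L)
    strand <- rep("+", num_reads)
    if (both_strands) {
      flip <- stats::runif(num_reads) < 0.5
      strand[flip] <- "-"
      seqs[flip] <- revcomp(seqs[flip])
    }
    if (error_rate > 0) {
      seqs <- add_substitutions(seqs, error_rate)
    }
    idx <- stats::ave(seq_len(num_reads), src, FUN = seq_along)
    tibble::tibble(
      read_id = sprintf("%s_%d", sources$source_id[src], idx),
      seq = seqs,
      source = sources$source_id[src],
      start = start,
      strand = strand
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# substitute each base with probability p by a uniformly chosen different base
add_substitutions <- function(seqs, p) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < p)
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
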