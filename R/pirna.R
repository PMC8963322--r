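#' Filter alignments to piRNA-sized candidates
#'
#' Retains alignments whose read length lies in `[min_len, max_len]`,
#' the 24-31 nt window in which piRNAs are enriched (distinct from the
#' sharp 21-nt siRNA class).
#'
#' @param alignments data.frame from [map_reads()].
#' @param min_len,max_len inclusive length bounds (defaults 24 and 31).
#' @return the filtered alignment data.frame.
#' @export
filter_pirna_candidates <- function(alignments, min_len = 24L, max_len = 31L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  lens <- alignments$end - alignments$start
  out <- alignments[lens >= min_len & lens <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positional nucleotide-frequency matrix for a read set
#'
#' Computes relative A/C/G/U frequencies at read positions 1..`max_pos`
#' (1-based from each read's 5' end), the representation in which piRNA
#' biases are read off: a 5'-U (U1) excess in primary piRNAs and a
#' position-10 A (A10) excess in their ping-pong partners. Reads shorter
#' than `max_pos` contribute only up to their own length, so each column
#' is normalized over the reads that reach it. Sequences are DNA-alphabet
#' internally; the `U` row reports `T` counts.
#'
#' @param seqs character vector (or DNAStringSet) of read sequences,
#'   as sequenced (5'->3').
#' @param max_pos number of positions to tabulate (default 24).
#' @return an object of class `positional_freq`: `freq` (4 x max_pos
#'   matrix, rows A/C/G/U, columns normalized to 1 where data exist),
#'   `counts`, `n_at_pos` (reads covering each position), `n_reads`; or a
#'   no-data object (`no_data = TRUE`) for an empty read set.
#' @export
positional_frequencies <- function(seqs, max_pos = 24L) {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) == 0L) {
    return(structure(list(no_data = TRUE, n_reads = 0L),
                     class = "positional_freq"))
  }
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = 4L, ncol = max_pos,
                   dimnames = list(c("A", "C", "G", "U"), seq_len(max_pos)))
  for (p in seq_len(max_pos)) {
    b <- substring(seqs, p, p)
    b <- b[b != ""]
    if (length(b)) {
      tab <- table(factor(b, levels = bases))
      counts[, p] <- as.integer(tab)
    }
  }
  n_at_pos <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(n_at_pos, 1L), "/")
  freq[, n_at_pos == 0L] <- NA_real_
  structure(list(no_data = FALSE, freq = freq, counts = counts,
                 n_at_pos = n_at_pos, n_reads = length(seqs)),
            class = "positional_freq")
}

#' @export
print.positional_freq <- function(x, ...) {
  if (isTRUE(x$no_data)) {
    cat("Positional frequency matrix: no reads\n")
  } else {
    cat("Positional frequency matrix over", x$n_reads, "reads\n")
    print(round(x$freq[, seq_len(min(12L, ncol(x$freq)))], 3))
  }
  invisible(x)
}

#' Call the piRNA ping-pong bias from positional frequency matrices
#'
#' Tests the antisense U1 frequency and the sense A10 frequency against a
#' background base frequency with one-sided exact binomial tests
#' (alternative: greater). The verdict is `ping_pong` when both biases
#' are significant at `alpha`, `u1_only`/`a10_only` when one is, `none`
#' otherwise. The uniform background 0.25 is the minimal null for raw
#' frequency plots; pass a contig-composition background where base
#' composition is skewed.
#'
#' @param sense a `positional_freq` for sense-mapped candidates (or NULL).
#' @param antisense a `positional_freq` for antisense-mapped candidates
#'   (or NULL).
#' @param background null base frequency (default 0.25).
#' @param alpha significance level (default 0.001; apply a Bonferroni
#'   factor externally when testing many contigs).
#' @return an object of class `bias_call`: `u1_freq`, `a10_freq`, `u1_p`,
#'   `a10_p`, `verdict`.
#' @export
call_bias <- function(sense = NULL, antisense = NULL, background = 0.25,
                      alpha = 0.001) {
  test_one <- function(pfm, base, pos) {
    if (is.null(pfm) || isTRUE(pfm$no_data) || pfm$n_at_pos[pos] == 0L) {
      return(list(freq = NA_real_, p = NA_real_, sig = FALSE))
    }
    x <- pfm$counts[base, pos]
    n <- pfm$n_at_pos[[pos]]
    p <- binom.test(x, n, p = background, alternative = "greater")$p.value
    list(freq = x / n, p = p, sig = p <= alpha)
  }
  u1 <- test_one(antisense, "U", 1L)
  a10 <- test_one(sense, "A", 10L)
  verdict <- if (u1$sig && a10$sig) "ping_pong"
             else if (u1$sig) "u1_only"
             else if (a10$sig) "a10_only"
             else "none"
  structure(list(u1_freq = u1$freq, a10_freq = a10$freq,
                 u1_p = u1$p, a10_p = a10$p,
                 background = background, alpha = alpha,
                 verdict = verdict),
            class = "bias_call")
}

#' @export
print.bias_call <- function(x, ...) {
  cat("piRNA bias call:", x$verdict, "\n")
  cat(sprintf("  antisense U1: freq %.3f, p = %.3g\n", x$u1_freq, x$u1_p))
  cat(sprintf("  sense A10:    freq %.3f, p = %.3g\n", x$a10_freq, x$a10_p))
  invisible(x)
}

#' Extract candidate read sequences by mapped strand
#'
#' Convenience helper joining piRNA-candidate alignments back to their
#' read sequences, split by mapping strand, ready for
#' [positional_frequencies()].
#'
#' @param candidates alignments from [filter_pirna_candidates()].
#' @param reads the read set the alignments were computed from.
#' @return list with `sense` and `antisense` character vectors.
#' @export
candidate_sequences <- function(candidates, reads) {
  seqs <- as_named_character(reads)
  list(sense = unname(seqs[candidates$read_id[candidates$strand == "sense"]]),
       antisense = unname(seqs[candidates$read_id[candidates$strand == "antisense"]]))
}
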