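#' Global alignment report for an EVE/virus pair
#'
#' Aligns the endogenous viral element (EVE) copy against its exogenous
#' counterpart with a global (Needleman-Wunsch) alignment (match +1,
#' mismatch -1, gap open 5, gap extend 1 by default), and reports percent
#' nucleotide identity over compared columns together with every maximal
#' run of consecutive identical columns ("identity windows"). Columns
#' falling in an excluded interval -- typically a tandem duplication
#' present in only one sequence, supplied from ground truth or annotation
#' rather than auto-detected -- are dropped from both the identity
#' denominator and the windows. Identity is `matches / compared columns`,
#' where compared columns have a base in both sequences and are not
#' excluded.
#'
#' @param virus,eve single sequences (character or Biostrings objects),
#'   each >= 100 nt.
#' @param exclude optional 0-based half-open `(start, end)` interval to
#'   exclude, in the coordinates of `exclude_on`.
#' @param exclude_on which sequence `exclude` refers to, `"eve"`
#'   (default) or `"virus"`.
#' @param match,mismatch,gap_opening,gap_extension alignment scores.
#' @return object of class `pairwise_report`: `identity_pct`, `matches`,
#'   `compared`, `aligned_length`, `windows` (data.frame of maximal
#'   identity runs with alignment-column and per-sequence coordinates,
#'   sorted, non-overlapping), `degenerate` flag, and the alignment
#'   strings.
#' @export
align_pair <- function(virus, eve, exclude = NULL, exclude_on = c("eve", "virus"),
                       match = 1, mismatch = -1, gap_opening = 5,
                       gap_extension = 1) {
  exclude_on <- match.arg(exclude_on)
  vchr <- toupper(as.character(virus)[1])
  echr <- toupper(as.character(eve)[1])
  if (nchar(vchr) < 100L || nchar(echr) < 100L) {
    stop("both sequences must be >= 100 nt")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(vchr),
                                       Biostrings::DNAString(echr),
                                       type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = gap_opening,
                                       gapExtension = gap_extension)
  va <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ea <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol_aln <- length(va)

  # 0-based per-sequence coordinate of each column's base (NA at gaps)
  vpos <- cumsum(va != "-") - 1L
  vpos[va == "-"] <- NA_integer_
  epos <- cumsum(ea != "-") - 1L
  epos[ea == "-"] <- NA_integer_

  excluded <- rep(FALSE, ncol_aln)
  if (!is.null(exclude)) {
    pos <- if (exclude_on == "eve") epos else vpos
    excluded <- !is.na(pos) & pos >= exclude[1] & pos < exclude[2]
  }

  both <- va != "-" & ea != "-"
  is_base <- va %in% c("A", "C", "G", "T") & ea %in% c("A", "C", "G", "T")
  compared <- both & !excluded
  matches_col <- compared & is_base & va == ea

  n_compared <- sum(compared)
  n_matches <- sum(matches_col)
  degenerate <- n_compared == 0L

  # maximal runs of consecutive identical, non-excluded columns
  r <- rle(matches_col)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  windows <- data.frame(
    col_start = run_start[keep] - 1L,
    col_end = run_end[keep],
    length = r$lengths[keep],
    virus_start = vpos[run_start[keep]],
    virus_end = vpos[run_end[keep]] + 1L,
    eve_start = epos[run_start[keep]],
    eve_end = epos[run_end[keep]] + 1L
  )
  windows <- windows[order(windows$col_start), , drop = FALSE]
  rownames(windows) <- NULL

  structure(list(
    aligned_length = ncol_aln,
    compared = n_compared,
    matches = n_matches,
    identity_pct = if (degenerate) NA_real_ else 100 * n_matches / n_compared,
    windows = windows,
    excluded = exclude,
    excluded_on = if (is.null(exclude)) NULL else exclude_on,
    degenerate = degenerate,
    virus_aligned = paste(va, collapse = ""),
    eve_aligned = paste(ea, collapse = "")
  ), class = "pairwise_report")
}

#' @export
print.pairwise_report <- function(x, ...) {
  cat(sprintf("EVE/virus global alignment: %d columns, %d compared, identity %.1f%%\n",
              x$aligned_length, x$compared, x$identity_pct))
  cat(sprintf("  %d identity windows, longest %d nt\n",
              nrow(x$windows), if (nrow(x$windows)) max(x$windows$length) else 0L))
  invisible(x)
}

#' Build the read-ambiguity mask from an alignment report
#'
#' A small RNA wholly contained in a perfectly conserved stretch cannot be
#' assigned to either the EVE or the virus. The mask is the union of
#' identity windows at least `min_read_len` long (the shortest read that
#' could lie inside one), mapped back to each sequence's own coordinates.
#' Growing `min_read_len` can only shrink the mask.
#'
#' @param report a `pairwise_report` from [align_pair()].
#' @param min_read_len minimum read length considered (default 18).
#' @return object of class `ambiguity_mask`: data.frames `virus` and
#'   `eve` of 0-based half-open intervals, plus `min_read_len`.
#' @export
build_ambiguity_mask <- function(report, min_read_len = 18L) {
  stopifnot(inherits(report, "pairwise_report"))
  w <- report$windows[report$windows$length >= min_read_len, , drop = FALSE]
  structure(list(
    virus = data.frame(start = w$virus_start, end = w$virus_end),
    eve = data.frame(start = w$eve_start, end = w$eve_end),
    min_read_len = min_read_len
  ), class = "ambiguity_mask")
}

in_mask <- function(start, end, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(start[i] >= intervals$start & end[i] <= intervals$end)
  }, logical(1))
}

best_of <- function(aln) {
  o <- order(aln$read_id, -aln$match_fraction, aln$contig_id, aln$start,
             aln$strand == "antisense")
  aln <- aln[o, , drop = FALSE]
  aln[!duplicated(aln$read_id), , drop = FALSE]
}

#' Assign reads to virus, EVE, or ambiguous
#'
#' Maps reads against both references in all-placements mode. A read is
#' `ambiguous` if it reaches the match-fraction threshold on both
#' references (dual mappability is authoritative) or if its placement
#' lies wholly inside an ambiguity-mask interval (the mask is the
#' precomputed fast path to the same judgement); otherwise it is labelled
#' by its unique target, or `unmapped`. Size profiles are computed per
#' label, so EVE-derived reads can be shown piRNA-sized while exogenous
#' virus reads are siRNA-sized.
#'
#' @param reads named character vector or DNAStringSet.
#' @param virus,eve single reference sequences.
#' @param mask optional `ambiguity_mask` from [build_ambiguity_mask()].
#' @param min_match_fraction mapping threshold (default 0.95).
#' @return list with `labels` (data.frame `read_id`, `label`),
#'   `profiles` (per-label `size_profile`s keyed `virus`, `eve`,
#'   `ambiguous`), and `placements` (best placement per mapped read, with
#'   contig ids `virus`/`eve`).
#' @export
assign_reads <- function(reads, virus, eve, mask = NULL,
                         min_match_fraction = 0.95) {
  refs <- c(virus = as.character(virus)[1], eve = as.character(eve)[1])
  aln <- map_reads(reads, refs, min_match_fraction = min_match_fraction,
                   all_placements = TRUE)
  reads <- as_named_character(reads)
  read_ids <- names(reads)
  if (is.null(read_ids)) read_ids <- paste0("read_", seq_along(reads))

  targets <- split(aln$contig_id, aln$read_id)
  n_targets <- vapply(targets, function(x) length(unique(x)), integer(1))
  best <- best_of(aln)
  rownames(best) <- best$read_id

  label <- setNames(rep("unmapped", length(read_ids)), read_ids)
  mapped <- names(targets)
  label[mapped[n_targets[mapped] >= 2L]] <- "ambiguous"
  single <- mapped[n_targets[mapped] == 1L]
  label[single] <- vapply(targets[single], function(x) x[[1]], character(1))

  if (!is.null(mask)) {
    for (ref in c("virus", "eve")) {
      ids <- names(label)[label == ref]
      if (!length(ids)) next
      b <- best[ids, , drop = FALSE]
      masked <- in_mask(b$start, b$end, mask[[ref]])
      label[ids[masked]] <- "ambiguous"
    }
  }

  profiles <- lapply(setNames(c("virus", "eve", "ambiguous"),
                              c("virus", "eve", "ambiguous")), function(lab) {
    ids <- names(label)[label == lab]
    sub <- best[best$read_id %in% ids, , drop = FALSE]
    # profile on a single pooled bin: reads with this label, by length
    sub$contig_id <- rep(lab, nrow(sub))
    size_profile(sub, contig_ids = lab)[[1]]
  })

  list(labels = data.frame(read_id = read_ids,
                           label = unname(label[read_ids]),
                           stringsAsFactors = FALSE),
       profiles = profiles,
       placements = best)
}
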