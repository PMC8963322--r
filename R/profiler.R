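#' Small-RNA size profiles per contig
#'
#' Tabulates mapped-read lengths 18-31 nt per contig, split by strand and
#' combined, with lengths outside 18-31 collected in an `other` bin.
#' `norm21` is the normalized 21-nt abundance, `100 * counts[21] /
#' total_18_31`, i.e. percent of 18-31 nt reads mapped to that contig --
#' the quantity a sharp Dicer-2 peak drives towards 100. Contigs with no
#' 18-31 nt reads are flagged `no_data` and have `norm21 = NA`.
#'
#' @param alignments data.frame from [map_reads()] (best-placement mode:
#'   each read attributed to one contig).
#' @param contig_ids optional character vector of contigs to profile
#'   (defaults to those present in `alignments`); contigs without
#'   alignments yield `no_data` profiles.
#' @return named list of `size_profile` objects, each with `contig_id`,
#'   `counts` (2 x 15 matrix, strands x lengths 18-31 + other),
#'   `combined`, `total_18_31`, `norm21`, `no_data`.
#' @export
size_profile <- function(alignments, contig_ids = NULL) {
  if (is.null(contig_ids)) contig_ids <- sort(unique(alignments$contig_id))
  lens <- alignments$end - alignments$start
  bins <- c(as.character(18:31), "other")
  lapply(setNames(contig_ids, contig_ids), function(cid) {
    sub <- alignments[alignments$contig_id == cid, , drop = FALSE]
    counts <- matrix(0L, nrow = 2L, ncol = length(bins),
                     dimnames = list(c("sense", "antisense"), bins))
    if (nrow(sub)) {
      l <- sub$end - sub$start
      bin <- ifelse(l >= 18L & l <= 31L, as.character(l), "other")
      for (strand in rownames(counts)) {
        tab <- table(factor(bin[sub$strand == strand], levels = bins))
        counts[strand, ] <- as.integer(tab)
      }
    }
    combined <- colSums(counts)
    total <- sum(combined[as.character(18:31)])
    structure(list(
      contig_id = cid,
      counts = counts,
      combined = combined,
      total_18_31 = total,
      norm21 = if (total > 0) 100 * combined[["21"]] / total else NA_real_,
      no_data = total == 0
    ), class = "size_profile")
  })
}

#' @export
print.size_profile <- function(x, ...) {
  cat("Small-RNA size profile for", x$contig_id, "\n")
  if (x$no_data) {
    cat("  no 18-31 nt reads mapped\n")
  } else {
    cat("  total 18-31 nt reads:", x$total_18_31, "\n")
    cat(sprintf("  norm21: %.1f%% of 18-31 nt reads are 21 nt\n", x$norm21))
  }
  invisible(x)
}

#' Flatten size profiles to a table
#' @param profiles result of [size_profile()].
#' @return data.frame with one row per contig: combined counts per length
#'   bin, `total_18_31`, and `norm21`.
#' @export
profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    cbind(data.frame(contig_id = p$contig_id, stringsAsFactors = FALSE),
          as.data.frame(t(p$combined)),
          data.frame(total_18_31 = p$total_18_31, norm21 = p$norm21))
  }))
}

#' Call 21-nt siRNA enrichment for one contig profile
#'
#' A contig is called siRNA-enriched (the signature of an actively
#' silenced, hence replicating, virus) when all three hold:
#' `total_18_31 >= min_reads` (guards against calling on a handful of
#' reads), `counts[21] >= peak_ratio * max(counts[20], counts[22])` (a
#' genuine peak, not a shoulder), and `norm21 >= min_norm21` percent. The
#' numeric cutoffs are declared pipeline policy, configurable and recorded
#' in the returned rationale so every call is auditable.
#'
#' @param profile a `size_profile` object.
#' @param min_reads minimum 18-31 nt read count (default 50).
#' @param min_norm21 minimum norm21 percent (default 20).
#' @param peak_ratio required ratio of the 21-nt count to its largest
#'   neighbour (default 2).
#' @return an object of class `sirna_call`: `call` (logical) plus the
#'   three individual checks and the numbers behind them.
#' @export
call_sirna_enrichment <- function(profile, min_reads = 50L, min_norm21 = 20,
                                  peak_ratio = 2) {
  stopifnot(inherits(profile, "size_profile"))
  n21 <- profile$combined[["21"]]
  neighbor <- max(profile$combined[["20"]], profile$combined[["22"]])
  checks <- c(
    enough_reads = profile$total_18_31 >= min_reads,
    peak = n21 >= peak_ratio * neighbor,
    norm21 = !is.na(profile$norm21) && profile$norm21 >= min_norm21
  )
  structure(list(
    contig_id = profile$contig_id,
    call = all(checks),
    checks = checks,
    total_18_31 = profile$total_18_31,
    count21 = n21,
    neighbor_max = neighbor,
    norm21 = profile$norm21,
    thresholds = c(min_reads = min_reads, min_norm21 = min_norm21,
                   peak_ratio = peak_ratio)
  ), class = "sirna_call")
}

#' @export
print.sirna_call <- function(x, ...) {
  cat(sprintf("siRNA enrichment call for %s: %s\n", x$contig_id,
              if (x$call) "ENRICHED" else "not enriched"))
  cat(sprintf("  reads 18-31: %d (>= %d: %s)\n", x$total_18_31,
              x$thresholds[["min_reads"]], x$checks[["enough_reads"]]))
  cat(sprintf("  21 nt peak: %d vs neighbour max %d x %.1f (%s)\n",
              x$count21, x$neighbor_max, x$thresholds[["peak_ratio"]],
              x$checks[["peak"]]))
  cat(sprintf("  norm21: %.1f%% (>= %.1f%%: %s)\n",
              if (is.na(x$norm21)) NaN else x$norm21,
              x$thresholds[["min_norm21"]], x$checks[["norm21"]]))
  invisible(x)
}
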