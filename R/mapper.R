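#' Map short reads to reference contigs (gapless, strand-aware)
#'
#' Places each 15-40 nt read on every reference contig on both strands and
#' reports placements whose match fraction (`matches / read length`, the
#' "minratio" of short-read mappers run in ratio mode) meets the
#' threshold. Alignment is gapless and substitutions-only: at these read
#' lengths indels are negligible and the match-fraction semantics are
#' exact. Every offset is verified (full sensitivity by construction), so
#' an exhaustive search is reproduced exactly at any threshold. `N` bases
#' never count as matches. Coordinates are 0-based half-open; `sense`
#' means the read equals the contig substring, `antisense` that it equals
#' its reverse complement.
#'
#' With `all_placements = FALSE` (default) only the single best placement
#' per read is reported, ties broken by highest match fraction, then
#' lowest contig id (lexicographic), lowest start, and sense before
#' antisense, giving deterministic output. `all_placements = TRUE` reports
#' every passing placement and is the mode the EVE disambiguation stage
#' relies on.
#'
#' @param reads named character vector or [Biostrings::DNAStringSet]
#'   (A/C/G/T/N only).
#' @param contigs named character vector or [Biostrings::DNAStringSet].
#' @param min_match_fraction minimum match fraction; 0.95 by default
#'   (strict), 0.75 is the relaxed cross-population setting.
#' @param all_placements report all passing placements instead of the
#'   single best one.
#' @return data.frame with columns `read_id`, `contig_id`, `start`, `end`,
#'   `strand`, `matches`, `match_fraction`.
#' @export
map_reads <- function(reads, contigs, min_match_fraction = 0.95,
                      all_placements = FALSE) {
  reads <- as_named_character(reads)
  contigs <- as_named_character(contigs)
  reads[] <- toupper(reads)      # toupper() drops names; [<- keeps them
  contigs[] <- toupper(contigs)
  if (length(contigs) == 0L) stop("contigs must be non-empty")
  if (length(reads) == 0L) {
    return(empty_alignments())
  }
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  if (is.null(names(contigs))) names(contigs) <- paste0("contig_", seq_along(contigs))
  if (min_match_fraction < 0 || min_match_fraction > 1) {
    stop("min_match_fraction must lie in [0,1]")
  }

  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    stop("reads contain non-ACGTN symbols: ",
         paste(utils::head(names(reads)[bad], 5L), collapse = ", "))
  }
  lens <- nchar(reads)
  out_of_range <- lens < 15L | lens > 40L
  if (any(out_of_range)) {
    stop("read lengths outside 15-40 nt: ",
         paste(utils::head(names(reads)[out_of_range], 5L), collapse = ", "))
  }
  if (any(grepl("[^ACGTN]", contigs))) {
    stop("contigs contain non-ACGTN symbols")
  }

  hits <- scan_reads_cpp(unname(reads), names(reads),
                         unname(contigs), names(contigs),
                         min_match_fraction)
  aln <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (nrow(aln) == 0L) return(empty_alignments())

  if (!all_placements) {
    o <- order(aln$read_id, -aln$match_fraction, aln$contig_id, aln$start,
               aln$strand == "antisense")
    aln <- aln[o, , drop = FALSE]
    aln <- aln[!duplicated(aln$read_id), , drop = FALSE]
  }
  rownames(aln) <- NULL
  aln
}

# as.character() drops names (also for character input); keep them
as_named_character <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  x
}

empty_alignments <- function() {
  data.frame(read_id = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             matches = integer(0), match_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' Per-base stranded coverage from alignments
#'
#' Accumulates per-position read depth separately for sense- and
#' antisense-mapped reads on each contig. The summed depth over all
#' positions and strands equals the summed length of the supplied
#' alignments (conservation), since alignments are gapless.
#'
#' @param alignments data.frame from [map_reads()].
#' @param contigs the reference sequences the alignments refer to (used
#'   for contig lengths and referential integrity).
#' @return named list (one element per contig) of lists with `contig_id`,
#'   `sense`, and `antisense` numeric depth vectors.
#' @export
stranded_coverage <- function(alignments, contigs) {
  contigs <- as_named_character(contigs)
  if (is.null(names(contigs))) names(contigs) <- paste0("contig_", seq_along(contigs))
  unknown <- setdiff(unique(alignments$contig_id), names(contigs))
  if (length(unknown)) {
    stop("alignments refer to unknown contigs: ", paste(unknown, collapse = ", "))
  }
  lapply(setNames(names(contigs), names(contigs)), function(cid) {
    len <- nchar(contigs[[cid]])
    cov <- list(contig_id = cid,
                sense = numeric(len), antisense = numeric(len))
    sub <- alignments[alignments$contig_id == cid, , drop = FALSE]
    for (strand in c("sense", "antisense")) {
      ss <- sub[sub$strand == strand, , drop = FALSE]
      if (nrow(ss) == 0L) next
      d <- numeric(len + 1L)
      starts <- table(ss$start + 1L)
      ends <- table(ss$end + 1L)
      d[as.integer(names(starts))] <- d[as.integer(names(starts))] + as.numeric(starts)
      d[as.integer(names(ends))] <- d[as.integer(names(ends))] - as.numeric(ends)
      cov[[strand]] <- cumsum(d)[seq_len(len)]
    }
    cov
  })
}

#' Export stranded coverage as bedGraph tracks
#'
#' Writes one bedGraph file per strand (suffixes `_sense.bedgraph`,
#' `_antisense.bedgraph`) covering all contigs, using the format's 0-based
#' half-open convention. Zero-depth runs are omitted, as is usual for
#' sparse tracks.
#'
#' @param coverage result of [stranded_coverage()].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths written.
#' @export
export_bedgraph <- function(coverage, prefix) {
  paths <- character(0)
  all_ids <- vapply(coverage, function(cov) cov$contig_id, character(1))
  for (strand in c("sense", "antisense")) {
    runs <- do.call(rbind, lapply(coverage, function(cov) {
      r <- S4Vectors::Rle(cov[[strand]])
      ends <- cumsum(S4Vectors::runLength(r))
      starts <- ends - S4Vectors::runLength(r) + 1L
      keep <- S4Vectors::runValue(r) != 0
      data.frame(seq = rep(cov$contig_id, sum(keep)),
                 start = starts[keep], end = ends[keep],
                 score = S4Vectors::runValue(r)[keep])
    }))
    gr <- GenomicRanges::GRanges(
      seqnames = factor(runs$seq, levels = all_ids),
      ranges = IRanges::IRanges(start = runs$start, end = runs$end),
      score = runs$score)
    path <- paste0(prefix, "_", strand, ".bedgraph")
    rtracklayer::export(gr, path, format = "bedGraph")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' @param path input file; format detected from the extension
#'   (`.fq`/`.fastq` as FASTQ, otherwise FASTA).
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_small_rna <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' Write alignments as TSV
#' @param alignments data.frame from [map_reads()].
#' @param path output path.
#' @export
write_alignments <- function(alignments, path) {
  write.table(alignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read alignments written by [write_alignments()]
#' @param path TSV path.
#' @return alignment data.frame.
#' @export
read_alignments <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
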