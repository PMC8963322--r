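# Fixture builders and the independent mapping oracle used across tests.

random_contig <- function(len, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
}

# reads drawn from a contig with 0-4 planted substitutions, random strand,
# plus a share of unrelated random reads
random_read_set <- function(contig, n, seed, max_mut = 4L, frac_random = 0.1) {
  withr::with_seed(seed, {
    G <- nchar(contig)
    reads <- vapply(seq_len(n), function(i) {
      L <- sample(18:31, 1L)
      if (runif(1) < frac_random) {
        r <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
      } else {
        s <- sample.int(G - L + 1L, 1L) - 1L
        r <- substring(contig, s + 1L, s + L)
        nmut <- sample(0:max_mut, 1L)
        if (nmut > 0) {
          rb <- strsplit(r, "")[[1]]
          pos <- sample(L, nmut)
          rb[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
          r <- paste(rb, collapse = "")
        }
      }
      if (runif(1) < 0.5) r <- revcomp(r)
      r
    }, character(1))
    setNames(reads, sprintf("r%04d", seq_len(n)))
  })
}

# Exhaustive mapping oracle built on Biostrings::neditStartingAt: Hamming
# mismatch counts at every offset on both strands, independent of the
# package's own scan. Returns the same columns as map_reads(all placements).
oracle_map <- function(reads, contigs, min_fraction) {
  out <- list()
  for (cid in names(contigs)) {
    subject <- Biostrings::DNAString(contigs[[cid]])
    G <- nchar(contigs[[cid]])
    for (rid in names(reads)) {
      L <- nchar(reads[[rid]])
      if (L > G) next
      min_matches <- ceiling(min_fraction * L - 1e-9)
      for (strand in c("sense", "antisense")) {
        q <- if (strand == "sense") reads[[rid]] else revcomp(reads[[rid]])
        ne <- Biostrings::neditStartingAt(Biostrings::DNAString(q), subject,
                                          starting.at = seq_len(G - L + 1L),
                                          with.indels = FALSE)
        hit <- which(L - ne >= min_matches)
        if (length(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            read_id = rid, contig_id = cid,
            start = hit - 1L, end = hit - 1L + L, strand = strand,
            matches = L - ne[hit],
            match_fraction = (L - ne[hit]) / L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(herivome:::empty_alignments())
  do.call(rbind, out)
}

alignment_key <- function(aln) {
  sort(paste(aln$read_id, aln$contig_id, aln$start, aln$strand, aln$matches))
}

# minimal pairwise_report stand-in for mask tests
fake_report <- function(windows) {
  structure(list(windows = windows), class = "pairwise_report")
}
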