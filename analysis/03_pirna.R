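#!/usr/bin/env Rscript
# Stage 3: filter 24-31 nt piRNA candidates from the mapped reads,
# build positional nucleotide-frequency matrices per strand, and test
# for the ping-pong signature (antisense U1 / sense A10) per segment.

suppressPackageStartupMessages(library(herivome))

sim <- "results/simdata"
out <- "results/pirna"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- Biostrings::readDNAStringSet(file.path(sim, "virus_genome.fa"))
reads <- read_small_rna(file.path(sim, "smallrna.fq"))
aln <- read_alignments("results/profiles/alignments.tsv")

cand <- filter_pirna_candidates(aln)
cat(sprintf("%d piRNA-sized (24-31 nt) candidates of %d mapped reads\n",
            nrow(cand), nrow(aln)))

alpha <- 0.001 / length(genome)  # Bonferroni over segments tested
rows <- list()
for (cid in names(genome)) {
  sub <- cand[cand$contig_id == cid, ]
  sq <- candidate_sequences(sub, reads)
  pfm_s <- positional_frequencies(sq$sense)
  pfm_a <- positional_frequencies(sq$antisense)
  for (strand in c("sense", "antisense")) {
    pfm <- if (strand == "sense") pfm_s else pfm_a
    if (!isTRUE(pfm$no_data)) {
      m <- as.data.frame(pfm$freq)
      m <- cbind(contig_id = cid, strand = strand, base = rownames(pfm$freq), m)
      write.table(m, file.path(out, paste0("pfm_", cid, "_", strand, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  b <- call_bias(sense = pfm_s, antisense = pfm_a, alpha = alpha)
  rows[[cid]] <- data.frame(contig_id = cid, n_candidates = nrow(sub),
                            u1_freq = b$u1_freq, u1_p = b$u1_p,
                            a10_freq = b$a10_freq, a10_p = b$a10_p,
                            verdict = b$verdict)
  cat(sprintf("%s: U1 %.3f (p=%.2g), A10 %.3f (p=%.2g) -> %s\n",
              cid, b$u1_freq, b$u1_p, b$a10_freq, b$a10_p, b$verdict))
}
write.table(do.call(rbind, rows), file.path(out, "bias_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
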