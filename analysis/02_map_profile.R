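#!/usr/bin/env Rscript
# Stage 2: map the small-RNA library to the virus genome, export
# alignments and stranded coverage, build per-segment size profiles, and
# make the 21-nt siRNA enrichment call that diagnoses active silencing
# of a replicating (inherited) virus.

suppressPackageStartupMessages(library(herivome))

sim <- "results/simdata"
out <- "results/profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- Biostrings::readDNAStringSet(file.path(sim, "virus_genome.fa"))
reads <- read_small_rna(file.path(sim, "smallrna.fq"))

aln <- map_reads(reads, genome, min_match_fraction = 0.95)
write_alignments(aln, file.path(out, "alignments.tsv"))
cat(sprintf("Mapped %d/%d reads (best placement, minratio 0.95)\n",
            nrow(aln), length(reads)))

cov <- stranded_coverage(aln, genome)
export_bedgraph(cov, file.path(out, "coverage"))

profiles <- size_profile(aln, contig_ids = names(genome))
tab <- profile_table(profiles)
calls <- lapply(profiles, call_sirna_enrichment)
tab$sirna_call <- vapply(calls[tab$contig_id], `[[`, logical(1), "call")
write.table(tab, file.path(out, "size_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (cid in names(profiles)) {
  p <- profiles[[cid]]
  cat(sprintf("%s: %d reads 18-31 nt, norm21 = %.1f%%, siRNA call: %s\n",
              cid, p$total_18_31, p$norm21,
              if (calls[[cid]]$call) "ENRICHED" else "not enriched"))
}
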