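#!/usr/bin/env Rscript
# Stage 4: align the EVE against its exogenous counterpart, report
# percent identity excluding the duplication, locate perfect-identity
# windows, build the read-ambiguity mask, and assign the EVE-library
# reads to virus / EVE / ambiguous with per-label size profiles.

suppressPackageStartupMessages(library(herivome))

sim <- "results/simdata"
out <- "results/eve"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- Biostrings::readDNAStringSet(file.path(sim, "virus_genome.fa"))
eve <- Biostrings::readDNAStringSet(file.path(sim, "eve.fa"))
truth <- read.delim(file.path(sim, "eve_truth.tsv"))
dup <- unlist(truth[truth$what == "duplication", c("start", "end")])

rep <- align_pair(genome[[1]], eve[[1]], exclude = dup, exclude_on = "eve")
cat(sprintf("EVE vs segment_1: %.1f%% identity over %d compared columns\n",
            rep$identity_pct, rep$compared))
write.table(rep$windows, file.path(out, "identity_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

big <- rep$windows[rep$windows$length >= 31, ]
cat(sprintf("%d perfect-identity windows >= 31 nt (planted motifs: %d)\n",
            nrow(big), sum(truth$what == "motif")))

mask <- build_ambiguity_mask(rep, min_read_len = 18L)
bed <- rbind(cbind(seq = "virus_segment_1", mask$virus),
             cbind(seq = "eve_segment_1", mask$eve))
write.table(bed, file.path(out, "ambiguity_mask.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

reads <- read_small_rna(file.path(sim, "smallrna_eve.fq"))
asg <- assign_reads(reads, genome[[1]], eve[[1]], mask = mask)
write.table(asg$labels, file.path(out, "read_labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(table(asg$labels$label))

for (lab in c("virus", "eve")) {
  p <- asg$profiles[[lab]]
  if (!p$no_data) {
    cat(sprintf("%s-labelled reads: %d in 18-31 nt, norm21 = %.1f%%\n",
                lab, p$total_18_31, p$norm21))
  }
}

lib_truth <- read.delim(file.path(sim, "smallrna_eve_truth.tsv"))
lab <- merge(asg$labels, lib_truth, by = "read_id")
lab$truth_label <- ifelse(lab$contig_id == "virus_segment_1", "virus", "eve")
definite <- lab[lab$label %in% c("virus", "eve"), ]
cat(sprintf("Definite-label accuracy vs truth: %.2f%% (%d reads)\n",
            100 * mean(definite$label == definite$truth_label),
            nrow(definite)))
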