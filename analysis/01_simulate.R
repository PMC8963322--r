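#!/usr/bin/env Rscript
# Stage 1: generate every input the downstream stages consume, from one
# seeded configuration: a trisegmented virus genome, an EVE copy of
# segment 1 (22% diverged, tandem duplication, three conserved motifs),
# a mixed siRNA/piRNA ovary-like small-RNA library per segment, and
# codiverging host COI / virus loci for six regional populations.

suppressPackageStartupMessages(library(herivome))

out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1L)
jsonlite::write_json(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                     file.path(out, "config.json"),
                     auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

genome <- simulate_virus_genome(cfg)
Biostrings::writeXStringSet(genome, file.path(out, "virus_genome.fa"))

ev <- simulate_eve(genome[[1]], cfg)
Biostrings::writeXStringSet(ev$eve, file.path(out, "eve.fa"))
write.table(cbind(what = c(rep("motif", nrow(ev$motifs_eve)), "duplication"),
                  rbind(ev$motifs_eve,
                        data.frame(start = ev$duplication_eve[1],
                                   end = ev$duplication_eve[2]))),
            file.path(out, "eve_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

lib <- simulate_small_rna_library(genome, cfg)
write_reads_fastq(lib$reads, file.path(out, "smallrna.fq"))
write.table(lib$truth, file.path(out, "smallrna_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# a second library drawn from the EVE, piRNA-dominated, for stage 4
cfg_eve_lib <- simulation_config(seed = 2L, sirna_fraction_21 = 0.1,
                                 reads_per_contig = 5000L)
lib_eve <- simulate_small_rna_library(
  c(virus_segment_1 = as.character(genome[[1]]),
    eve_segment_1 = as.character(ev$eve[[1]])), cfg_eve_lib)
write_reads_fastq(lib_eve$reads, file.path(out, "smallrna_eve.fq"))
write.table(lib_eve$truth, file.path(out, "smallrna_eve_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

loci <- simulate_codiverging_loci(cfg)
Biostrings::writeXStringSet(loci$host_alignment, file.path(out, "host_coi.fa"))
Biostrings::writeXStringSet(loci$virus_alignment,
                            file.path(out, "virus_locus.fa"))
ape::write.tree(loci$tree, file.path(out, "true_tree.nwk"))

file.copy(system.file("extdata", "screening_synthetic.tsv",
                      package = "herivome"),
          file.path(out, "screening.tsv"), overwrite = TRUE)

cat("Simulated inputs written to", out, "\n")
cat("  genome segments:", length(genome),
    "x", unique(Biostrings::width(genome)), "nt\n")
cat("  EVE length:", Biostrings::width(ev$eve), "nt;",
    ev$n_substitutions, "substitutions planted\n")
cat("  small-RNA reads:", length(lib$reads), "(genome library),",
    length(lib_eve$reads), "(EVE library)\n")
cat("  codiverging taxa:", length(loci$tree$tip.label), "haplotypes from",
    length(loci$populations), "populations\n")
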