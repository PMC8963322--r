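test_that("configuration validation rejects inconsistent settings", {
  expect_error(simulation_config(u1_prob = 1.2), "probabilities")
  expect_error(simulation_config(pirna_length_weights = c(
    "24" = 0.5, "25" = 0.6, "26" = 0, "27" = 0, "28" = 0, "29" = 0,
    "30" = 0, "31" = 0)), "sum to 1")
  expect_error(simulation_config(eve_divergence = 0.8), "eve_divergence")
  expect_error(simulation_config(conserved_motifs = list(c(150L, 40L))),
               "overlaps the duplication")
  st <- default_split_times(4L)
  st[1, 2] <- st[2, 1] <- 0.9  # deeper than the root: violates three-point
  expect_error(simulation_config(n_populations = 4L, split_times = st),
               "ultrametric")
})

test_that("genome simulation is deterministic, sized, and guarded", {
  cfg <- simulation_config(seed = 1, n_segments = 3L, genome_length = 1000L,
                           eve_duplication = c(100L, 300L),
                           conserved_motifs = list(c(500L, 35L)))
  g1 <- simulate_virus_genome(cfg)
  g2 <- simulate_virus_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  expect_length(g1, 3L)
  expect_true(all(Biostrings::width(g1) == 1000L))
  expect_identical(names(g1), c("segment_1", "segment_2", "segment_3"))

  other <- simulate_virus_genome(simulation_config(seed = 2, n_segments = 3L,
    genome_length = 1000L, eve_duplication = c(100L, 300L),
    conserved_motifs = list(c(500L, 35L))))
  expect_false(identical(as.character(g1), as.character(other)))

  tiny <- simulation_config(genome_length = 0L, eve_duplication = NULL,
                            conserved_motifs = list())
  expect_error(simulate_virus_genome(tiny), ">= 200")
})

test_that("EVE simulation honours divergence, motifs, and tandem duplication", {
  cfg0 <- simulation_config(seed = 3, eve_divergence = 0,
                            eve_duplication = NULL,
                            conserved_motifs = list())
  g <- simulate_virus_genome(cfg0)
  ev0 <- simulate_eve(g[[1]], cfg0)
  expect_identical(as.character(ev0$eve[[1]]), as.character(g[[1]]))
  expect_identical(ev0$n_substitutions, 0L)

  cfg <- simulation_config(seed = 3, eve_duplication = c(50L, 150L))
  evd <- simulate_eve(g[[1]], cfg)
  expect_equal(Biostrings::width(evd$eve), Biostrings::width(g[1]) + 100L)
  expect_identical(evd$duplication_eve, c(150L, 250L))

  # realized identity outside motifs: oracle = direct position-wise
  # comparison after removing the tandem copy
  cfg22 <- simulation_config(seed = 5)
  ev <- simulate_eve(g[[1]], cfg22)
  vb <- strsplit(as.character(g[[1]]), "")[[1]]
  eb <- strsplit(as.character(ev$eve[[1]]), "")[[1]]
  de <- ev$duplication_eve
  eb <- eb[-((de[1] + 1L):de[2])]
  protected <- logical(length(vb))
  for (i in seq_len(nrow(ev$motifs_virus))) {
    protected[(ev$motifs_virus$start[i] + 1L):ev$motifs_virus$end[i]] <- TRUE
  }
  ident_outside <- mean(vb[!protected] == eb[!protected])
  se <- sqrt(0.22 * 0.78 / sum(!protected))
  expect_lt(abs(ident_outside - 0.78), 3 * se)
  expect_true(all(vb[protected] == eb[protected]))

  bad <- cfg22
  bad$conserved_motifs <- list(c(5000L, 31L))
  expect_error(simulate_eve(g[[1]], bad), "bounds")
})

test_that("small-RNA library matches its truth table and class structure", {
  cfg <- simulation_config(seed = 7, reads_per_contig = 1000L, n_segments = 1L)
  g <- simulate_virus_genome(cfg)
  lib <- simulate_small_rna_library(g, cfg)
  expect_identical(length(lib$reads), nrow(lib$truth))
  expect_identical(names(lib$reads), lib$truth$read_id)
  expect_false(any(duplicated(lib$truth$read_id)))
  expect_identical(Biostrings::width(lib$reads), lib$truth$length)
  expect_true(all(lib$truth$length[lib$truth$class == "siRNA"] == 21L))
  expect_true(all(lib$truth$length[lib$truth$class == "piRNA"] %in% 24:31))

  # determinism
  lib2 <- simulate_small_rna_library(g, cfg)
  expect_identical(as.character(lib$reads), as.character(lib2$reads))

  expect_error(simulate_small_rna_library(character(0), cfg), "empty contig")
})

test_that("siRNA-only libraries are pure 21-mers and u1_prob=1 forces 5' U", {
  cfg <- simulation_config(seed = 8, sirna_fraction_21 = 1, n_segments = 1L,
                           reads_per_contig = 1000L)
  g <- simulate_virus_genome(cfg)
  lib <- simulate_small_rna_library(g, cfg)
  expect_true(all(Biostrings::width(lib$reads) == 21L))

  cfgp <- simulation_config(seed = 8, sirna_fraction_21 = 0, u1_prob = 1,
                            n_segments = 1L, reads_per_contig = 1000L)
  libp <- simulate_small_rna_library(g, cfgp)
  anti <- as.character(libp$reads)[libp$truth$strand == "antisense"]
  expect_true(all(substring(anti, 1, 1) == "T"))
})

test_that("antisense U1 frequency is binomial around u1_prob", {
  cfg <- simulation_config(seed = 9, sirna_fraction_21 = 0, u1_prob = 0.8,
                           n_segments = 1L, reads_per_contig = 10000L)
  g <- simulate_virus_genome(cfg)
  lib <- simulate_small_rna_library(g, cfg)
  anti <- as.character(lib$reads)[lib$truth$strand == "antisense"]
  n <- length(anti)
  obs <- mean(substring(anti, 1, 1) == "T")
  expect_lt(abs(obs - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  # oracle: exact binomial CI contains the configured probability
  ci <- binom.test(sum(substring(anti, 1, 1) == "T"), n)$conf.int
  expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])
})

test_that("piRNA length distribution converges to its weights", {
  cfg <- simulation_config(seed = 10, sirna_fraction_21 = 0, n_segments = 1L,
                           reads_per_contig = 50000L)
  g <- simulate_virus_genome(cfg)
  lib <- simulate_small_rna_library(g, cfg)
  counts <- table(factor(lib$truth$length, levels = 24:31))
  gof <- chisq.test(counts, p = cfg$pirna_length_weights)
  expect_gt(gof$p.value, 0.001)
})

test_that("codiverging loci accumulate the clock-expected divergence", {
  st <- matrix(c(0, 0.407, 0.407, 0), 2, 2,
               dimnames = list(c("AK", "WI"), c("AK", "WI")))
  cfg <- simulation_config(seed = 11, n_populations = 2L, split_times = st,
                           coi_length = 10000L,
                           haplotypes_per_population = 1L)
  loci <- simulate_codiverging_loci(cfg)
  d <- p_distance_matrix(loci$host_alignment)["AK", "WI"]
  expected <- 2 * 0.0354 * 0.407  # 2.88%
  expect_lt(abs(d - expected), 3 * sqrt(expected * (1 - expected) / 10000))

  # same seed, same alignments; zero split time, identical sequences
  loci2 <- simulate_codiverging_loci(cfg)
  expect_identical(as.character(loci$host_alignment),
                   as.character(loci2$host_alignment))

  st0 <- matrix(0, 2, 2, dimnames = dimnames(st))
  cfg0 <- simulation_config(seed = 11, n_populations = 2L, split_times = st0,
                            haplotypes_per_population = 1L)
  loci0 <- simulate_codiverging_loci(cfg0)
  expect_identical(as.character(loci0$host_alignment[[1]]),
                   as.character(loci0$host_alignment[[2]]))
})
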