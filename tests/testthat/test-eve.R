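test_that("identical sequences align at 100% identity in one window", {
  s <- random_contig(400, seed = 51)
  rep <- align_pair(s, s)
  expect_identical(rep$identity_pct, 100)
  expect_identical(nrow(rep$windows), 1L)
  expect_identical(rep$windows$length, 400L)
  expect_error(align_pair("ACGT", s), ">= 100")
})

test_that("synthetic EVE pair recovers identity and planted motifs", {
  cfg <- simulation_config(seed = 52)
  g <- simulate_virus_genome(cfg)
  ev <- simulate_eve(g[[1]], cfg)
  rep <- align_pair(g[[1]], ev$eve[[1]], exclude = ev$duplication_eve,
                    exclude_on = "eve")

  # oracle: direct position-wise identity of the generated pair with the
  # tandem copy removed (no indels elsewhere by construction)
  vb <- strsplit(as.character(g[[1]]), "")[[1]]
  eb <- strsplit(as.character(ev$eve[[1]]), "")[[1]]
  de <- ev$duplication_eve
  eb_flat <- eb[-((de[1] + 1L):de[2])]
  realized <- 100 * mean(vb == eb_flat)
  expect_lt(abs(rep$identity_pct - realized), 1)

  # exactly the three planted conserved motifs appear as windows >= 31 nt
  big <- rep$windows[rep$windows$length >= 31L, ]
  expect_identical(nrow(big), 3L)
  for (i in 1:3) {
    m <- ev$motifs_eve[i, ]
    hit <- big$eve_start <= m$start & big$eve_end >= m$end
    expect_identical(sum(hit), 1L)
  }
})

test_that("excluding the duplication leaves identity as if it never existed", {
  cfg_dup <- simulation_config(seed = 53)
  cfg_nodup <- simulation_config(seed = 53, eve_duplication = NULL)
  g <- simulate_virus_genome(cfg_dup)
  ev_dup <- simulate_eve(g[[1]], cfg_dup)
  ev_nodup <- simulate_eve(g[[1]], cfg_nodup)
  rep_dup <- align_pair(g[[1]], ev_dup$eve[[1]],
                        exclude = ev_dup$duplication_eve, exclude_on = "eve")
  rep_nodup <- align_pair(g[[1]], ev_nodup$eve[[1]])
  expect_lt(abs(rep_dup$identity_pct - rep_nodup$identity_pct), 0.5)
})

test_that("ambiguity mask keeps only windows a read could hide in", {
  win <- data.frame(col_start = c(0L, 100L, 300L), col_end = c(12L, 120L, 335L),
                    length = c(12L, 20L, 35L),
                    virus_start = c(0L, 100L, 300L), virus_end = c(12L, 120L, 335L),
                    eve_start = c(0L, 150L, 350L), eve_end = c(12L, 170L, 385L))
  mask <- build_ambiguity_mask(fake_report(win), min_read_len = 18L)
  expect_identical(nrow(mask$virus), 2L)
  expect_identical(mask$virus$start, c(100L, 300L))
  expect_identical(mask$eve$start, c(150L, 350L))

  none <- build_ambiguity_mask(fake_report(win[win$length < 18, ]),
                               min_read_len = 18L)
  expect_identical(nrow(none$virus), 0L)

  # monotonicity: a larger minimum read length can only shrink the mask
  m18 <- build_ambiguity_mask(fake_report(win), 18L)
  m24 <- build_ambiguity_mask(fake_report(win), 24L)
  expect_true(nrow(m24$virus) <= nrow(m18$virus))
})

test_that("long perfect windows are rare but 15-17 nt near-matches common", {
  cfg <- simulation_config(seed = 54, genome_length = 5000L,
                           eve_duplication = NULL, conserved_motifs = list())
  g <- simulate_virus_genome(cfg)
  ev <- simulate_eve(g[[1]], cfg)
  rep <- align_pair(g[[1]], ev$eve[[1]])
  n_short <- sum(rep$windows$length >= 15L & rep$windows$length <= 17L)
  n_long <- sum(rep$windows$length >= 24L)
  expect_gt(n_short, n_long)
  # long perfect windows are a rare minority of all identity windows
  expect_lt(n_long / nrow(rep$windows), 0.05)
})

test_that("reads are assigned to their true source with motif reads ambiguous", {
  cfg <- simulation_config(seed = 55, n_segments = 1L,
                           reads_per_contig = 2000L, sirna_fraction_21 = 0.5)
  g <- simulate_virus_genome(cfg)
  ev <- simulate_eve(g[[1]], cfg)
  rep <- align_pair(g[[1]], ev$eve[[1]], exclude = ev$duplication_eve,
                    exclude_on = "eve")
  mask <- build_ambiguity_mask(rep)

  refs <- c(virus = as.character(g[[1]]), eve = as.character(ev$eve[[1]]))
  lib <- simulate_small_rna_library(refs, cfg)
  asg <- assign_reads(lib$reads, refs[["virus"]], refs[["eve"]], mask = mask)

  lab <- merge(asg$labels, lib$truth, by = "read_id")
  definite <- lab[lab$label %in% c("virus", "eve"), ]
  acc <- mean(definite$label == definite$contig_id)
  expect_gte(acc, 0.99)

  # every read wholly inside a planted motif is ambiguous
  for (i in seq_len(nrow(ev$motifs_virus))) {
    m <- ev$motifs_virus[i, ]
    inside <- lab$contig_id == "virus" &
      lab$start >= m$start & (lab$start + lab$length) <= m$end
    if (any(inside)) {
      expect_true(all(lab$label[inside] == "ambiguous"))
    }
  }
})

test_that("assignment is symmetric under swapping the references", {
  cfg <- simulation_config(seed = 56, n_segments = 1L, reads_per_contig = 400L)
  g <- simulate_virus_genome(cfg)
  ev <- simulate_eve(g[[1]], cfg)
  refs <- c(virus = as.character(g[[1]]), eve = as.character(ev$eve[[1]]))
  lib <- simulate_small_rna_library(refs, cfg)
  a1 <- assign_reads(lib$reads, refs[["virus"]], refs[["eve"]])
  a2 <- assign_reads(lib$reads, refs[["eve"]], refs[["virus"]])
  amb1 <- a1$labels$read_id[a1$labels$label == "ambiguous"]
  amb2 <- a2$labels$read_id[a2$labels$label == "ambiguous"]
  expect_setequal(amb1, amb2)
  expect_setequal(a1$labels$read_id[a1$labels$label == "virus"],
                  a2$labels$read_id[a2$labels$label == "eve"])
})

test_that("ambiguity saturates at zero divergence and vanishes at high", {
  cfg0 <- simulation_config(seed = 57, n_segments = 1L, eve_divergence = 0,
                            eve_duplication = NULL, conserved_motifs = list(),
                            reads_per_contig = 300L)
  g <- simulate_virus_genome(cfg0)
  ev0 <- simulate_eve(g[[1]], cfg0)
  lib0 <- simulate_small_rna_library(g, cfg0)
  a0 <- assign_reads(lib0$reads, g[[1]], ev0$eve[[1]])
  mapped0 <- a0$labels$label != "unmapped"
  expect_true(all(a0$labels$label[mapped0] == "ambiguous"))

  cfg45 <- simulation_config(seed = 58, n_segments = 1L, eve_divergence = 0.45,
                             eve_duplication = NULL, conserved_motifs = list(),
                             reads_per_contig = 300L)
  ev45 <- simulate_eve(g[[1]], cfg45)
  lib45 <- simulate_small_rna_library(g, cfg45)
  a45 <- assign_reads(lib45$reads, g[[1]], ev45$eve[[1]])
  amb_frac <- mean(a45$labels$label == "ambiguous")
  expect_lt(amb_frac, 0.01)

  # per-label size profiles: an EVE-only piRNA library peaks at 25-30 nt
  cfg_eve <- simulation_config(seed = 59, n_segments = 1L,
                               sirna_fraction_21 = 0, reads_per_contig = 500L)
  ev <- simulate_eve(g[[1]], cfg_eve)
  lib_eve <- simulate_small_rna_library(
    c(eve = as.character(ev$eve[[1]])), cfg_eve)
  a_eve <- assign_reads(lib_eve$reads, g[[1]], ev$eve[[1]])
  expect_lt(sum(a_eve$labels$label == "virus"), 5L)
  prof <- a_eve$profiles$eve
  peak_25_30 <- sum(prof$combined[as.character(25:30)])
  expect_gt(peak_25_30 / prof$total_18_31, 0.5)
})
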