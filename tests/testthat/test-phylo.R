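test_that("p-distance matches hand counts and excludes gaps pairwise", {
  expect_identical(p_distance_matrix(c(a = "ACGTACGTAC",
                                       b = "ACGTACGTAC"))["a", "b"], 0)
  # 10 columns, 3 differences
  d <- p_distance_matrix(c(a = "ACGTACGTAC", b = "TCGTACGTGG"))
  expect_identical(d["a", "b"], 0.3)

  # gap and N columns drop out of the denominator for that pair only
  d2 <- p_distance_matrix(c(a = "AC-TACGTAN", b = "ACGTACGTAC",
                            c = "ACGTACGTAC"))
  expect_identical(d2["a", "b"], 0)      # 8 comparable, all equal
  expect_identical(d2["b", "c"], 0)      # full 10 columns
  expect_true(is.na(suppressWarnings(
    p_distance_matrix(c(a = "NNNN", b = "ACGT"))["a", "b"])))
  expect_warning(p_distance_matrix(c(a = "NNNN", b = "ACGT")), "comparable")
  expect_error(p_distance_matrix(c(a = "ACGT")), "at least 2")
  expect_error(p_distance_matrix(c(a = "ACGT", b = "ACGTA")), "aligned")
})

test_that("p-distance agrees with the ape reference implementation", {
  seqs <- withr::with_seed(61, {
    vapply(1:6, function(i) paste(sample(c("A", "C", "G", "T", "-", "N"), 300,
      replace = TRUE, prob = c(0.23, 0.23, 0.23, 0.23, 0.04, 0.04)),
      collapse = ""), character(1))
  })
  names(seqs) <- paste0("t", 1:6)
  mine <- p_distance_matrix(seqs)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-12)
})

test_that("p-distance satisfies the triangle inequality on gap-free triples", {
  withr::with_seed(62, {
    for (i in 1:20) {
      seqs <- vapply(1:3, function(j) paste(
        sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""),
        character(1))
      names(seqs) <- c("x", "y", "z")
      d <- p_distance_matrix(seqs)
      expect_lte(d["x", "z"], d["x", "y"] + d["y", "z"] + 1e-12)
    }
  })
})

test_that("NJ recovers additive matrices and random trees exactly", {
  # known 4-taxon additive matrix
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  d <- cophenetic(tr)
  rec <- nj_tree(d)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(rec)), 0)
  expect_equal(cophenetic(rec)[rownames(d), colnames(d)], d, tolerance = 1e-10)

  # oracle round trip on random binary trees
  withr::with_seed(63, {
    for (n in c(5, 10, 20)) {
      tr <- ape::rtree(n)
      tr$edge.length <- tr$edge.length + 0.1
      rec <- nj_tree(cophenetic(tr))
      expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(rec)), 0)
    }
  })

  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)  # 1
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)  # 2
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)  # 3

  d_na <- d3; d_na[1, 2] <- NA
  expect_error(nj_tree(d_na), "missing")
})

test_that("congruence distinguishes identical from conflicting topologies", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  same <- congruence(t1, t1, permutations = 99)
  expect_equal(same$rf, 0)
  expect_equal(same$rf_normalized, 0)

  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  diff <- congruence(t1, t2, permutations = 99)
  expect_equal(diff$rf_normalized, 1)

  t3 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(congruence(t1, t3), "leaf set")
})

test_that("clock dating reproduces the COI calibration arithmetic", {
  est <- clock_date(0.0288, 0.0354)
  expect_equal(est$tmrca_years, 0.0288 / 0.0354 * 1e6)  # ~813,559 years
  expect_identical(est$tmrca_rounded, 8e5)

  expect_identical(clock_date(0, 0.0354)$tmrca_years, 0)
  expect_identical(clock_date(0.0354, 0.0354)$tmrca_years, 1e6)
  expect_error(clock_date(0.03, 0), "rate")

  # linear in divergence, inverse in rate
  for (k in c(0.5, 2, 3)) {
    expect_equal(clock_date(k * 0.0288, 0.0354)$tmrca_years,
                 k * est$tmrca_years)
    expect_equal(clock_date(0.0288, k * 0.0354)$tmrca_years,
                 est$tmrca_years / k)
  }
})

test_that("prevalence arithmetic and exact binomial intervals", {
  toy <- data.frame(population = c("p1", "p2"),
                    n_screened = c(10L, 10L), n_positive = c(2L, 1L))
  expect_identical(prevalence(toy)$overall_pct, 15)

  one <- function(n, x) prevalence(data.frame(population = "p",
                                              n_screened = n, n_positive = x))
  expect_identical(one(353L, 39L)$overall_pct, 11)
  expect_identical(one(353L, 40L)$overall_pct, 11.3)

  z <- one(100L, 0L)
  expect_identical(z$overall_pct, 0)
  expect_identical(unname(z$overall_ci[1]), 0)
  expect_identical(unname(z$overall_ci[2]), 3.6)

  expect_error(prevalence(data.frame(population = "p", n_screened = 0L,
                                     n_positive = 0L)), "screened")
  expect_error(prevalence(data.frame(population = "p", n_screened = 5L,
                                     n_positive = 6L)), "n_positive")
})

test_that("simulated codivergence yields congruent NJ trees", {
  cfg <- simulation_config(seed = 64, coi_length = 10000L,
                           virus_locus_length = 2000L)
  loci <- simulate_codiverging_loci(cfg)
  ht <- nj_tree(p_distance_matrix(loci$host_alignment))
  vt <- nj_tree(p_distance_matrix(loci$virus_alignment))
  expect_equal(phangorn::RF.dist(ape::unroot(ht), ape::unroot(vt)), 0)
  # both recover the generating population tree
  expect_equal(phangorn::RF.dist(ape::unroot(ht),
                                     ape::unroot(loci$tree)), 0)
})
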