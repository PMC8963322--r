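#' Uncorrected pairwise p-distance matrix
#'
#' For each pair of aligned sequences, the proportion of differing sites
#' over columns where both sequences have an unambiguous base (A/C/G/T);
#' gaps and Ns are excluded pairwise. Uncorrected distances are used
#' deliberately: percent-divergence clock rates are quoted on the raw
#' scale, so no multiple-hit correction is applied.
#'
#' @param aln aligned sequences of equal length: a
#'   [Biostrings::DNAStringSet], named character vector, or character
#'   matrix (taxa x sites).
#' @return symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`; a pair with no comparable columns is `NA` (flagged with a
#'   warning).
#' @export
p_distance_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else {
    ch <- as_named_character(aln)
    ch[] <- toupper(ch)
    if (length(unique(nchar(ch))) != 1L) {
      stop("sequences must be aligned (equal length)")
    }
    m <- do.call(rbind, strsplit(ch, ""))
    rownames(m) <- names(ch)
  }
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(m))) rownames(m) <- paste0("taxon_", seq_len(n))
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        warning("no comparable columns for pair ", rownames(m)[i], " / ",
                rownames(m)[j])
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]); on an
#' additive matrix the generating topology and branch lengths are
#' recovered exactly. Output is an unrooted [ape::phylo]; root for
#' display only (e.g. midpoint) since congruence statistics are computed
#' unrooted.
#'
#' @param d symmetric distance matrix with taxon dimnames (no missing
#'   entries) or a `dist` object.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (any(is.na(d))) stop("distance matrix has missing entries")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  ape::nj(as.dist(d))
}

#' Host-virus phylogenetic congruence
#'
#' Quantifies codivergence between a host tree and a virus tree on the
#' same leaf set (the host<->virus pairing is given by matching labels):
#' Robinson-Foulds distance on unrooted topologies, its normalized form
#' (divided by `2(n-3)`), and a Mantel-type Pearson correlation of the
#' two distance matrices with a taxa-permutation null. Under genuine
#' codivergence RF is 0 and the permutation p-value is small; under
#' independent evolution the p-value is uniform.
#'
#' @param host_tree,virus_tree [ape::phylo] trees with identical leaf
#'   sets.
#' @param host_dist,virus_dist optional distance matrices (taxa
#'   dimnames); defaults to the trees' cophenetic (path-length) matrices.
#' @param permutations number of Mantel permutations (default 9999).
#' @return list: `rf`, `rf_normalized`, `r` (Pearson correlation of
#'   distances), `p` (permutation p-value), `n_taxa`, `permutations`.
#' @export
congruence <- function(host_tree, virus_tree, host_dist = NULL,
                       virus_dist = NULL, permutations = 9999) {
  if (!setequal(host_tree$tip.label, virus_tree$tip.label)) {
    stop("host and virus trees must share an identical leaf set")
  }
  n <- length(host_tree$tip.label)
  rf <- phangorn::RF.dist(ape::unroot(host_tree), ape::unroot(virus_tree))
  rf_norm <- if (n > 3L) rf / (2 * (n - 3L)) else 0
  if (is.null(host_dist)) host_dist <- cophenetic(host_tree)
  if (is.null(virus_dist)) virus_dist <- cophenetic(virus_tree)
  taxa <- sort(host_tree$tip.label)
  hd <- host_dist[taxa, taxa]
  vd <- virus_dist[taxa, taxa]
  mt <- vegan::mantel(as.dist(hd), as.dist(vd), method = "pearson",
                      permutations = permutations)
  list(rf = rf, rf_normalized = rf_norm,
       r = unname(mt$statistic), p = mt$signif,
       n_taxa = n, permutations = permutations)
}

#' Molecular-clock dating from divergence and rate
#'
#' Converts an observed pairwise divergence and a pairwise clock rate
#' (proportion of divergence accumulated between two lineages per million
#' years -- the convention of insect mitochondrial "percent per My"
#' clocks) into a time to most recent common ancestor:
#' `tmrca_years = divergence / rate x 1e6`, also reported rounded to the
#' nearest 100,000 years.
#'
#' @param divergence pairwise divergence as a proportion (e.g. 0.0288).
#' @param rate clock rate as a proportion per million years (e.g.
#'   0.0354).
#' @return object of class `clock_estimate`: `divergence`, `rate`,
#'   `tmrca_years`, `tmrca_rounded`.
#' @export
clock_date <- function(divergence, rate) {
  if (rate <= 0) stop("rate must be positive")
  if (divergence < 0) stop("divergence must be nonnegative")
  years <- divergence / rate * 1e6
  structure(list(divergence = divergence, rate = rate,
                 tmrca_years = years,
                 tmrca_rounded = round(years / 1e5) * 1e5),
            class = "clock_estimate")
}

#' @export
print.clock_estimate <- function(x, ...) {
  cat(sprintf("Clock estimate: %.2f%% divergence at %.2f%%/My -> %s years",
              100 * x$divergence, 100 * x$rate,
              format(round(x$tmrca_years), big.mark = ",", scientific = FALSE)),
      "\n")
  cat(sprintf("  rounded to nearest 100,000: %s years\n",
              format(x$tmrca_rounded, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Infection prevalence from a screening table
#'
#' Overall prevalence is total positives over total screened, as a
#' percent rounded to one decimal; per-population prevalence likewise,
#' with exact (Clopper-Pearson) 95% binomial confidence intervals.
#'
#' @param table data.frame with columns `population`, `n_screened`,
#'   `n_positive`.
#' @return list: `overall_pct`, `overall_ci` (percent), `n_screened`,
#'   `n_positive`, and `per_population` (data.frame with percent and CI
#'   columns).
#' @export
prevalence <- function(table) {
  req <- c("population", "n_screened", "n_positive")
  if (!all(req %in% names(table))) {
    stop("screening table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(table$n_screened <= 0)) stop("zero (or negative) screened in a row")
  if (any(table$n_positive < 0 | table$n_positive > table$n_screened)) {
    stop("n_positive must lie in [0, n_screened]")
  }
  tot_n <- sum(table$n_screened)
  tot_pos <- sum(table$n_positive)
  ci <- binom.test(tot_pos, tot_n)$conf.int * 100
  per <- table
  cis <- t(vapply(seq_len(nrow(table)), function(i) {
    binom.test(table$n_positive[i], table$n_screened[i])$conf.int * 100
  }, numeric(2)))
  per$percent <- round(100 * per$n_positive / per$n_screened, 1)
  per$ci_lower <- round(cis[, 1], 1)
  per$ci_upper <- round(cis[, 2], 1)
  list(overall_pct = round(100 * tot_pos / tot_n, 1),
       overall_ci = round(ci, 1),
       n_screened = tot_n, n_positive = tot_pos,
       per_population = per)
}

#' Read a screening table from TSV
#' @param path TSV with columns population, n_screened, n_positive.
#' @return data.frame.
#' @export
read_screening_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
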