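#' Simulation configuration for the inherited-virome pipeline
#'
#' Bundles every tunable of the data generator into a single validated,
#' seeded configuration. The defaults describe the study system the
#' pipeline is aimed at: a trisegmented negative-sense RNA virus of an
#' insect whose small-RNA response is dominated by 21-nt siRNAs on both
#' strands, with a 24-31 nt piRNA population carrying an antisense 5'-U
#' (U1) and sense position-10 A (A10) bias; an endogenous viral element
#' (EVE) copy of one segment at ~22% nucleotide divergence containing a
#' tandem partial gene duplication and three short perfectly conserved
#' motifs; and six geographically isolated host populations whose
#' mitochondrial COI and virus loci codiverge under a clock, the deepest
#' split placed so that the most divergent population pair reaches ~2.88%
#' COI divergence.
#'
#' All sequences are stored DNA-alphabet (U written as T). All intervals
#' are 0-based half-open.
#'
#' @param seed integer seed; the full generator output is a pure function
#'   of (config, seed).
#' @param genome_length length (nt) of each simulated genome segment.
#' @param n_segments number of genome segments.
#' @param sirna_fraction_21 probability a simulated read is a 21-nt
#'   siRNA-class read (the remainder are piRNA-class).
#' @param pirna_length_weights named probability vector over piRNA read
#'   lengths 24-31; must sum to 1.
#' @param u1_prob probability an antisense piRNA-class read carries U at
#'   position 1 (drawn U with this probability, else uniform over A/C/G,
#'   so the realised U1 frequency equals `u1_prob`).
#' @param a10_prob probability a sense piRNA-class read carries A at
#'   position 10 (same drawing scheme).
#' @param strand_balance probability a read originates from the antisense
#'   strand.
#' @param eve_divergence per-site substitution probability applied outside
#'   conserved motifs when deriving the EVE copy; in `[0, 0.75]`.
#' @param eve_duplication 0-based half-open `(start, end)` interval of the
#'   virus segment duplicated in tandem in the EVE, or `NULL` for none.
#' @param conserved_motifs list of `(start, length)` pairs held perfectly
#'   identical between EVE and virus; must not overlap the duplication.
#' @param n_populations number of host populations (>= 2).
#' @param clock_rate per-lineage substitution rate as a proportion of
#'   sites per million years; expected pairwise divergence between two
#'   populations split `T` My ago is `2 * clock_rate * T`. (Note this is
#'   half the "percent divergence per My" pairwise-clock convention used
#'   by [clock_date()].)
#' @param split_times symmetric matrix of population split times (My),
#'   zero diagonal, ultrametric-consistent. `NULL` uses a default: the
#'   named six-region matrix when `n_populations == 6`, otherwise a
#'   ladder with deepest split 0.407 My.
#' @param reads_per_contig reads simulated per reference contig.
#' @param coi_length host COI locus length in nt (default 658, the
#'   standard barcode fragment).
#' @param virus_locus_length virus locus length in nt.
#' @param virus_rate_scale multiplier on `clock_rate` for the virus locus.
#' @param haplotypes_per_population haplotypes sampled per population in
#'   the codivergence simulation (default 2, reflecting that several
#'   individuals are sequenced per region in a real screen).
#' @param within_pop_time coalescent depth (My) of haplotypes within one
#'   population; must be shallower than the shallowest population split.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 2000L,
                              n_segments = 3L,
                              sirna_fraction_21 = 0.6,
                              pirna_length_weights = c(
                                "24" = 0.08, "25" = 0.12, "26" = 0.16,
                                "27" = 0.18, "28" = 0.16, "29" = 0.13,
                                "30" = 0.10, "31" = 0.07),
                              u1_prob = 0.8,
                              a10_prob = 0.8,
                              strand_balance = 0.5,
                              eve_divergence = 0.22,
                              eve_duplication = c(100L, 400L),
                              conserved_motifs = list(c(600L, 31L),
                                                      c(1000L, 35L),
                                                      c(1500L, 39L)),
                              n_populations = 6L,
                              clock_rate = 0.0354,
                              split_times = NULL,
                              reads_per_contig = 10000L,
                              coi_length = 658L,
                              virus_locus_length = 2000L,
                              virus_rate_scale = 1.5,
                              haplotypes_per_population = 2L,
                              within_pop_time = 0.02) {
  if (is.null(split_times)) {
    split_times <- default_split_times(n_populations)
  }
  cfg <- structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         n_segments = as.integer(n_segments),
         sirna_fraction_21 = sirna_fraction_21,
         pirna_length_weights = pirna_length_weights,
         u1_prob = u1_prob, a10_prob = a10_prob,
         strand_balance = strand_balance,
         eve_divergence = eve_divergence,
         eve_duplication = if (is.null(eve_duplication)) NULL else as.integer(eve_duplication),
         conserved_motifs = conserved_motifs,
         n_populations = as.integer(n_populations),
         clock_rate = clock_rate, split_times = split_times,
         reads_per_contig = as.integer(reads_per_contig),
         coi_length = as.integer(coi_length),
         virus_locus_length = as.integer(virus_locus_length),
         virus_rate_scale = virus_rate_scale,
         haplotypes_per_population = as.integer(haplotypes_per_population),
         within_pop_time = within_pop_time),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' Default population split-time matrix
#'
#' For six populations, a named matrix loosely modelled on isolated
#' Nearctic regions (Alaska, Rocky Mountains, Pacific Northwest, Utah,
#' Midwest, East): Alaska groups with the Rockies rather than the nearer
#' Pacific Northwest, Utah is deeply divergent from the Midwest/East, and
#' the deepest (trans-continental) split is 0.407 My so that the most
#' divergent pair accumulates ~2 x 0.0354 x 0.407 = 2.88% divergence under
#' the default clock. For other population counts, a uniform ladder with
#' the same maximum depth.
#'
#' @param n number of populations.
#' @return symmetric matrix of split times in My.
#' @export
default_split_times <- function(n) {
  if (n == 6L) {
    pops <- c("AK", "RM", "PNW", "UT", "MW", "EA")
    m <- matrix(0.407, 6L, 6L, dimnames = list(pops, pops))
    m["AK", "RM"] <- m["RM", "AK"] <- 0.12
    m["AK", "PNW"] <- m["PNW", "AK"] <- 0.25
    m["RM", "PNW"] <- m["PNW", "RM"] <- 0.25
    m["MW", "EA"] <- m["EA", "MW"] <- 0.10
    m["UT", "MW"] <- m["MW", "UT"] <- 0.30
    m["UT", "EA"] <- m["EA", "UT"] <- 0.30
    diag(m) <- 0
    return(m)
  }
  pops <- paste0("pop", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) m[i, j] <- 0.407 * (max(i, j) - 1L) / (n - 1L)
    }
  }
  m
}

validate_simulation_config <- function(cfg) {
  stopifnot(is.list(cfg))
  probs <- c(sirna_fraction_21 = cfg$sirna_fraction_21, u1_prob = cfg$u1_prob,
             a10_prob = cfg$a10_prob, strand_balance = cfg$strand_balance)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities outside [0,1]: ", paste(names(probs)[bad], collapse = ", "))
  }
  w <- cfg$pirna_length_weights
  if (!identical(names(w), as.character(24:31))) {
    stop("pirna_length_weights must be named '24'..'31'")
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("pirna_length_weights must be nonnegative and sum to 1 (tol 1e-9)")
  }
  if (cfg$eve_divergence < 0 || cfg$eve_divergence > 0.75) {
    stop("eve_divergence must lie in [0, 0.75]")
  }
  G <- cfg$genome_length
  dup <- cfg$eve_duplication
  if (!is.null(dup)) {
    if (length(dup) != 2L || dup[1] < 0 || dup[2] <= dup[1] || dup[2] > G) {
      stop("eve_duplication must be a valid 0-based half-open interval within the segment")
    }
  }
  for (m in cfg$conserved_motifs) {
    if (length(m) != 2L || m[1] < 0 || m[2] < 1 || m[1] + m[2] > G) {
      stop("conserved motif (start=", m[1], ", len=", m[2], ") outside contig bounds")
    }
    if (!is.null(dup) && m[1] < dup[2] && m[1] + m[2] > dup[1]) {
      stop("conserved motif overlaps the duplication interval")
    }
  }
  if (cfg$n_populations < 2L) stop("n_populations must be >= 2")
  st <- cfg$split_times
  if (!is.matrix(st) || nrow(st) != cfg$n_populations ||
      !isTRUE(all.equal(st, t(st))) || any(diag(st) != 0) || any(st < 0)) {
    stop("split_times must be a symmetric nonnegative matrix with zero diagonal, ",
         "one row per population")
  }
  # ultrametric (three-point) consistency, required for a valid population tree
  n <- nrow(st)
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      for (j in seq(i + 1L, n - 1L)) {
        for (k in seq(j + 1L, n)) {
          d <- sort(c(st[i, j], st[i, k], st[j, k]))
          if (d[2] < d[3] - 1e-9) {
            stop("split_times are not ultrametric-consistent (taxa ",
                 i, ",", j, ",", k, ")")
          }
        }
      }
    }
  }
  if (cfg$clock_rate <= 0) stop("clock_rate must be positive")
  if (cfg$reads_per_contig < 1L) stop("reads_per_contig must be >= 1")
  if (cfg$haplotypes_per_population < 1L) {
    stop("haplotypes_per_population must be >= 1")
  }
  if (cfg$haplotypes_per_population > 1L) {
    pos <- st[st > 0]
    if (cfg$within_pop_time < 0 ||
        (length(pos) && cfg$within_pop_time >= min(pos))) {
      stop("within_pop_time must be nonnegative and shallower than the ",
           "shallowest population split")
    }
  }
  invisible(cfg)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of character DNA sequences
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate viral genome segments
#'
#' Generates `n_segments` uniform-random nucleotide contigs of
#' `genome_length` nt each, with deterministic identifiers
#' `segment_1 ... segment_n`. Identical seed + config give byte-identical
#' output.
#'
#' @param config a [simulation_config()].
#' @return a named [Biostrings::DNAStringSet] of reference contigs.
#' @export
simulate_virus_genome <- function(config) {
  validate_simulation_config(config)
  if (config$genome_length < 200L) {
    stop("genome_length must be >= 200 (got ", config$genome_length, ")")
  }
  withr::with_seed(config$seed + 101L, {
    seqs <- vapply(seq_len(config$n_segments),
                   function(i) random_dna(config$genome_length), character(1))
  })
  names(seqs) <- paste0("segment_", seq_len(config$n_segments))
  Biostrings::DNAStringSet(seqs)
}

#' Simulate an endogenous viral element (EVE) from a virus segment
#'
#' Copies the virus segment, substitutes each site outside the conserved
#' motifs with probability `eve_divergence` (uniformly to one of the three
#' other bases; no indels), then inserts the duplication interval's
#' (already mutated) sequence in tandem immediately after itself. Ground
#' truth coordinates of the motifs and both duplication copies are
#' returned in virus and EVE coordinates (0-based half-open).
#'
#' @param virus_contig a single sequence (character or
#'   [Biostrings::DNAStringSet]/`DNAString`).
#' @param config a [simulation_config()]; uses `eve_divergence`,
#'   `eve_duplication`, `conserved_motifs`, `seed`.
#' @return list with elements `eve` (DNAStringSet of 1), `motifs_virus`
#'   and `motifs_eve` (data.frames of `start`, `end`), `duplication_virus`,
#'   `duplication_eve` (0-based half-open intervals or NULL), and
#'   `n_substitutions`.
#' @export
simulate_eve <- function(virus_contig, config) {
  validate_simulation_config(config)
  seqchr <- as.character(virus_contig)
  if (length(seqchr) != 1L) stop("virus_contig must be a single sequence")
  bases <- strsplit(seqchr, "")[[1]]
  L <- length(bases)

  motifs <- do.call(rbind, lapply(config$conserved_motifs, function(m) {
    data.frame(start = m[1], end = m[1] + m[2])
  }))
  if (is.null(motifs)) motifs <- data.frame(start = integer(0), end = integer(0))
  dup <- config$eve_duplication
  if (any(motifs$end > L) || (!is.null(dup) && dup[2] > L)) {
    stop("motif or duplication interval outside contig bounds (length ", L, ")")
  }

  protected <- logical(L)
  for (i in seq_len(nrow(motifs))) {
    protected[(motifs$start[i] + 1L):motifs$end[i]] <- TRUE
  }

  withr::with_seed(config$seed + 202L, {
    hit <- which(!protected & runif(L) < config$eve_divergence)
    if (length(hit)) {
      bases[hit] <- vapply(bases[hit],
                           function(b) sample(setdiff(DNA_BASES, b), 1L),
                           character(1))
    }
  })

  motifs_eve <- motifs
  dup_eve <- NULL
  if (!is.null(dup)) {
    dlen <- dup[2] - dup[1]
    bases <- c(bases[seq_len(dup[2])],
               bases[(dup[1] + 1L):dup[2]],
               if (dup[2] < L) bases[(dup[2] + 1L):L] else character(0))
    # tandem second copy occupies [end, end + dlen) in EVE coordinates
    dup_eve <- c(dup[2], dup[2] + dlen)
    shift <- ifelse(motifs$start >= dup[2], dlen, 0L)
    motifs_eve$start <- motifs$start + shift
    motifs_eve$end <- motifs$end + shift
  }

  eve <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(eve) <- paste0(if (!is.null(names(virus_contig))) names(virus_contig)[1] else "segment",
                       "_EVE")
  list(eve = eve,
       motifs_virus = motifs, motifs_eve = motifs_eve,
       duplication_virus = dup, duplication_eve = dup_eve,
       n_substitutions = length(hit))
}

#' Simulate a small-RNA library with siRNA/piRNA structure
#'
#' For each reference contig, draws `reads_per_contig` reads. With
#' probability `sirna_fraction_21` a read is siRNA-class: an exact 21-mer
#' from a uniform position on a uniformly chosen strand. Otherwise it is
#' piRNA-class: length drawn from `pirna_length_weights` (24-31 nt);
#' antisense reads have their 5' base drawn U with probability `u1_prob`
#' (else uniform A/C/G), sense reads their position-10 base drawn A with
#' probability `a10_prob` (else uniform C/G/T), so the realised positional
#' frequencies equal the configured probabilities. No sequencing error or
#' quality model: reads are exact substrings apart from the bias bases.
#'
#' @param contigs named character vector or [Biostrings::DNAStringSet].
#' @param config a [simulation_config()].
#' @return list with `reads` (named DNAStringSet) and `truth`
#'   (data.frame: read_id, contig_id, strand, class, start, length), one
#'   truth row per read.
#' @export
simulate_small_rna_library <- function(contigs, config) {
  validate_simulation_config(config)
  contigs <- as_named_character(contigs)
  if (length(contigs) == 0L) stop("empty contig set")
  if (is.null(names(contigs))) names(contigs) <- paste0("contig_", seq_along(contigs))

  pirna_lens <- as.integer(names(config$pirna_length_weights))
  withr::with_seed(config$seed + 303L, {
    per_contig <- lapply(names(contigs), function(cid) {
      cs <- contigs[[cid]]
      L <- nchar(cs)
      n <- config$reads_per_contig
      is_sirna <- runif(n) < config$sirna_fraction_21
      antisense <- runif(n) < config$strand_balance
      len <- ifelse(is_sirna, 21L,
                    sample(pirna_lens, n, replace = TRUE,
                           prob = config$pirna_length_weights))
      if (any(len > L)) stop("contig ", cid, " shorter than a read length")
      start <- vapply(len, function(l) sample.int(L - l + 1L, 1L) - 1L, integer(1))
      seqs <- substring(cs, start + 1L, start + len)
      seqs[antisense] <- revcomp(seqs[antisense])
      # positional bias bases for piRNA-class reads
      pa <- which(!is_sirna & antisense)
      if (length(pa)) {
        u <- ifelse(runif(length(pa)) < config$u1_prob, "T",
                    sample(c("A", "C", "G"), length(pa), replace = TRUE))
        substring(seqs[pa], 1L, 1L) <- u
      }
      ps <- which(!is_sirna & !antisense)
      if (length(ps)) {
        a <- ifelse(runif(length(ps)) < config$a10_prob, "A",
                    sample(c("C", "G", "T"), length(ps), replace = TRUE))
        substring(seqs[ps], 10L, 10L) <- a
      }
      data.frame(read_id = sprintf("%s_r%06d", cid, seq_len(n)),
                 contig_id = cid,
                 strand = ifelse(antisense, "antisense", "sense"),
                 class = ifelse(is_sirna, "siRNA", "piRNA"),
                 start = start, length = len, seq = seqs,
                 stringsAsFactors = FALSE)
    })
  })
  truth <- do.call(rbind, per_contig)
  reads <- Biostrings::DNAStringSet(setNames(truth$seq, truth$read_id))
  truth$seq <- NULL
  list(reads = reads, truth = truth)
}

#' Write reads as FASTQ with constant high quality
#'
#' The pipeline analyses pre-trimmed inserts only, so qualities carry no
#' information and are written as a constant 'I' (Q40).
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param path output FASTQ path.
#' @export
write_reads_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}

build_population_tree <- function(split_times, haplotypes = 1L,
                                  within_pop_time = 0) {
  # hclust heights equal the supplied distances; as.phylo halves node
  # heights, so feed 2 x split time to get root-to-tip depths in My.
  if (haplotypes > 1L) {
    pops <- rownames(split_times)
    taxa <- as.vector(t(outer(pops, seq_len(haplotypes), paste, sep = ".")))
    taxon_pop <- rep(pops, each = haplotypes)
    m <- matrix(0, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
    for (i in seq_along(taxa)) {
      for (j in seq_along(taxa)) {
        if (i == j) next
        m[i, j] <- if (taxon_pop[i] == taxon_pop[j]) within_pop_time
                   else split_times[taxon_pop[i], taxon_pop[j]]
      }
    }
    split_times <- m
  }
  hc <- hclust(as.dist(2 * split_times), method = "average")
  ape::as.phylo(hc)
}

evolve_along_tree <- function(tree, root_seq, rate) {
  # independent-site substitution: along a branch of length l (My), each
  # site substitutes with probability rate*l, uniformly to another base
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  seqs <- vector("list", n_node)
  root <- n_tip + 1L
  seqs[[root]] <- root_seq
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]
    child <- ord$edge[e, 2L]
    p_sub <- rate * ord$edge.length[e]
    if (p_sub > 1) stop("substitution probability exceeds 1 on a branch")
    s <- seqs[[parent]]
    hit <- which(runif(length(s)) < p_sub)
    if (length(hit)) {
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1))
    }
    seqs[[child]] <- s
  }
  tips <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                 character(1))
  setNames(tips, tree$tip.label)
}

#' Simulate codiverging host and virus loci along one population tree
#'
#' Builds the ultrametric population tree implied by `split_times`,
#' evolves a host COI-like locus and a virus locus along the *same* tree
#' by independent-site substitution (host rate `clock_rate` per lineage,
#' virus rate `clock_rate * virus_rate_scale`), and returns both
#' alignments plus the true tree. Expected pairwise host divergence
#' between populations split `T` My ago is `2 * clock_rate * T` (up to
#' multiple-hit saturation, negligible at the default depths).
#'
#' @param config a [simulation_config()].
#' @return list with `host_alignment` and `virus_alignment` (named
#'   [Biostrings::DNAStringSet], one sequence per sampled haplotype,
#'   named `<pop>.<k>` when `haplotypes_per_population > 1`), `tree`
#'   (an [ape::phylo] with branch lengths in My), and `populations`.
#' @export
simulate_codiverging_loci <- function(config) {
  validate_simulation_config(config)
  tree <- build_population_tree(config$split_times,
                                config$haplotypes_per_population,
                                config$within_pop_time)
  withr::with_seed(config$seed + 404L, {
    host_root <- sample(DNA_BASES, config$coi_length, replace = TRUE)
    host <- evolve_along_tree(tree, host_root, config$clock_rate)
    virus_root <- sample(DNA_BASES, config$virus_locus_length, replace = TRUE)
    virus <- evolve_along_tree(tree, virus_root,
                               config$clock_rate * config$virus_rate_scale)
  })
  list(host_alignment = Biostrings::DNAStringSet(host),
       virus_alignment = Biostrings::DNAStringSet(virus),
       tree = tree,
       populations = rownames(config$split_times))
}
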