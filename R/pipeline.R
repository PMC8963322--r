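#' Pipeline configuration
#'
#' Assembles input paths and per-stage thresholds into a validated
#' configuration for [run_pipeline()]. Unknown keys are rejected so typos
#' cannot silently revert a threshold to its default. The configuration
#' is echoed verbatim (JSON) into the output directory for provenance.
#'
#' @param reads path to a FASTA/FASTQ read file.
#' @param contigs path to a reference contig FASTA.
#' @param out_dir output directory.
#' @param eve_fasta optional path to an EVE reference FASTA (enables the
#'   EVE disambiguation stage; the first contig in `contigs` is taken as
#'   the exogenous counterpart unless `virus_contig` names one).
#' @param virus_contig optional contig id paired with the EVE.
#' @param eve_exclude optional 0-based half-open `(start, end)` interval
#'   excluded from the EVE/virus identity computation (e.g. a known
#'   duplication), in EVE coordinates.
#' @param host_fasta,virus_locus_fasta optional aligned FASTA paths for
#'   the codivergence stage.
#' @param screening_table optional TSV path for the prevalence stage.
#' @param clock_divergence,clock_rate optional clock inputs (proportions).
#' @param min_match_fraction mapping threshold.
#' @param min_reads,min_norm21,peak_ratio siRNA-enrichment call policy.
#' @param pirna_min_len,pirna_max_len piRNA candidate size window.
#' @param alpha significance level for bias calls (Bonferroni over
#'   contigs is applied inside the pipeline).
#' @param mask_min_read_len minimum window length entering the ambiguity
#'   mask.
#' @param permutations Mantel permutations for the congruence stage.
#' @param seed seed for the congruence permutation null.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, contigs, out_dir,
                            eve_fasta = NULL, virus_contig = NULL,
                            eve_exclude = NULL,
                            host_fasta = NULL, virus_locus_fasta = NULL,
                            screening_table = NULL,
                            clock_divergence = NULL, clock_rate = NULL,
                            min_match_fraction = 0.95,
                            min_reads = 50L, min_norm21 = 20, peak_ratio = 2,
                            pirna_min_len = 24L, pirna_max_len = 31L,
                            alpha = 0.001, mask_min_read_len = 18L,
                            permutations = 9999, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

write_stage <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full small-RNA virome pipeline
#'
#' Executes map -> profile -> piRNA bias -> EVE disambiguation (if an EVE
#' reference is supplied) -> congruence/clock/prevalence (if their inputs
#' are supplied), writing per-stage TSV outputs, a `MANIFEST` marking
#' stage completeness, a JSON echo of the configuration, and a summary
#' table with one row per contig (siRNA call, piRNA verdict) plus the
#' phylogeographic numbers. Refuses to reuse an existing output
#' directory unless `force = TRUE`.
#'
#' @param config a [pipeline_config()].
#' @param force overwrite an existing output directory.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(config$out_dir)) {
    if (!force) stop("output directory exists (use force = TRUE): ",
                     config$out_dir)
  } else {
    dir.create(config$out_dir, recursive = TRUE)
  }
  for (p in c(config$reads, config$contigs, config$eve_fasta,
              config$host_fasta, config$virus_locus_fasta,
              config$screening_table)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  echo <- config
  class(echo) <- NULL
  jsonlite::write_json(echo[!vapply(echo, is.null, logical(1))],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- character(0)
  note <- function(stage) manifest <<- c(manifest, stage)

  reads <- read_small_rna(config$reads)
  contigs <- Biostrings::readDNAStringSet(config$contigs)

  aln <- map_reads(reads, contigs,
                   min_match_fraction = config$min_match_fraction)
  write_stage(aln, config$out_dir, "alignments.tsv")
  cov <- stranded_coverage(aln, contigs)
  export_bedgraph(cov, file.path(config$out_dir, "coverage"))
  note("map")

  profiles <- size_profile(aln, contig_ids = names(contigs))
  calls <- lapply(profiles, call_sirna_enrichment,
                  min_reads = config$min_reads,
                  min_norm21 = config$min_norm21,
                  peak_ratio = config$peak_ratio)
  prof_tab <- profile_table(profiles)
  prof_tab$sirna_call <- vapply(calls[prof_tab$contig_id],
                                function(x) x$call, logical(1))
  write_stage(prof_tab, config$out_dir, "profiles.tsv")
  note("profile")

  cand <- filter_pirna_candidates(aln, config$pirna_min_len,
                                  config$pirna_max_len)
  alpha_adj <- config$alpha / max(1L, length(contigs))
  bias <- lapply(setNames(names(contigs), names(contigs)), function(cid) {
    sub <- cand[cand$contig_id == cid, , drop = FALSE]
    sq <- candidate_sequences(sub, reads)
    call_bias(sense = positional_frequencies(sq$sense),
              antisense = positional_frequencies(sq$antisense),
              alpha = alpha_adj)
  })
  bias_tab <- do.call(rbind, lapply(names(bias), function(cid) {
    b <- bias[[cid]]
    data.frame(contig_id = cid, u1_freq = b$u1_freq, a10_freq = b$a10_freq,
               u1_p = b$u1_p, a10_p = b$a10_p, verdict = b$verdict)
  }))
  write_stage(bias_tab, config$out_dir, "pirna_bias.tsv")
  note("pirna")

  eve_summary <- NULL
  if (!is.null(config$eve_fasta)) {
    eve_seq <- Biostrings::readDNAStringSet(config$eve_fasta)
    vid <- if (is.null(config$virus_contig)) names(contigs)[1] else config$virus_contig
    rep <- align_pair(contigs[[vid]], eve_seq[[1]],
                      exclude = config$eve_exclude)
    mask <- build_ambiguity_mask(rep, config$mask_min_read_len)
    asg <- assign_reads(reads, contigs[[vid]], eve_seq[[1]], mask = mask,
                        min_match_fraction = config$min_match_fraction)
    write_stage(asg$labels, config$out_dir, "eve_labels.tsv")
    write_stage(rep$windows, config$out_dir, "eve_windows.tsv")
    eve_summary <- list(identity_pct = rep$identity_pct,
                        n_windows = nrow(rep$windows),
                        label_counts = table(asg$labels$label))
    note("eve")
  }

  phylo_summary <- NULL
  if (!is.null(config$host_fasta) && !is.null(config$virus_locus_fasta)) {
    host <- Biostrings::readDNAStringSet(config$host_fasta)
    vloc <- Biostrings::readDNAStringSet(config$virus_locus_fasta)
    hd <- p_distance_matrix(host)
    vd <- p_distance_matrix(vloc)
    ht <- nj_tree(hd)
    vt <- nj_tree(vd)
    ape::write.tree(ht, file.path(config$out_dir, "host_nj.nwk"))
    ape::write.tree(vt, file.path(config$out_dir, "virus_nj.nwk"))
    cong <- withr::with_seed(config$seed,
      congruence(ht, vt, hd, vd, permutations = config$permutations))
    phylo_summary <- cong
    note("phylo")
  }

  clock <- NULL
  if (!is.null(config$clock_divergence) && !is.null(config$clock_rate)) {
    clock <- clock_date(config$clock_divergence, config$clock_rate)
    note("clock")
  }

  prev <- NULL
  if (!is.null(config$screening_table)) {
    prev <- prevalence(read_screening_table(config$screening_table))
    note("prevalence")
  }

  writeLines(manifest, file.path(config$out_dir, "MANIFEST"))
  summary <- list(profiles = prof_tab, bias = bias_tab, eve = eve_summary,
                  congruence = phylo_summary, clock = clock,
                  prevalence = prev)
  invisible(summary)
}
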