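---
title: "Methods: small-RNA profiling and phylogeographic dating of inherited insect viromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA profiling and phylogeographic dating of inherited insect viromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and rationale

`herivome` implements the computational core of a small-RNA approach to
inherited (vertically transmitted) RNA viruses in insects. Three kinds of
evidence are produced from trimmed 18–31 nt small-RNA reads and a set of
reference sequences:

1. **Active replication and host silencing.** An insect infected by a
   replicating RNA virus produces Dicer-2 siRNAs, a sharp population of
   21-nt fragments mapping to both genome strands. Their presence in
   reads from eggs or ovaries is the signature of an inherited infection.
2. **piRNA-pathway engagement.** PIWI-associated small RNAs are longer
   (24–31 nt) and carry positional biases: primary piRNAs a 5′ uridine
   (U1), secondary (ping-pong) partners an adenine at position 10 (A10),
   on opposite strands. Endogenous viral elements (EVEs) — virus-derived
   sequences integrated in the host genome — are a prolific piRNA source,
   so reads must be disambiguated between an EVE and its exogenous
   relative before either signal is interpreted.
3. **Timescale of persistence.** Where host populations are isolated,
   host and virus loci codiverge; uncorrected COI divergence and an
   insect mitochondrial clock date the association.

Every stage is driven by plain data structures (data frames, named
sequence sets) so each number in a summary can be traced to a stage
output. The numbered scripts under `analysis/` run the stages in order
on simulated data; the same functions serve real inputs.

# The simulator

`simulation_config()` fixes the study conditions. Defaults, with the
reasoning behind each:

| parameter | default | why |
|---|---|---|
| `n_segments`, `genome_length` | 3 × 2000 nt | a trisegmented bunyavirus-like genome; 2 kb is the order of an S/M segment and keeps desk runs fast |
| `sirna_fraction_21` | 0.6 | siRNA-dominated response typical of an actively silenced virus; the remainder is the piRNA-sized class |
| `pirna_length_weights` | peak at 27 nt over 24–31 | unimodal piRNA length profile centred where insect piRNAs concentrate (25–30 nt) |
| `u1_prob`, `a10_prob` | 0.8 | strong but imperfect biases, as observed in real ping-pong signatures |
| `strand_balance` | 0.5 | the true strand ratio of viral siRNAs is not established; symmetric is the neutral choice |
| `eve_divergence` | 0.22 | nucleotide divergence at which an EVE and its exogenous relative can still cross-map short reads in conserved stretches |
| `eve_duplication` | (100, 400) | a 300-nt tandem duplication of part of the nucleoprotein-like gene, excluded from identity computations as an annotated interval |
| `conserved_motifs` | 31, 35, 39 nt | three short perfectly conserved motifs, the length class that defeats read-level disambiguation |
| `n_populations` | 6 | isolated Nearctic-style regions (AK, RM, PNW, UT, MW, EA) |
| `clock_rate` | 0.0354 / My (per lineage) | see "clock-rate conventions" below |
| `split_times` | deepest split 0.407 My | places the most divergent population pair at ~2.88% expected COI divergence under the default clock |
| `haplotypes_per_population` | 2 (depth 0.02 My) | screens sequence several individuals per region; two haplotypes per population give the congruence test realistic resolution |
| `coi_length` | 658 nt | the standard COI barcode fragment |
| `reads_per_contig` | 10,000 | a modest per-virus small-RNA yield |

Sequence evolution is independent-site substitution with equal exchange
among the three alternative bases (Jukes–Cantor-like), because all
downstream quantities are *uncorrected* identities and p-distances; no
indels, rate heterogeneity, or codon structure are simulated. Reads are
exact substrings with constant FASTQ qualities — the pipeline consumes
pre-trimmed inserts, so base-call noise is outside scope. U is stored as
T throughout; the piRNA module's frequency matrices relabel the row.

Two generator conventions matter for interpretation:

* **Bias bases are drawn, not overprinted.** The 5′ base of an antisense
  piRNA-class read is drawn U with probability `u1_prob` and otherwise
  uniformly from A/C/G, so the realised U1 frequency *equals* `u1_prob`
  (an overprint on a uniform base would give `u1 + (1-u1)/4`). The same
  scheme gives sense A10. `u1_prob = 1` still forces U always.
* **Ping-pong is modelled marginally.** Only the positional biases are
  generated, not explicit 10-nt 5′-overlap read pairs; the evidence the
  pipeline evaluates is the positional frequency matrix, not an overlap
  z-score.

What the generator deliberately does not emulate: read-count
overdispersion and hotspots, RNA secondary structure, host background
reads, sequencing error. A green test suite therefore demonstrates that
the *estimators* are correct and calibrated under clean sampling noise;
on real libraries, hotspot-driven coverage and contamination can only
degrade, not bias, the binomial quantities (norm21, U1/A10 frequencies),
but the enrichment-call thresholds below may need adjusting.

# Mapping

`map_reads()` is a strand-aware, gapless, substitutions-only aligner
with a minimum match-fraction threshold ("minratio" semantics): a
placement is reported when `matches / read_length ≥ t`, with `t = 0.95`
by default and 0.75 as the relaxed setting for mapping reads across
diverged strains. At 18–31 nt, indels are rare enough that gapless
verification is the appropriate model, and it keeps the match-fraction
definition exact.

Every offset on both strands is verified in C++ with early-exit mismatch
counting. We chose exhaustive verification over seed-and-extend
deliberately: at minratio 0.75 an 18-nt read may carry 4 mismatches,
and by pigeonhole its longest exact run can be as short as 3 nt, so any
fixed practical seed length loses sensitivity exactly where the relaxed
threshold is used. At these reference sizes (kilobases, not gigabases)
the exhaustive scan is fast and its output provably equals exhaustive
search — which the tests confirm against an independent
`Biostrings::neditStartingAt()` oracle on 50 seeded instances at
thresholds 0.75 / 0.95 / 1.0.

Conventions: 0-based half-open coordinates; `N` never counts as a match
(in read or reference); reads outside 15–40 nt or with non-ACGTN symbols
are rejected by name. Default output is the single best placement per
read, with ties broken by match fraction, then contig id
(lexicographic), start, and sense before antisense — deterministic
output was preferred over random tie-breaking so that reruns are
byte-identical. `all_placements = TRUE` reports every passing placement
and is what the EVE stage uses. `stranded_coverage()` accumulates
per-base depth per strand (total depth always equals total aligned
read length) and exports bedGraph tracks per strand.

# Size profiles and the siRNA call

`size_profile()` tabulates mapped read lengths 18–31 nt per contig
(outside lengths go to an overflow bin) and computes `norm21`, the
percent of 18–31 nt reads that are exactly 21 nt. The denominator is
per-contig, matching per-virus panels; a sample-wide denominator is a
one-line change at the call site if cross-virus comparability is wanted.

The literature rarely states a numeric criterion for "siRNA enriched",
so `call_sirna_enrichment()` makes the policy explicit and auditable.
All three must hold:

* `total_18_31 ≥ 50` — prevents calling on a handful of reads (the
  "extremely rare siRNAs" situation must return FALSE, not a weak TRUE);
* `counts[21] ≥ 2 × max(counts[20], counts[22])` — a genuine peak, not a
  shoulder of a broad distribution;
* `norm21 ≥ 20%` — the peak must carry a meaningful share of the
  small-RNA mass.

Each call records the three comparisons, so a reviewer can see which
gate failed. On simulated libraries the call is TRUE for 100/100
siRNA-dominated replicates and FALSE for 100/100 piRNA-only replicates
at these defaults (500 reads per replicate).

# piRNA analysis

`filter_pirna_candidates()` keeps 24–31 nt alignments.
`positional_frequencies()` tabulates A/C/G/U at positions 1–24 from each
read's 5′ end; reads shorter than 24 nt contribute up to their own
length, so every column is normalised over the reads that reach it (the
alternative — dropping short reads entirely — discards a third of the
candidate mass at typical length profiles). Strand is the *mapping*
strand: references are supplied in genome orientation, so for a
negative-sense virus "sense" reads correspond to genome-strand RNAs.

`call_bias()` runs one-sided exact binomial tests of antisense U1 and
sense A10 frequencies against a background of 0.25 at `alpha = 0.001`.
Uniform background is the minimal null for raw frequency plots; pass a
contig-composition background when base content is skewed. When several
contigs are tested the pipeline Bonferroni-divides alpha by the contig
count — with a handful of contigs and the strong biases of interest,
power is not a concern, and the strict alpha keeps the null libraries
quiet (≥ 99% verdict `none` across replicates). Verdicts: `ping_pong`
(both significant), `u1_only`, `a10_only`, `none`.

# EVE read disambiguation

`align_pair()` global-aligns EVE against virus (match +1, mismatch −1,
gap open 5, gap extend 1 — standard nucleotide weights; global, not
local, because the comparison is between a full coding region and its
integrated copy). Identity is `matches / compared columns`, where
compared columns have a base in both rows and are not excluded. A known
duplication is supplied as an *annotated excluded interval* rather than
auto-detected — breakpoint detection is a different problem, and ground
truth (from the simulator or from annotation of real data) is available
wherever this pipeline applies. The report lists every maximal run of
identical columns ("identity windows") with coordinates in both
sequences.

`build_ambiguity_mask()` unions the windows at least `min_read_len`
(default 18, the shortest read considered) long: inside such a window a
read cannot be attributed to either sequence. `assign_reads()` maps the
library against both references in all-placements mode and labels each
read `virus`, `eve`, `ambiguous` (maps to both, or lies wholly inside a
mask interval), or `unmapped`. Dual mappability at the active threshold
is authoritative; the mask is the precomputed fast path to the same
judgement. Accuracy is evaluated over reads given a definite label —
`ambiguous` is the designed conservative outcome for reads from
conserved stretches, mirroring the practice of excluding such reads from
per-source analyses. On simulated pairs at 22% divergence, definite
labels are ≥ 99% correct and every read wholly inside a planted motif is
ambiguous.

A census of the windows in a 22%-diverged pair shows why the mask is
short: windows ≥ 24 nt are a < 5% minority (essentially only the planted
motifs), while 15–17 nt near-matches are numerous — long enough to seed
PIWI target recognition, too short to trap an 18-nt read.

# Phylogeography

`p_distance_matrix()` computes uncorrected pairwise mismatch proportions
over columns where both sequences have an unambiguous base (gaps/N
excluded pairwise; a pair with no comparable columns is flagged NA).
Uncorrected distances are used because percent-per-My clock rates are
quoted on the raw scale; at the ~3% divergences involved, multiple-hit
corrections are smaller than sampling noise. The implementation is
cross-checked in the tests against `ape::dist.dna(model = "raw")`.

`nj_tree()` wraps `ape::nj()`: deterministic, exact on additive
matrices (verified by round-tripping random trees through their
path-length matrices), and entirely adequate for the desk-scale
congruence question; likelihood inference is out of scope.
`congruence()` reports Robinson–Foulds distance on unrooted topologies
(normalised by `2(n−3)`) plus a Mantel-type Pearson correlation of the
two distance matrices with a taxa-permutation null (`vegan::mantel`,
9999 permutations by default; with 12 taxa the null has ample support).
Rooting is for display only and never affects RF.

Two haplotypes per population matter here: with one haplotype per
population (6 taxa) the permutation null is fully enumerable (720
permutations) and ultrametric cherries make taxa exchangeable, so even
perfect cospeciation cannot push p much below ~0.005 and occasionally
lands above 0.01. Sampling two haplotypes per region — as a real screen
does — removes that granularity floor. At the 658-nt COI default the
host NJ tree can misresolve a shallow node (the analysis run shows
RF = 2 with Mantel p = 1e−4); the acceptance computation uses a 10-kb
host locus, where topology recovery is exact, to separate estimator
correctness from barcode-length noise.

`clock_date(divergence, rate)` converts pairwise divergence and a
pairwise clock rate into `tmrca_years = divergence / rate × 1e6`,
reported raw and rounded to the nearest 100,000 years:
`clock_date(0.0288, 0.0354)` gives 813,559 → 800,000 years, the
Mid-Pleistocene. **Clock-rate conventions:** `clock_date()` treats the
rate as *pairwise* divergence per My (the convention in which insect
COI clocks near 3.5%/My are quoted), while the simulator's `clock_rate`
is *per lineage* (expected pairwise divergence `2 × rate × T`). The two
conventions differ by a factor of two and are documented at both sites;
conflating them is the classic way to halve or double a TMRCA.

`prevalence()` is screening-table arithmetic: overall and per-population
percent positive (one decimal) with exact Clopper–Pearson 95% intervals.
The bundled table under `inst/extdata/` is synthetic (and so labelled):
353 screened across six populations, 39 positive, per-population
frequencies 3.2–51.7%.

# Numerical and degenerate-input choices

* Match-fraction thresholds compare `matches ≥ ceiling(t·L − 1e−9)` to
  avoid floating-point edge cases at exact multiples.
* Zero-read profiles are flagged `no_data` with `norm21 = NA`; empty
  candidate sets give an explicit no-data frequency object, not an
  error; a degenerate (all-gap) alignment is flagged.
* Generator sub-streams are seeded as `seed + fixed offset` per
  operation, so each output is a pure function of (config, seed) and
  regenerating one input does not shift another's stream.
* `simulation_config()` validates: probabilities in [0,1], piRNA length
  weights summing to 1 (1e−9), `eve_divergence ∈ [0, 0.75]`, motifs
  inside bounds and disjoint from the duplication, split-time matrices
  symmetric, zero-diagonal, and three-point (ultrametric) consistent.

# Problem sizes

The default test suite and the acceptance script are sized for a
single-CPU desk run (the full suite takes ~2 minutes): 2-kb segments,
10,000-read libraries for calibration checks, 500-read libraries × 100
replicates for call power/specificity, 50 mapper-oracle instances of
0.6–1.5 kb × 100–250 reads at three thresholds, and 10–20 codivergence
replicates (10-kb host locus, 2-kb virus locus, 12 taxa, 999
permutations).

# Known limitations

* Gapless mapping cannot place reads across indel polymorphisms between
  strains; at 18–31 nt this loses only reads overlapping the indel.
* The EVE stage handles one EVE/virus pair per call; paralogous EVE
  families would need pairwise masks between all members.
* The siRNA call thresholds are policy, not biology; they are explicit
  parameters precisely so that a different tissue or library chemistry
  can recalibrate them.
* p-distances and NJ assume the loci are recombination-free; the
  pipeline does not test for reassortment or recombination breakpoints.
* The Mantel permutation p-value tests association of distance matrices,
  not cospeciation per se; topological congruence (RF) and the clock
  date carry the historical interpretation.
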