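#' Configuration for the synthetic splicing dataset
#'
#' Defines the study conditions emulated by the generator: a toy genome of
#' multi-exon genes whose introns carry donor sites of graded strength, CLIP
#' cross-links concentrated a fixed distance upstream of donors, spliced and
#' unspliced molecules in class-dependent proportions, rRNA/snRNA contaminant
#' reads, and a knockout condition in which unspliced (retained) signal of
#' weak-donor introns is up-regulated and cryptic donors inside those introns
#' become used.
#'
#' Donor strength classes are realized as controlled mismatches to the donor
#' consensus `CAGGTAAGT` at fixed positions (GT at the first two intronic
#' bases is never touched): `strong` is the consensus, `medium` carries one
#' exonic mismatch, `weak` two intronic mismatches. This gives a monotone
#' ground-truth strength axis that a trained position weight matrix separates
#' perfectly.
#'
#' @param seed Integer seed; a fixed seed makes every generated file
#'   byte-identical across runs.
#' @param n_genes Number of genes (default 30).
#' @param exons_per_gene Integer range (length 2) of exons per gene.
#' @param exon_length Integer range of exon lengths (nt).
#' @param intron_length_short,intron_length_long Ranges (nt) for the two
#'   components of the intron-length mixture (below and above 1 kb).
#' @param p_long_intron Probability an intron is drawn from the long component.
#' @param class_probs Named numeric, sampling probabilities of the donor
#'   strength classes `strong`, `medium`, `weak`; must sum to 1.
#' @param spliced_fraction Named list, one numeric vector per condition giving
#'   the per-class probability that a donor-overlapping CLIP read derives from
#'   a spliced molecule. Values in \[0, 1\].
#' @param crosslink_offset Numeric `c(mean, sd)`: cross-link positions are
#'   drawn at `Normal(-mean, sd)` nt relative to the donor (offset 0 = first
#'   intronic base; negative = exonic/upstream). The default mean of 30 nt
#'   upstream reproduces the observed CLIP signal geometry at 5' splice sites.
#' @param read_length Integer range of read lengths (nt), spanning typical
#'   short-insert CLIP libraries.
#' @param n_reads_per_library Reads emitted per library.
#' @param contaminant_fractions Named numeric over
#'   `c("rRNA","U1","U2","U4","U5","U6")`; must sum to < 1.
#' @param conditions Character vector of condition labels (first is the
#'   reference, e.g. wild type).
#' @param replicates_per_condition Number of replicates per condition.
#' @param planted_intron_log2fc Log2 fold change applied to the unspliced
#'   (intron-retained) molecule abundance of weak-class introns in the
#'   non-reference condition of the RNA-seq simulation.
#' @param planted_gene_log2fc Log2 fold change applied to the mature
#'   (exonic + junction) abundance of genes hosting a weak-class intron in
#'   the non-reference condition, emulating degradation of misspliced
#'   transcripts (slightly negative by default).
#' @param rnaseq_intron_scale Steady-state survival of unspliced molecules
#'   in the RNA-seq simulation: intron read abundance is
#'   `length * expr * (1 - spliced_fraction) * rnaseq_intron_scale`, keeping
#'   retained-intron signal a minor share of gene signal as in polyadenylated
#'   RNA-seq.
#' @param cryptic_inclusion Named numeric per condition: fraction of junction
#'   reads of a weak intron that use its planted cryptic donor.
#' @param proteins Labels of the CLIP'd proteins; each gets
#'   `replicates_per_condition` libraries.
#' @param clip_enrichment Fold enrichment of CLIP reads at bound donors over
#'   unbound ones.
#' @param clip_bound_other_fraction Fraction of non-weak introns bound by each
#'   protein (weak introns are always bound, so distinct proteins share their
#'   weak-donor targets).
#' @param clip_multimap_fraction Fraction of CLIP gene reads flagged as
#'   multi-mapping (excluded by uniqueness filters downstream).
#' @param expressed_fraction Fraction of genes with nonzero expression.
#' @param junction_weight Sampling weight (effective nt) of each splice
#'   junction in the RNA-seq simulation, controlling junction-read depth.
#'
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_genes = 30L,
    exons_per_gene = c(2L, 4L),
    exon_length = c(100L, 200L),
    intron_length_short = c(300L, 900L),
    intron_length_long = c(1200L, 2500L),
    p_long_intron = 0.5,
    class_probs = c(strong = 1 / 3, medium = 1 / 3, weak = 1 / 3),
    spliced_fraction = list(
      WT = c(strong = 0.95, medium = 0.80, weak = 0.50),
      KO = c(strong = 0.95, medium = 0.80, weak = 0.50)
    ),
    crosslink_offset = c(mean = 30, sd = 3),
    read_length = c(20L, 150L),
    n_reads_per_library = 20000L,
    contaminant_fractions = c(
      rRNA = 0.05, U1 = 0.04, U2 = 0.02, U4 = 0.01, U5 = 0.01, U6 = 0.01
    ),
    conditions = c("WT", "KO"),
    replicates_per_condition = 2L,
    planted_intron_log2fc = 1,
    planted_gene_log2fc = -0.5,
    rnaseq_intron_scale = 0.05,
    cryptic_inclusion = c(WT = 0, KO = 0.5),
    proteins = c("P1", "P2"),
    clip_enrichment = 20,
    clip_bound_other_fraction = 0.5,
    clip_multimap_fraction = 0.02,
    expressed_fraction = 1,
    junction_weight = 60) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length_short = as.integer(intron_length_short),
    intron_length_long = as.integer(intron_length_long),
    p_long_intron = p_long_intron, class_probs = class_probs,
    spliced_fraction = spliced_fraction,
    crosslink_offset = crosslink_offset,
    read_length = as.integer(read_length),
    n_reads_per_library = as.integer(n_reads_per_library),
    contaminant_fractions = contaminant_fractions,
    conditions = conditions,
    replicates_per_condition = as.integer(replicates_per_condition),
    planted_intron_log2fc = planted_intron_log2fc,
    planted_gene_log2fc = planted_gene_log2fc,
    rnaseq_intron_scale = rnaseq_intron_scale,
    cryptic_inclusion = cryptic_inclusion,
    proteins = proteins, clip_enrichment = clip_enrichment,
    clip_bound_other_fraction = clip_bound_other_fraction,
    clip_multimap_fraction = clip_multimap_fraction,
    expressed_fraction = expressed_fraction,
    junction_weight = junction_weight
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) abort("n_genes must be >= 1")
  if (sum(cfg$contaminant_fractions) >= 1) {
    abort("contaminant fractions must sum to < 1")
  }
  if (any(cfg$contaminant_fractions < 0)) {
    abort("contaminant fractions must be nonnegative")
  }
  sf <- unlist(cfg$spliced_fraction)
  if (any(sf < 0 | sf > 1)) abort("spliced fractions must be in [0, 1]")
  if (abs(sum(cfg$class_probs) - 1) > 1e-8) {
    abort("class_probs must sum to 1")
  }
  missing_cond <- setdiff(cfg$conditions, names(cfg$spliced_fraction))
  if (length(missing_cond) > 0) {
    abort(sprintf(
      "spliced_fraction missing condition(s): %s",
      paste(missing_cond, collapse = ", ")
    ))
  }
  if (cfg$read_length[1] < 10) abort("minimum read length must be >= 10")
  invisible(cfg)
}

# Motif constants. Anchors: donor motif spans transcript offsets -3..+5
# around the first intronic base (offset 0); acceptor motif spans -20..+2
# around the first exonic base after the intron; branch heptamer spans
# -30..-24 on the same anchor.
donor_consensus_seq <- function() "CAGGTAAGT"
acceptor_consensus_seq <- function() "TTTTTTTTTTTTTTTTTCAGGTT"
branch_consensus_seq <- function() "TACTAAC"

donor_class_seq <- function(label) {
  s <- strsplit(donor_consensus_seq(), "")[[1]]
  if (label == "medium") {
    s[1] <- "T" # exonic -3
  } else if (label == "weak") {
    s[8] <- "C" # intronic +4
    s[9] <- "C" # intronic +5
  } else if (label == "cryptic") {
    s[1] <- "A"
    s[9] <- "C"
  } else if (label != "strong") {
    abort(sprintf("unknown donor class '%s'", label))
  }
  paste(s, collapse = "")
}

contaminant_lengths <- function() {
  c(rRNA = 2000L, U1 = 164L, U2 = 191L, U4 = 145L, U5 = 116L, U6 = 106L)
}

ms_snrnas <- function() c("U1", "U2", "U4", "U5", "U6")
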