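# Gene/intron layout and genome synthesis.
#
# The layout (gene coordinates, intron classes, expression truth, cryptic
# donor placement) is derived deterministically from config$seed, so
# generate_genome() and generate_annotation() can be called independently and
# still agree. All internal coordinates are 0-based half-open; GTF/SAM output
# converts at the boundary.

simulate_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "layout"), {
    n <- config$n_genes
    gene_ids <- sprintf("g%03d", seq_len(n))
    strands <- rep(c("+", "-"), length.out = n)
    n_exons <- sample_range(
      config$exons_per_gene[1], config$exons_per_gene[2], n
    )
    expr <- exp(rnorm(n, 0, 0.5))
    silent <- runif(n) > config$expressed_fraction
    expr[silent] <- 0

    exons <- vector("list", n)
    introns <- vector("list", n)
    cursor <- 1500L
    for (i in seq_len(n)) {
      ne <- n_exons[i]
      elens <- sample_range(config$exon_length[1], config$exon_length[2], ne)
      ni <- ne - 1L
      if (ni > 0) {
        long <- runif(ni) < config$p_long_intron
        ilens <- integer(ni)
        ilens[long] <- sample_range(
          config$intron_length_long[1], config$intron_length_long[2],
          sum(long)
        )
        ilens[!long] <- sample_range(
          config$intron_length_short[1], config$intron_length_short[2],
          sum(!long)
        )
      } else {
        ilens <- integer(0)
      }
      starts <- cursor + c(0L, cumsum(elens + c(ilens, 0L))[-ne])
      ends <- starts + elens
      exons[[i]] <- tibble(
        gene_id = gene_ids[i], exon_rank = seq_len(ne),
        start = starts, end = ends
      )
      if (ni > 0) {
        introns[[i]] <- tibble(
          gene_id = gene_ids[i], intron_rank = seq_len(ni),
          start = ends[-ne], end = starts[-1]
        )
      }
      cursor <- ends[ne] + 2000L
    }
    exons <- bind_rows(exons)
    introns <- bind_rows(introns)
    if (nrow(introns) == 0) {
      introns <- tibble(
        gene_id = character(), intron_rank = integer(),
        start = integer(), end = integer()
      )
    }
    # strength classes allocated at the configured proportions with
    # deterministic balancing (largest-remainder), randomly placed: balanced
    # class sizes keep each mismatched position a clear minority, so PWM
    # scores order the classes strong > medium > weak by construction
    ni_all <- nrow(introns)
    if (ni_all > 0) {
      probs <- config$class_probs
      base_n <- floor(probs * ni_all)
      frac <- probs * ni_all - base_n
      rem <- ni_all - sum(base_n)
      if (rem > 0) {
        extra <- order(-frac)[seq_len(rem)]
        base_n[extra] <- base_n[extra] + 1
      }
      introns$class <- sample(rep(names(probs), times = base_n))
      coff <- sample_range(30L, 120L, ni_all)
      gene_strand <- strands[match(introns$gene_id, gene_ids)]
      weak <- introns$class == "weak"
      introns$cgap_start <- ifelse(weak,
        ifelse(gene_strand == "+", introns$start + coff, introns$start),
        NA_integer_
      )
      introns$cgap_end <- ifelse(weak,
        ifelse(gene_strand == "+", introns$end, introns$end - coff),
        NA_integer_
      )
    } else {
      introns$class <- character(0)
      introns$cgap_start <- integer(0)
      introns$cgap_end <- integer(0)
    }

    genes <- exons |>
      group_by(.data$gene_id) |>
      summarise(start = min(.data$start), end = max(.data$end)) |>
      mutate(
        chrom = "chrS",
        strand = strands[match(.data$gene_id, gene_ids)],
        expr = expr[match(.data$gene_id, gene_ids)]
      )
    exons <- exons |>
      mutate(
        chrom = "chrS",
        strand = genes$strand[match(.data$gene_id, genes$gene_id)],
        transcript_id = sub("^g", "tx", .data$gene_id)
      )
    introns <- introns |>
      mutate(
        chrom = rep("chrS", n()),
        strand = genes$strand[match(.data$gene_id, genes$gene_id)],
        intron_id = sprintf(
          "%s:%d-%d:%s", .data$chrom, .data$start, .data$end, .data$strand
        ),
        length = .data$end - .data$start,
        donor = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
        acceptor = ifelse(.data$strand == "+", .data$end - 1L, .data$start),
        has_cryptic = .data$class == "weak",
        # cryptic donor genomic position (first intronic base of the
        # cryptic variant) in transcript orientation
        cryptic_donor = ifelse(!.data$has_cryptic, NA_integer_,
          ifelse(.data$strand == "+", .data$cgap_start, .data$cgap_end - 1L)
        )
      )
    chrom_len <- cursor - 2000L + 1500L
    list(
      genes = genes, exons = exons, introns = introns,
      chrom_lengths = c(chrS = chrom_len)
    )
  })
}

#' Generate the synthetic genome and contaminant references
#'
#' Builds one chromosome hosting every gene of the layout with >= 1 kb flanks,
#' with donor, acceptor, branch-point and cryptic-donor motifs planted at the
#' annotated positions (reverse-complemented on minus-strand genes), plus
#' random reference sequences named rRNA, U1, U2, U4, U5 and U6 for the
#' contaminant tiers.
#'
#' @param config A [simulation_config()] object.
#' @return A list with `genome` and `contaminants`, both
#'   [Biostrings::DNAStringSet] objects, and the `layout` used.
#' @export
generate_genome <- function(config) {
  layout <- simulate_layout(config)
  len <- unname(layout$chrom_lengths["chrS"])
  if (len < 3000L) abort("configured genes do not fit the chromosome")
  base_probs <- c(A = 0.275, C = 0.225, G = 0.225, T = 0.275)
  chars <- with_seed(
    derive_seed(config$seed, "genomeseq"),
    sample(names(base_probs), len, replace = TRUE, prob = base_probs)
  )

  plant <- function(chars, anchor, strand, motif, off0) {
    # motif occupies transcript offsets off0 .. off0+len-1 relative to anchor
    m <- strsplit(motif, "")[[1]]
    offs <- off0 + seq_along(m) - 1L
    if (strand == "+") {
      chars[anchor + offs + 1L] <- m
    } else {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      chars[anchor - offs + 1L] <- unname(comp[m])
    }
    chars
  }

  intr <- layout$introns
  for (i in seq_len(nrow(intr))) {
    st <- intr$strand[i]
    chars <- plant(chars, intr$donor[i], st, donor_class_seq(intr$class[i]), -3L)
    # acceptor anchor = first exonic base after the intron
    acc_anchor <- if (st == "+") intr$end[i] else intr$start[i] - 1L
    chars <- plant(chars, acc_anchor, st, acceptor_consensus_seq(), -20L)
    chars <- plant(chars, acc_anchor, st, branch_consensus_seq(), -30L)
    if (isTRUE(intr$has_cryptic[i])) {
      chars <- plant(chars, intr$cryptic_donor[i], st, donor_class_seq("cryptic"), -3L)
    }
  }
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chrS"

  cont_len <- contaminant_lengths()
  cont <- with_seed(derive_seed(config$seed, "contaminants"), {
    seqs <- vapply(cont_len, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })

  structure(
    list(genome = genome, contaminants = cont, layout = layout),
    class = "sim_genome"
  )
}

#' Generate the synthetic annotation
#'
#' Returns the gene/transcript/exon model implied by the configuration (one
#' transcript per gene). Every intron's first two intronic bases are GT and
#' its last two are AG on the annotated strand, by construction of the
#' planted motifs.
#'
#' @param config A [simulation_config()] object.
#' @param genome Optional [generate_genome()] result; when supplied, its
#'   layout is reused instead of being recomputed.
#' @return An `annotation_model` (see [parse_gtf()]).
#' @export
generate_annotation <- function(config, genome = NULL) {
  layout <- if (!is.null(genome)) genome$layout else simulate_layout(config)
  tx <- layout$exons |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  new_annotation_model(
    genes = layout$genes |>
      select("gene_id", "chrom", "strand", "start", "end"),
    transcripts = tx,
    exons = layout$exons |>
      select(
        "transcript_id", "gene_id", "chrom", "strand",
        "start", "end", "exon_rank"
      )
  )
}

#' Ground truth of the simulated dataset
#'
#' Per-intron truth table: donor class and sequence, per-condition spliced
#' fraction, planted intron log2 fold change, and cryptic donor position
#' (NA when none was planted).
#'
#' @param config A [simulation_config()] object.
#' @return A tibble, one row per intron.
#' @export
simulation_truth <- function(config) {
  layout <- simulate_layout(config)
  intr <- layout$introns
  if (nrow(intr) == 0) {
    return(tibble())
  }
  sf <- config$spliced_fraction
  out <- intr |>
    mutate(
      donor_seq = vapply(.data$class, donor_class_seq, character(1)),
      planted_log2fc = ifelse(
        .data$class == "weak", config$planted_intron_log2fc, 0
      ),
      expr = layout$genes$expr[match(.data$gene_id, layout$genes$gene_id)]
    )
  for (cond in config$conditions) {
    out[[paste0("spliced_fraction_", cond)]] <- unname(sf[[cond]][out$class])
  }
  out |>
    select(
      "intron_id", "gene_id", "chrom", "strand", "start", "end", "length",
      "donor", "acceptor", "class", "donor_seq", "expr",
      dplyr::starts_with("spliced_fraction_"),
      "planted_log2fc", "has_cryptic", "cryptic_donor",
      "cgap_start", "cgap_end"
    )
}
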