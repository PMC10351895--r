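# Read-level simulation. Reads are emitted pre-aligned (two-block records
# with gapped CIGARs on output) so no external aligner is needed; the
# real-data path consumes externally aligned SAM/BAM via read_alignments().

# Map transcript-oriented read span [o1, o2] (offsets relative to the donor,
# offset 0 = first intronic base) onto genomic blocks, for an unspliced
# precursor or a molecule with the focal intron spliced out.
donor_anchored_blocks <- function(o1, o2, donor, strand, intron_len, spliced) {
  n <- length(o1)
  start <- end <- gap_start <- gap_end <- integer(n)
  for (i in seq_len(n)) {
    if (!spliced[i]) {
      g <- sort(c(
        genomic_pos(o1[i], donor[i], strand[i]),
        genomic_pos(o2[i], donor[i], strand[i])
      ))
      start[i] <- g[1]
      end[i] <- g[2] + 1L
      gap_start[i] <- NA_integer_
      gap_end[i] <- NA_integer_
    } else if (o2[i] < 0L) {
      g <- sort(c(
        genomic_pos(o1[i], donor[i], strand[i]),
        genomic_pos(o2[i], donor[i], strand[i])
      ))
      start[i] <- g[1]
      end[i] <- g[2] + 1L
      gap_start[i] <- NA_integer_
      gap_end[i] <- NA_integer_
    } else if (o1[i] >= 0L) {
      sh <- function(o) genomic_pos(o + intron_len[i], donor[i], strand[i])
      g <- sort(c(sh(o1[i]), sh(o2[i])))
      start[i] <- g[1]
      end[i] <- g[2] + 1L
      gap_start[i] <- NA_integer_
      gap_end[i] <- NA_integer_
    } else {
      # spans the junction: exonic block o1..-1, downstream block 0..o2
      if (strand[i] == "+") {
        start[i] <- donor[i] + o1[i]
        gap_start[i] <- donor[i]
        gap_end[i] <- donor[i] + intron_len[i]
        end[i] <- gap_end[i] + o2[i] + 1L
      } else {
        end[i] <- donor[i] - o1[i] + 1L
        gap_end[i] <- donor[i] + 1L
        gap_start[i] <- gap_end[i] - intron_len[i]
        start[i] <- gap_start[i] - o2[i] - 1L
      }
    }
  }
  tibble(
    start = start, end = end,
    gap_start = gap_start, gap_end = gap_end
  )
}

genomic_pos <- function(offset, donor, strand) {
  if (strand == "+") donor + offset else donor - offset
}

sample_read_lengths <- function(n, config) {
  sample_range(config$read_length[1], config$read_length[2], n)
}

# Contaminant reads for one library.
contaminant_reads <- function(config, counts) {
  lens <- contaminant_lengths()
  out <- purrr::imap(counts, function(k, ref) {
    if (k == 0) {
      return(NULL)
    }
    L <- pmin(sample_read_lengths(k, config), lens[[ref]])
    start <- vapply(
      L, function(l) sample.int(lens[[ref]] - l + 1L, 1L) - 1L, integer(1)
    )
    tibble(
      chrom = ref, strand = "+", start = start, end = start + L,
      gap_start = NA_integer_, gap_end = NA_integer_,
      nm = sample(0:2, k, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
      unique = TRUE, origin = "contaminant", ref = ref,
      intron_id = NA_character_, spliced = NA,
      crosslink_offset = NA_integer_
    )
  })
  bind_rows(out)
}

#' Simulate CLIP libraries as pre-aligned reads
#'
#' Emulates cross-linking immunoprecipitation libraries of proteins bound at
#' 5' splice sites: cross-link positions are drawn `Normal(-mean, sd)` nt
#' around donors (upstream negative, so the configured default places the
#' pileup mode 30 nt into the upstream exon), the cross-link sits at a
#' uniform position within each read, reads from unspliced precursors are
#' contiguous across or near the donor, and reads from spliced molecules
#' carry a gap spanning exactly the annotated intron. Each protein binds all
#' weak-donor introns plus a random share of the others, with configurable
#' fold enrichment; the remainder of each library is rRNA/snRNA contaminant
#' reads.
#'
#' @param config A [simulation_config()] object.
#' @param genome A [generate_genome()] result.
#' @param annotation Optional `annotation_model` (recomputed if absent).
#' @return A list of class `sim_reads`: `reads` (a tibble of aligned records
#'   with `qname`, `lib`, `protein`, `condition`, `replicate`, `chrom`,
#'   `strand`, `start`, `end`, `gap_start`, `gap_end`, `unique`, `nm`) and
#'   `truth` (per-read origin records).
#' @export
simulate_clip_reads <- function(config, genome, annotation = NULL) {
  layout <- genome$layout
  intr <- layout$introns
  if (nrow(intr) == 0) abort("layout has no introns to bind")
  expr <- layout$genes$expr[match(intr$gene_id, layout$genes$gene_id)]
  ref_cond <- config$conditions[1]
  p_spliced <- config$spliced_fraction[[ref_cond]][intr$class]

  libs <- tidyr::expand_grid(
    protein = config$proteins,
    replicate = seq_len(config$replicates_per_condition)
  ) |>
    mutate(lib = sprintf("%s_rep%d", .data$protein, .data$replicate))

  bound_sets <- lapply(config$proteins, function(p) {
    with_seed(derive_seed(config$seed, paste0("bound_", p)), {
      other <- which(intr$class != "weak")
      pick <- other[runif(length(other)) < config$clip_bound_other_fraction]
      sort(c(which(intr$class == "weak"), pick))
    })
  })
  names(bound_sets) <- config$proteins

  sim_lib <- function(lib, protein, replicate) {
    with_seed(derive_seed(config$seed, paste0("clip_", lib)), {
      n <- config$n_reads_per_library
      cont_n <- floor(config$contaminant_fractions * n)
      n_gene <- n - sum(cont_n)
      bound <- seq_len(nrow(intr)) %in% bound_sets[[protein]]
      w <- expr * ifelse(bound, config$clip_enrichment, 1)
      if (sum(w) == 0) abort("no expressed introns to sample CLIP reads from")
      idx <- sample.int(nrow(intr), n_gene, replace = TRUE, prob = w)
      spliced <- rbinom(n_gene, 1L, p_spliced[idx]) == 1L
      off <- round(rnorm(
        n_gene, -config$crosslink_offset[["mean"]],
        config$crosslink_offset[["sd"]]
      ))
      off <- as.integer(ifelse(spliced & off >= 0L, -1L, off))
      L <- sample_read_lengths(n_gene, config)
      u <- vapply(L, function(l) sample.int(l, 1L), integer(1))
      o1 <- off - (u - 1L)
      o2 <- off + (L - u)
      blocks <- donor_anchored_blocks(
        o1, o2, intr$donor[idx], intr$strand[idx], intr$length[idx], spliced
      )
      gene_reads <- blocks |>
        mutate(
          chrom = intr$chrom[idx], strand = intr$strand[idx],
          nm = 0L,
          unique = runif(n_gene) >= config$clip_multimap_fraction,
          origin = "gene", ref = intr$gene_id[idx],
          intron_id = intr$intron_id[idx], spliced = spliced,
          crosslink_offset = off
        )
      all_reads <- bind_rows(gene_reads, contaminant_reads(config, cont_n)) |>
        mutate(
          lib = lib, protein = protein, condition = protein,
          replicate = replicate,
          qname = sprintf("%s_r%06d", lib, row_number())
        )
      all_reads
    })
  }

  reads <- purrr::pmap(libs, function(protein, replicate, lib) {
    sim_lib(lib, protein, replicate)
  }) |> bind_rows()
  truth <- reads |>
    select(
      "qname", "lib", "origin", "ref", "intron_id", "spliced",
      "crosslink_offset"
    )
  reads <- reads |>
    select(
      "qname", "lib", "protein", "condition", "replicate", "chrom",
      "strand", "start", "end", "gap_start", "gap_end", "unique", "nm"
    )
  structure(list(reads = reads, truth = truth), class = "sim_reads")
}

#' Simulate RNA-seq libraries as pre-aligned reads
#'
#' Uniform positional coverage along exons and (unspliced) introns plus
#' junction-spanning reads. Intron read abundance scales with
#' `1 - spliced_fraction`; in non-reference conditions the unspliced
#' abundance of weak-class introns is multiplied by
#' `2^planted_intron_log2fc`, and the planted cryptic donor of each weak
#' intron captures `cryptic_inclusion[condition]` of its junction reads.
#'
#' @inheritParams simulate_clip_reads
#' @return A list of class `sim_reads` (see [simulate_clip_reads()]); truth
#'   records carry the sampled segment type (`exon`, `intron`,
#'   `junction_annotated`, `junction_cryptic`).
#' @export
simulate_rnaseq_reads <- function(config, genome, annotation = NULL) {
  layout <- genome$layout
  intr <- layout$introns
  exons <- layout$exons
  genes <- layout$genes
  ref_cond <- config$conditions[1]

  libs <- tidyr::expand_grid(
    condition = config$conditions,
    replicate = seq_len(config$replicates_per_condition)
  ) |>
    mutate(lib = sprintf("%s_rep%d", .data$condition, .data$replicate))

  weak_genes <- unique(intr$gene_id[intr$class == "weak"])

  segment_table <- function(cond) {
    p_spliced <- config$spliced_fraction[[cond]][intr$class]
    upf <- ifelse(
      intr$class == "weak" & cond != ref_cond,
      2^config$planted_intron_log2fc, 1
    )
    cinc <- unname(config$cryptic_inclusion[cond])
    if (is.na(cinc)) cinc <- 0
    # mature-signal effect of missplicing: genes hosting a weak intron lose
    # exonic/junction abundance in the perturbed condition
    mature_f <- function(gene_id) {
      ifelse(
        gene_id %in% weak_genes & cond != ref_cond,
        2^config$planted_gene_log2fc, 1
      )
    }
    gexpr <- genes$expr[match(exons$gene_id, genes$gene_id)] *
      mature_f(exons$gene_id)
    iexpr <- genes$expr[match(intr$gene_id, genes$gene_id)]
    jexpr <- iexpr * mature_f(intr$gene_id)
    seg_ex <- tibble(
      type = "exon", chrom = exons$chrom, strand = exons$strand,
      seg_start = exons$start, seg_end = exons$end,
      gap_start = NA_integer_, gap_end = NA_integer_,
      intron_id = NA_character_,
      weight = (exons$end - exons$start) * gexpr
    )
    seg_in <- tibble(
      type = "intron", chrom = intr$chrom, strand = intr$strand,
      seg_start = intr$start, seg_end = intr$end,
      gap_start = NA_integer_, gap_end = NA_integer_,
      intron_id = intr$intron_id,
      weight = intr$length * iexpr * (1 - p_spliced) *
        config$rnaseq_intron_scale * upf
    )
    seg_ja <- tibble(
      type = "junction_annotated", chrom = intr$chrom, strand = intr$strand,
      seg_start = NA_integer_, seg_end = NA_integer_,
      gap_start = intr$start, gap_end = intr$end,
      intron_id = intr$intron_id,
      weight = config$junction_weight * jexpr * p_spliced *
        ifelse(intr$has_cryptic, 1 - cinc, 1)
    )
    seg_jc <- tibble(
      type = "junction_cryptic", chrom = intr$chrom, strand = intr$strand,
      seg_start = NA_integer_, seg_end = NA_integer_,
      gap_start = intr$cgap_start, gap_end = intr$cgap_end,
      intron_id = intr$intron_id,
      weight = config$junction_weight * jexpr * p_spliced *
        ifelse(intr$has_cryptic, cinc, 0)
    )
    bind_rows(seg_ex, seg_in, seg_ja, seg_jc) |>
      filter(.data$weight > 0)
  }

  sim_lib <- function(lib, condition, replicate) {
    segs <- segment_table(condition)
    with_seed(derive_seed(config$seed, paste0("rna_", lib)), {
      n <- config$n_reads_per_library
      idx <- sample.int(nrow(segs), n, replace = TRUE, prob = segs$weight)
      L <- sample_read_lengths(n, config)
      s <- segs[idx, ]
      is_junc <- grepl("^junction", s$type)
      start <- end <- gap_start <- gap_end <- integer(n)
      # contiguous segment reads
      ci <- which(!is_junc)
      seg_len <- s$seg_end[ci] - s$seg_start[ci]
      Lc <- pmin(L[ci], seg_len)
      off <- vapply(
        seg_len - Lc + 1L, function(m) sample.int(m, 1L) - 1L, integer(1)
      )
      start[ci] <- s$seg_start[ci] + off
      end[ci] <- start[ci] + Lc
      gap_start[ci] <- NA_integer_
      gap_end[ci] <- NA_integer_
      # junction reads: overhangs of >= 5 nt on both sides
      ji <- which(is_junc)
      if (length(ji) > 0) {
        Lj <- pmax(L[ji], 12L)
        a <- vapply(Lj, function(l) sample(5:(l - 5L), 1L), integer(1))
        start[ji] <- s$gap_start[ji] - a
        end[ji] <- s$gap_end[ji] + (Lj - a)
        gap_start[ji] <- s$gap_start[ji]
        gap_end[ji] <- s$gap_end[ji]
      }
      tibble(
        qname = sprintf("%s_r%06d", lib, seq_len(n)),
        lib = lib, protein = NA_character_, condition = condition,
        replicate = replicate,
        chrom = s$chrom, strand = s$strand,
        start = start, end = end,
        gap_start = ifelse(is_junc, gap_start, NA_integer_),
        gap_end = ifelse(is_junc, gap_end, NA_integer_),
        unique = TRUE, nm = 0L,
        origin = s$type, ref = NA_character_, intron_id = s$intron_id
      )
    })
  }

  all <- purrr::pmap(libs, function(condition, replicate, lib) {
    sim_lib(lib, condition, replicate)
  }) |> bind_rows()
  truth <- all |> select("qname", "lib", "origin", "intron_id")
  reads <- all |>
    select(
      "qname", "lib", "protein", "condition", "replicate", "chrom",
      "strand", "start", "end", "gap_start", "gap_end", "unique", "nm"
    )
  structure(list(reads = reads, truth = truth), class = "sim_reads")
}

#' Write aligned reads as SAM
#'
#' Emits one single-end record per read with gapped CIGARs (`xMyNzM`) for
#' junction reads, MAPQ 255 for unique and 0 for multi-mapping alignments,
#' and `NM`/`NH` tags. Sequence and quality fields are `*` placeholders.
#'
#' @param reads Read tibble (see [simulate_clip_reads()]).
#' @param path Output path.
#' @param seqlengths Named integer vector of reference lengths for the
#'   header, e.g. from the generated genome and contaminant set.
#' @export
write_sam <- function(reads, path, seqlengths) {
  reads <- check_read_tbl(reads)
  used <- unique(reads$chrom)
  missing <- setdiff(used, names(seqlengths))
  if (length(missing) > 0) {
    abort(sprintf(
      "seqlengths missing reference(s): %s", paste(missing, collapse = ", ")
    ))
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths))
  )
  gapped <- !is.na(reads$gap_start)
  cigar <- ifelse(gapped,
    sprintf(
      "%dM%dN%dM",
      reads$gap_start - reads$start,
      reads$gap_end - reads$gap_start,
      reads$end - reads$gap_end
    ),
    sprintf("%dM", reads$end - reads$start)
  )
  nm <- if ("nm" %in% names(reads)) reads$nm else 0L
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNM:i:%d\tNH:i:%d",
    reads$qname,
    ifelse(reads$strand == "-", 16L, 0L),
    reads$chrom, reads$start + 1L,
    ifelse(reads$unique, 255L, 0L),
    cigar, nm, ifelse(reads$unique, 1L, 2L)
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Load aligned reads from SAM/BAM into the canonical read tibble
#'
#' Real-data entry point: converts SAM to BAM if needed (Rsamtools), reads
#' alignments with GenomicAlignments, and returns the two-block read tibble
#' the analysis functions consume. Reads with more than one junction gap
#' keep their first gap; uniqueness is taken from the NH tag when present,
#' else MAPQ == 255.
#'
#' @param path SAM or BAM file.
#' @param lib,condition,replicate Library labels attached to every read.
#' @return A read tibble.
#' @export
read_alignments <- function(path, lib = basename(path),
                            condition = NA_character_, replicate = NA_integer_) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
    !requireNamespace("GenomicAlignments", quietly = TRUE)) {
    abort("Rsamtools and GenomicAlignments are required to read SAM/BAM")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
      overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    tag = c("NM", "NH"), what = c("qname", "mapq")
  )
  ga <- GenomicAlignments::readGAlignments(path, param = param, use.names = FALSE)
  md <- S4Vectors::mcols(ga)
  cig <- GenomicAlignments::cigar(ga)
  pos <- GenomicRanges::start(ga) - 1L
  gaps <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, ops = "N", pos = GenomicRanges::start(ga))
  ngap <- lengths(gaps)
  first_gap_start <- rep(NA_integer_, length(ga))
  first_gap_end <- rep(NA_integer_, length(ga))
  has <- ngap > 0
  if (any(has)) {
    fg <- vapply(which(has), function(i) {
      r <- gaps[[i]][1]
      c(IRanges::start(r) - 1L, IRanges::end(r))
    }, integer(2))
    first_gap_start[has] <- fg[1, ]
    first_gap_end[has] <- fg[2, ]
  }
  nh <- md$NH
  unique_flag <- if (!is.null(nh) && !all(is.na(nh))) {
    ifelse(is.na(nh), md$mapq == 255L, nh == 1L)
  } else {
    md$mapq == 255L
  }
  tibble(
    qname = md$qname,
    lib = lib, condition = condition, replicate = replicate,
    chrom = as.character(GenomicRanges::seqnames(ga)),
    strand = as.character(GenomicRanges::strand(ga)),
    start = pos,
    end = GenomicRanges::end(ga),
    gap_start = first_gap_start,
    gap_end = first_gap_end,
    unique = unique_flag,
    nm = if (!is.null(md$NM)) md$NM else NA_integer_
  )
}
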