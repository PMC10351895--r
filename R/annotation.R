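# Annotation model: genes/transcripts/exons as tibbles, introns derived.
# Internal coordinates are 0-based half-open; GTF I/O is 1-based closed.

new_annotation_model <- function(genes, transcripts, exons) {
  exons <- exons |>
    arrange(.data$transcript_id, .data$start)
  bad <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      overlap = any(.data$start[-1] < head(.data$end, -1)),
      .groups = "drop"
    ) |>
    filter(.data$overlap)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "overlapping exons within transcript(s): %s",
      paste(bad$transcript_id, collapse = ", ")
    ))
  }
  structure(
    list(
      genes = as_tibble(genes), transcripts = as_tibble(transcripts),
      exons = as_tibble(exons)
    ),
    class = "annotation_model"
  )
}

#' @export
print.annotation_model <- function(x, ...) {
  cat(sprintf(
    "<annotation_model> %d genes, %d transcripts, %d exons\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons)
  ))
  invisible(x)
}

#' Parse a GTF annotation into a hierarchical model
#'
#' Reads gene, transcript and exon records from a GTF file into tibbles of
#' 0-based half-open intervals. Transcript and gene records missing from the
#' file are reconstructed from the exon spans. Exons overlapping within a
#' transcript fail validation.
#'
#' @param path Path to a GTF file.
#' @return An object of class `annotation_model`: a list of tibbles `genes`
#'   (`gene_id`, `chrom`, `strand`, `start`, `end`), `transcripts`, and
#'   `exons` (with `exon_rank` in transcript orientation).
#' @export
parse_gtf <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    abort(sprintf(
      "malformed GTF record at line %d (fewer than 9 fields)",
      body[which(nf < 9)[1]]
    ))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!all(c("type", "gene_id") %in% names(df))) {
    abort("GTF lacks type/gene_id attributes")
  }
  ex <- df |>
    filter(.data$type == "exon") |>
    mutate(
      chrom = as.character(.data$seqnames),
      strand = as.character(.data$strand),
      start = .data$start - 1L
    )
  if (nrow(ex) == 0) abort("GTF contains no exon records")
  if (!"transcript_id" %in% names(ex) || anyNA(ex$transcript_id)) {
    abort("exon records must carry transcript_id")
  }
  exons <- ex |>
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end") |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(exon_rank = if (first(.data$strand) == "-") {
      rev(row_number())
    } else {
      row_number()
    }) |>
    ungroup()
  transcripts <- exons |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  genes <- transcripts |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  new_annotation_model(genes, transcripts, exons)
}

#' Write an annotation model as GTF
#'
#' @param model An `annotation_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(model, path) {
  ex <- model$exons
  attr_str <- sprintf(
    'gene_id "%s"; transcript_id "%s";',
    ex$gene_id, ex$transcript_id
  )
  rows <- c(
    sprintf(
      "%s\tspliceclip\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
      model$transcripts$chrom, model$transcripts$start + 1L,
      model$transcripts$end, model$transcripts$strand,
      sprintf(
        'gene_id "%s"; transcript_id "%s";',
        model$transcripts$gene_id, model$transcripts$transcript_id
      )
    ),
    sprintf(
      "%s\tspliceclip\texon\t%d\t%d\t.\t%s\t.\t%s",
      ex$chrom, ex$start + 1L, ex$end, ex$strand, attr_str
    )
  )
  writeLines(rows, path)
  invisible(path)
}

#' Extract unique introns from an annotation model
#'
#' Introns are the gaps between consecutive exons of each transcript,
#' deduplicated by (chrom, start, end, strand) with transcript ids
#' aggregated. Donor is the first intronic base and acceptor the last, in
#' transcript orientation. When a genome is supplied, intron GC fraction is
#' computed from its sequence.
#'
#' @param model An `annotation_model`.
#' @param genome Optional [Biostrings::DNAStringSet] holding the chromosome
#'   sequences.
#' @return A tibble with one row per unique intron: `intron_id`, `gene_id`,
#'   `transcript_ids` (comma-collapsed), `chrom`, `strand`, `start`, `end`
#'   (0-based half-open), `donor`, `acceptor`, `length`, and `gc` when a
#'   genome is given.
#' @export
extract_introns <- function(model, genome = NULL) {
  per_tx <- model$exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(
      .data$transcript_id, .data$gene_id, .data$chrom, .data$strand
    ) |>
    summarise(
      istart = list(head(.data$end, -1)),
      iend = list(.data$start[-1]),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("istart", "iend")) |>
    rename(start = "istart", end = "iend")
  if (nrow(per_tx) == 0) {
    return(tibble(
      intron_id = character(), gene_id = character(),
      transcript_ids = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      donor = integer(), acceptor = integer(), length = integer()
    ))
  }
  introns <- per_tx |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    summarise(
      gene_id = first(.data$gene_id),
      transcript_ids = paste(sort(unique(.data$transcript_id)),
        collapse = ","
      ),
      .groups = "drop"
    ) |>
    mutate(
      length = .data$end - .data$start,
      donor = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
      acceptor = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
    ) |>
    arrange(.data$chrom, .data$start, .data$end) |>
    mutate(intron_id = sprintf(
      "%s:%d-%d:%s", .data$chrom, .data$start, .data$end, .data$strand
    ))
  if (any(introns$length < 4)) abort("intron shorter than 4 nt in model")
  if (!is.null(genome)) {
    seqs <- intron_sequences(introns, genome)
    introns$gc <- vapply(seqs, function(s) {
      b <- strsplit(s, "")[[1]]
      mean(b %in% c("G", "C"))
    }, numeric(1), USE.NAMES = FALSE)
  }
  introns |>
    select(
      "intron_id", "gene_id", "transcript_ids", "chrom", "strand",
      "start", "end", "donor", "acceptor", "length",
      dplyr::any_of("gc")
    )
}

# Strand-oriented intron sequences (character vector).
intron_sequences <- function(introns, genome) {
  vapply(seq_len(nrow(introns)), function(i) {
    s <- Biostrings::subseq(
      genome[[introns$chrom[i]]],
      start = introns$start[i] + 1L, end = introns$end[i]
    )
    if (introns$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
}

# Strand-oriented genomic window sequence around an anchor position:
# transcript offsets off0 .. off0+len-1, offset 0 = anchor base.
anchored_sequence <- function(chrom, anchor, strand, off0, len, genome) {
  vapply(seq_along(anchor), function(i) {
    if (strand[i] == "+") {
      s <- Biostrings::subseq(genome[[chrom[i]]],
        start = anchor[i] + off0 + 1L, end = anchor[i] + off0 + len
      )
    } else {
      s <- Biostrings::subseq(genome[[chrom[i]]],
        start = anchor[i] - off0 - len + 2L, end = anchor[i] - off0 + 1L
      )
      s <- Biostrings::reverseComplement(s)
    }
    as.character(s)
  }, character(1))
}

#' Select expressed genes, transcripts and 5' splice sites
#'
#' Applies the expression rules used to define the analysed splice-site
#' universe: genes with abundance > 0 are expressed, transcripts with
#' abundance > 0 within expressed genes are kept, and the donors of the kept
#' transcripts' introns are deduplicated into the expressed 5'SS list. Both
#' filters are required for a donor to survive. Any positive-scaling
#' abundance unit (FPKM, TPM, raw counts) is equivalent under the > 0
#' threshold.
#'
#' @param model An `annotation_model`.
#' @param gene_counts Tibble with `gene_id` and `count` (or any abundance).
#' @param transcript_abundance Tibble with `transcript_id` and `abundance`.
#' @param genome Optional genome for intron GC annotation.
#' @return A list of class `expressed_set`: `genes`, `transcripts`
#'   (character vectors) and `donors`, a tibble of deduplicated expressed
#'   5'SSs keyed by (chrom, donor, strand) carrying the shortest containing
#'   intron's metadata.
#' @export
select_expressed <- function(model, gene_counts, transcript_abundance,
                             genome = NULL) {
  unknown_g <- setdiff(gene_counts$gene_id, model$genes$gene_id)
  unknown_t <- setdiff(
    transcript_abundance$transcript_id, model$transcripts$transcript_id
  )
  if (length(unknown_g) + length(unknown_t) > 0) {
    abort(sprintf(
      "unknown ids: %s",
      paste(c(unknown_g, unknown_t), collapse = ", ")
    ))
  }
  expressed_genes <- gene_counts$gene_id[gene_counts$count > 0]
  expressed_tx <- transcript_abundance$transcript_id[
    transcript_abundance$abundance > 0
  ]
  tx_gene <- model$transcripts$gene_id[
    match(expressed_tx, model$transcripts$transcript_id)
  ]
  expressed_tx <- expressed_tx[tx_gene %in% expressed_genes]

  introns <- extract_introns(model, genome)
  keep <- purrr::map_lgl(
    strsplit(introns$transcript_ids, ","),
    function(t) any(t %in% expressed_tx)
  )
  donors <- introns[keep, , drop = FALSE] |>
    arrange(.data$chrom, .data$donor, .data$strand, .data$length) |>
    distinct(.data$chrom, .data$donor, .data$strand, .keep_all = TRUE)
  structure(
    list(
      genes = intersect(model$genes$gene_id, expressed_genes),
      transcripts = expressed_tx,
      donors = donors
    ),
    class = "expressed_set"
  )
}

#' Write donor sites as BED6
#'
#' One 1-nt interval per expressed donor (0-based half-open), name = gene id,
#' score = 0.
#'
#' @param donors Donor tibble (e.g. `select_expressed()$donors`).
#' @param path Output path.
#' @export
write_donor_bed <- function(donors, path) {
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t0\t%s",
    donors$chrom, donors$donor, donors$donor + 1L,
    donors$gene_id, donors$strand
  ), path)
  invisible(path)
}
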