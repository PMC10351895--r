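# Read preprocessing bookkeeping, hierarchical read categorization, and
# snRNA coverage profiling.

#' Preprocess raw reads: collapse duplicates, demultiplex, trim 3' tails
#'
#' Mirrors the bookkeeping steps of CLIP library preprocessing: exact
#' sequence duplicates are collapsed, reads are assigned to samples by exact
#' in-line barcode prefix match (the barcode is removed), and 3' homopolymer
#' runs of at least `min_homopolymer` nt -- the low-complexity tails left by
#' poly(A)-tailing chemistry -- are trimmed. Reads matching no barcode are
#' routed to the `undetermined` bin and counted.
#'
#' @param reads A tibble with columns `id` and `seq`, or a FASTA/FASTQ path.
#' @param barcodes A tibble with columns `sample` and `barcode`.
#' @param min_homopolymer Minimum length of a trailing single-nucleotide run
#'   to trim (default 6).
#' @return A tibble with `sample`, `id`, `seq` (processed).
#' @export
preprocess_reads <- function(reads, barcodes, min_homopolymer = 6L) {
  if (is.character(reads) && length(reads) == 1) {
    fmt <- if (grepl("\\.(fq|fastq)$", reads, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
    ss <- Biostrings::readDNAStringSet(reads, format = fmt)
    reads <- tibble(id = names(ss), seq = as.character(ss))
  }
  if (anyDuplicated(barcodes$barcode)) {
    dup <- barcodes$barcode[duplicated(barcodes$barcode)]
    abort(sprintf(
      "barcode collision: %s assigned to more than one sample",
      paste(unique(dup), collapse = ", ")
    ))
  }
  collapsed <- reads |> distinct(.data$seq, .keep_all = TRUE)
  bc <- barcodes |> arrange(desc(nchar(.data$barcode)))
  assign_one <- function(s) {
    hit <- which(startsWith(s, bc$barcode))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  hits <- vapply(collapsed$seq, assign_one, integer(1), USE.NAMES = FALSE)
  out <- collapsed |>
    mutate(
      sample = ifelse(is.na(hits), "undetermined", bc$sample[hits]),
      seq = ifelse(is.na(hits), .data$seq,
        substring(.data$seq, nchar(bc$barcode[hits]) + 1L)
      )
    )
  out$seq <- trim_3p_homopolymer(out$seq, min_homopolymer)
  out |> select("sample", "id", "seq")
}

trim_3p_homopolymer <- function(seq, min_run) {
  pattern <- sprintf("([ACGTN])\\1{%d,}$", min_run - 1L)
  sub(pattern, "", seq)
}

#' Hierarchically categorize reads across reference tiers
#'
#' Each read is assigned to the first reference tier in which it has an
#' alignment (e.g. rRNA, then mature mRNA, then genome); reads mapping
#' nowhere are `unmapped`. The categories partition the pool, so the tally
#' always sums to the input read count.
#'
#' @param pool Character vector of read ids (the full read pool).
#' @param tier_hits Named list, in cascade order, of character vectors of
#'   read ids aligned in each tier.
#' @return A tibble with `category` (tier names plus `unmapped`), `count`
#'   and `fraction`.
#' @export
categorize_hierarchical <- function(pool, tier_hits) {
  if (is.null(names(tier_hits)) || any(!nzchar(names(tier_hits)))) {
    abort("tier_hits must be a fully named list")
  }
  stray <- setdiff(unique(unlist(tier_hits)), pool)
  if (length(stray) > 0) {
    abort(sprintf(
      "read id(s) present in a tier but missing from the pool: %s",
      paste(head(stray, 5), collapse = ", ")
    ))
  }
  remaining <- unique(pool)
  counts <- integer(length(tier_hits))
  for (i in seq_along(tier_hits)) {
    hit <- intersect(remaining, tier_hits[[i]])
    counts[i] <- length(hit)
    remaining <- setdiff(remaining, hit)
  }
  tibble(
    category = c(names(tier_hits), "unmapped"),
    count = c(counts, length(remaining))
  ) |>
    mutate(fraction = .data$count / length(unique(pool)))
}

#' Profile snRNA-mapping reads
#'
#' Computes per-base coverage across each snRNA reference and the read-share
#' statistics of the major-spliceosome snRNAs (U1, U2, U4, U5, U6). Only
#' alignments at least `min_length` nt long with edit distance at most
#' `max_nm` contribute.
#'
#' @param alignments Read tibble of alignments to snRNA references (`chrom`
#'   = snRNA name); must carry an `nm` edit-distance column.
#' @param snrna_lengths Named integer vector of snRNA reference lengths.
#' @param total_reads Total reads in the library, the denominator of the
#'   ms-snRNA fraction (defaults to the number of alignment records).
#' @param min_length,max_nm Alignment filters (defaults 20 nt and 1 edit).
#' @return A list of class `snrna_profile`: `coverage` (tibble snrna/pos/
#'   cov), `counts` (per-snRNA reads and share of ms-snRNA reads), and
#'   `ms_fraction` (ms-snRNA reads / `total_reads`).
#' @export
snrna_profile <- function(alignments, snrna_lengths,
                          total_reads = nrow(alignments),
                          min_length = 20L, max_nm = 1L) {
  alignments <- check_read_tbl(alignments, "alignments")
  if (!"nm" %in% names(alignments) || anyNA(alignments$nm)) {
    bad <- if (!"nm" %in% names(alignments)) {
      "all records"
    } else {
      paste(head(alignments$qname[is.na(alignments$nm)], 3), collapse = ", ")
    }
    abort(sprintf("missing edit-distance (NM) annotation: %s", bad))
  }
  snrnas <- intersect(names(snrna_lengths), ms_snrnas())
  keep <- alignments |>
    filter(
      .data$chrom %in% snrnas,
      (.data$end - .data$start) >= min_length,
      .data$nm <= max_nm
    )
  cov <- purrr::map(snrnas, function(s) {
    L <- snrna_lengths[[s]]
    v <- integer(L)
    r <- keep |> filter(.data$chrom == s)
    for (i in seq_len(nrow(r))) {
      pos <- (r$start[i] + 1L):r$end[i]
      v[pos] <- v[pos] + 1L
    }
    tibble(snrna = s, pos = seq_len(L), cov = v)
  }) |> bind_rows()
  counts <- keep |>
    count(snrna = .data$chrom, name = "reads") |>
    tidyr::complete(snrna = snrnas, fill = list(reads = 0L)) |>
    mutate(share = if (sum(.data$reads) > 0) {
      .data$reads / sum(.data$reads)
    } else {
      NA_real_
    })
  structure(
    list(
      coverage = cov, counts = counts,
      ms_fraction = sum(counts$reads) / total_reads
    ),
    class = "snrna_profile"
  )
}

#' Write per-snRNA coverage as bedGraph
#'
#' @param profile A [snrna_profile()] result.
#' @param path Output path.
#' @export
write_snrna_bedgraph <- function(profile, path) {
  cov <- profile$coverage
  writeLines(sprintf(
    "%s\t%d\t%d\t%d", cov$snrna, cov$pos - 1L, cov$pos, cov$cov
  ), path)
  invisible(path)
}
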