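# Internal helpers shared across modules.

# Overlap length between a two-block read and a feature interval, all 0-based
# half-open. Vectorized over reads.
block_overlap_width <- function(start, end, gap_start, gap_end, f_start, f_end) {
  gapped <- !is.na(gap_start)
  b1_end <- ifelse(gapped, gap_start, end)
  w1 <- pmax(0L, pmin(b1_end, f_end) - pmax(start, f_start))
  w2 <- ifelse(gapped,
    pmax(0L, pmin(end, f_end) - pmax(gap_end, f_start)),
    0L
  )
  as.integer(w1 + w2)
}

# GRanges from the block structure of a read table: one range per aligned
# block, with a read index in mcols for mapping hits back to rows.
reads_to_block_granges <- function(reads) {
  gapped <- !is.na(reads$gap_start)
  b1 <- tibble(
    idx = seq_len(nrow(reads)),
    chrom = reads$chrom, strand = reads$strand,
    start = reads$start,
    end = ifelse(gapped, reads$gap_start, reads$end)
  )
  b2 <- tibble(
    idx = which(gapped),
    chrom = reads$chrom[gapped], strand = reads$strand[gapped],
    start = reads$gap_end[gapped], end = reads$end[gapped]
  )
  blocks <- bind_rows(b1, b2)
  gr <- GenomicRanges::GRanges(
    seqnames = blocks$chrom,
    ranges = IRanges::IRanges(start = blocks$start + 1L, end = blocks$end),
    strand = blocks$strand
  )
  S4Vectors::mcols(gr)$idx <- blocks$idx
  gr
}

# Validate that a data frame has the canonical aligned-read columns.
check_read_tbl <- function(reads, arg = "reads") {
  needed <- c("qname", "chrom", "strand", "start", "end")
  missing <- setdiff(needed, names(reads))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s", arg,
      paste(missing, collapse = ", ")
    ))
  }
  if (!"gap_start" %in% names(reads)) reads$gap_start <- NA_integer_
  if (!"gap_end" %in% names(reads)) reads$gap_end <- NA_integer_
  if (!"unique" %in% names(reads)) reads$unique <- TRUE
  reads
}

# Uniform integer draws from [lo, hi], safe for lo == hi (unlike sample()).
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Deterministic child seed derived from a base seed and a label, kept within
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
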