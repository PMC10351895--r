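# Brute-force oracles and small fixture builders, independent of the
# package's implementation paths.

# A read tibble row.
mk_read <- function(chrom, strand, start, end, gap_start = NA_integer_,
                    gap_end = NA_integer_, unique = TRUE, lib = "lib1",
                    condition = NA_character_, replicate = 1L,
                    nm = 0L, qname = NULL) {
  tibble::tibble(
    qname = qname %||% sprintf("r%06d", sample.int(1e6, 1)),
    lib = lib, condition = condition, replicate = replicate,
    chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    gap_start = as.integer(gap_start), gap_end = as.integer(gap_end),
    unique = unique, nm = as.integer(nm)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Position-by-position brute-force classification of one read for a donor.
oracle_classify_one <- function(read, intron, k = 5) {
  if (read$chrom != intron$chrom || read$strand != intron$strand) {
    return("ignored")
  }
  gapped <- !is.na(read$gap_start)
  if (gapped && read$gap_start == intron$start && read$gap_end == intron$end) {
    return("spliced")
  }
  if (gapped) {
    return("ignored")
  }
  covered <- seq(read$start, read$end - 1L)
  intronic <- intersect(covered, seq(intron$start, intron$end - 1L))
  exonic <- if (intron$strand == "+") {
    intersect(covered, seq(intron$start - 200L, intron$start - 1L))
  } else {
    intersect(covered, seq(intron$end, intron$end + 199L))
  }
  if (length(intronic) >= k && length(exonic) >= k) {
    # require contiguity through the boundary
    boundary <- if (intron$strand == "+") intron$start else intron$end - 1L
    if (boundary %in% covered) {
      return("unspliced")
    }
  }
  "ignored"
}

# Closed-form Benjamini-Hochberg.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Exhaustive two-sided rank-sum p-value by permutation enumeration.
oracle_ranksum_p <- function(x, y) {
  all <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(all), n)
  w_obs <- sum(rank(all)[seq_len(n)])
  ws <- apply(idx, 2, function(i) sum(rank(all)[i]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Brute-force interval intersection (0-based half-open).
oracle_intersects <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# Tiny two-gene annotation GTF written to a temp file.
write_toy_gtf <- function(path) {
  lines <- c(
    "# toy annotation",
    paste("chr1\ttoy\texon\t101\t200\t.\t+\t.",
      'gene_id "gA"; transcript_id "gA.t1";',
      sep = "\t"
    ),
    paste("chr1\ttoy\texon\t301\t400\t.\t+\t.",
      'gene_id "gA"; transcript_id "gA.t1";',
      sep = "\t"
    ),
    paste("chr1\ttoy\texon\t601\t700\t.\t-\t.",
      'gene_id "gB"; transcript_id "gB.t1";',
      sep = "\t"
    ),
    paste("chr1\ttoy\texon\t801\t900\t.\t-\t.",
      'gene_id "gB"; transcript_id "gB.t1";',
      sep = "\t"
    )
  )
  writeLines(lines, path)
  path
}

# Small shared simulation for expensive fixtures, built once per test run.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        seed = 42L, n_genes = 10L, n_reads_per_library = 8000L
      )
      g <- generate_genome(cfg)
      ann <- generate_annotation(cfg, g)
      cache <<- list(
        cfg = cfg, genome = g, annotation = ann,
        introns = extract_introns(ann, g$genome),
        truth = simulation_truth(cfg)
      )
    }
    cache
  }
})
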