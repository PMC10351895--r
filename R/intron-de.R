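# Gene- and intron-level counting and negative-binomial differential
# analysis with the count prefilters and missplicing selection logic.

#' Count reads in genes or introns
#'
#' Gene mode mirrors strict unique-gene counting: uniquely mapping reads
#' overlapping exactly one gene by at least 1 nt are counted for it;
#' reads hitting two genes count for neither. Intron mode counts a read for
#' every intron it overlaps by at least `min_overlap` nt (default 10),
#' multi-feature overlap allowed. Overlap width is computed on the aligned
#' blocks, so a junction read's gap contributes nothing. `strandedness`
#' chooses between sense counting (synthetic libraries) and antisense
#' counting (reverse-stranded chemistry, featureCounts strandSpecific = 2).
#'
#' @param reads Read tibble with `lib`, `condition`, `replicate`.
#' @param features Feature tibble: genes (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`) or introns (with `intron_id`).
#' @param mode `"gene"` or `"intron"`.
#' @param min_overlap Minimum overlap in nt (1 for genes, 10 for introns by
#'   default).
#' @param strandedness `"sense"` or `"antisense"`.
#' @return An object of class `counts_table`: list with `counts` (features x
#'   libraries integer matrix) and `samples` (tibble lib/condition/
#'   replicate).
#' @export
count_features <- function(reads, features, mode = c("gene", "intron"),
                           min_overlap = NULL,
                           strandedness = c("sense", "antisense")) {
  mode <- match.arg(mode)
  strandedness <- match.arg(strandedness)
  reads <- check_read_tbl(reads)
  if (is.null(min_overlap)) {
    min_overlap <- if (mode == "gene") 1L else 10L
  }
  id_col <- if (mode == "gene") "gene_id" else "intron_id"
  reads <- reads |> filter(.data$unique)
  fstrand <- features$strand
  rstrand <- if (strandedness == "sense") {
    reads$strand
  } else {
    ifelse(reads$strand == "+", "-", "+")
  }
  libs <- reads |>
    distinct(.data$lib, .data$condition, .data$replicate) |>
    arrange(.data$condition, .data$replicate)
  mat <- matrix(0L,
    nrow = nrow(features), ncol = nrow(libs),
    dimnames = list(features[[id_col]], libs$lib)
  )
  # overlap widths read x feature via block ranges
  gr_reads <- reads_to_block_granges(reads)
  gr_feat <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start + 1L, features$end),
    fstrand
  )
  hits <- GenomicRanges::findOverlaps(gr_reads, gr_feat,
    ignore.strand = TRUE
  )
  if (length(hits) > 0) {
    ridx <- S4Vectors::mcols(gr_reads)$idx[S4Vectors::queryHits(hits)]
    fidx <- S4Vectors::subjectHits(hits)
    ok_strand <- rstrand[ridx] == fstrand[fidx]
    df <- tibble(ridx = ridx, fidx = fidx)[ok_strand, ] |>
      group_by(.data$ridx, .data$fidx) |>
      summarise(.groups = "drop") |>
      mutate(ov = block_overlap_width(
        reads$start[.data$ridx], reads$end[.data$ridx],
        reads$gap_start[.data$ridx], reads$gap_end[.data$ridx],
        features$start[.data$fidx], features$end[.data$fidx]
      )) |>
      filter(.data$ov >= min_overlap)
    if (mode == "gene") {
      multi <- df |>
        count(.data$ridx) |>
        filter(.data$n > 1) |>
        pull(.data$ridx)
      df <- df |> filter(!(.data$ridx %in% multi))
    }
    if (nrow(df) > 0) {
      tal <- df |>
        mutate(lib = reads$lib[.data$ridx]) |>
        count(.data$fidx, .data$lib)
      mat[cbind(tal$fidx, match(tal$lib, libs$lib))] <- tal$n
    }
  }
  structure(list(counts = mat, samples = libs), class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf(
    "<counts_table> %d features x %d libraries (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(x$samples$lib, collapse = ", ")
  ))
  invisible(x)
}

# Median-of-ratios size factors (geometric-mean reference over features with
# all-positive counts).
size_factors <- function(counts) {
  logc <- log(counts)
  ok <- apply(is.finite(logc), 1, all)
  if (sum(ok) == 0) abort("no feature with positive counts in all libraries")
  ref <- rowMeans(logc[ok, , drop = FALSE])
  sf <- apply(logc[ok, , drop = FALSE], 2, function(x) exp(median(x - ref)))
  # stabilized so the median factor is 1: rescaling a single library by c
  # then moves only that library's factor (by exactly c)
  sf / median(sf)
}

# Per-feature method-of-moments NB dispersion pooled through a parametric
# mean-dispersion trend alpha(mu) = a0 + a1/mu (least squares on the raw
# per-feature moment estimates), floored.
trend_dispersion <- function(norm, group, floor = 1e-8) {
  g <- split(seq_len(ncol(norm)), group)
  means <- vapply(g, function(j) rowMeans(norm[, j, drop = FALSE]),
    numeric(nrow(norm))
  )
  vars <- vapply(g, function(j) apply(norm[, j, drop = FALSE], 1, var),
    numeric(nrow(norm))
  )
  ns <- lengths(g)
  vpool <- as.numeric(vars %*% (ns - 1)) / sum(ns - 1)
  mpool <- as.numeric(means %*% ns) / sum(ns)
  mom <- (vpool - mpool) / mpool^2
  ok <- is.finite(mom) & mpool > 0
  disp <- if (sum(ok) >= 10) {
    X <- cbind(1, 1 / mpool[ok])
    co <- tryCatch(qr.solve(X, mom[ok]),
      error = function(e) c(mean(mom[ok]), 0)
    )
    co[1] + co[2] / mpool
  } else {
    rep(mean(mom[ok]), length(mom))
  }
  pmax(disp, floor)
}

de_prefilter_thresholds <- function(mode, chx) {
  switch(mode,
    gene = if (chx) 80L else 200L,
    intron = if (chx) 40L else 110L,
    ribo = 10L,
    abort(sprintf("unknown mode '%s'", mode))
  )
}

de_call_thresholds <- function(mode) {
  if (mode == "intron") {
    list(alpha = 0.05, lfc = 0.5)
  } else {
    list(alpha = 0.01, lfc = 1)
  }
}

#' Differential expression: NB Wald test with count prefilter
#'
#' Features below the mode-specific total-count prefilter (genes: < 200
#' across all samples, or < 80 for CHX-treated designs; introns: < 110 /
#' < 40; ribosome profiling genes: < 10) are flagged excluded. Surviving
#' features get median-of-ratios normalization, a negative-binomial Wald
#' test of the condition effect (method-of-moments dispersion pooled through
#' a parametric mean-dispersion trend, floored at 1e-8), and BH adjustment.
#' Up/down calls use adjusted p < 0.05 with |log2FC| > 0.5 for introns and
#' adjusted p < 0.01 with |log2FC| > 1 for genes.
#'
#' @param counts A [count_features()] result (or list with `counts` matrix
#'   and `samples` tibble).
#' @param mode `"gene"`, `"intron"` or `"ribo"`.
#' @param chx Is this the CHX-treated design? Affects the prefilter only;
#'   treated and untreated libraries are analysed as separate designs.
#' @param reference Reference condition (default: first level); log2FC is
#'   the other condition over the reference.
#' @return An object of class `nb_de`: tibble `results` with `feature_id`,
#'   `base_mean`, `log2fc`, `p`, `padj`, `excluded`, `up`, `down`; plus
#'   `size_factors` and the thresholds used.
#' @export
differential <- function(counts, mode = c("gene", "intron", "ribo"),
                         chx = FALSE, reference = NULL) {
  mode <- match.arg(mode)
  mat <- counts$counts
  samples <- counts$samples
  conds <- unique(samples$condition)
  if (length(conds) != 2) abort("exactly two conditions required")
  reference <- reference %||% conds[1]
  other <- setdiff(conds, reference)
  if (any(table(samples$condition) < 2)) {
    abort("at least two replicates per condition are required")
  }
  prefilter <- de_prefilter_thresholds(mode, chx)
  call_thr <- de_call_thresholds(mode)

  excluded <- rowSums(mat) < prefilter
  sf <- size_factors(mat[, , drop = FALSE])
  norm <- sweep(mat, 2, sf, "/")
  tested <- which(!excluded)
  res <- tibble(
    feature_id = rownames(mat),
    base_mean = rowMeans(norm),
    log2fc = NA_real_, p = NA_real_, padj = NA_real_,
    excluded = excluded
  )
  if (length(tested) > 0) {
    sub <- norm[tested, , drop = FALSE]
    g_ref <- samples$condition == reference
    disp <- trend_dispersion(sub, samples$condition)
    m1 <- rowMeans(sub[, g_ref, drop = FALSE])
    m2 <- rowMeans(sub[, !g_ref, drop = FALSE])
    n1 <- sum(g_ref)
    n2 <- sum(!g_ref)
    lfc <- ifelse(m1 > 0 & m2 > 0,
      log2(m2 / m1),
      log2((m2 + 0.5) / (m1 + 0.5))
    )
    se2 <- (1 / log(2)^2) * (
      (m1 + disp * m1^2) / (n1 * pmax(m1, 0.5)^2) +
        (m2 + disp * m2^2) / (n2 * pmax(m2, 0.5)^2)
    )
    z <- lfc / sqrt(se2)
    p <- 2 * pnorm(-abs(z))
    res$log2fc[tested] <- lfc
    res$p[tested] <- p
    res$padj[tested] <- p.adjust(p, method = "BH")
  }
  res <- res |>
    mutate(
      up = !.data$excluded & !is.na(.data$padj) &
        .data$padj < call_thr$alpha & .data$log2fc > call_thr$lfc,
      down = !.data$excluded & !is.na(.data$padj) &
        .data$padj < call_thr$alpha & .data$log2fc < -call_thr$lfc
    )
  structure(
    list(
      results = res, size_factors = sf, mode = mode, chx = chx,
      reference = reference, contrast = other,
      alpha = call_thr$alpha, lfc_threshold = call_thr$lfc,
      prefilter = prefilter
    ),
    class = "nb_de"
  )
}

#' @export
print.nb_de <- function(x, ...) {
  cat(sprintf(
    "<nb_de> %s-level %s vs %s: %d features (%d excluded), %d up, %d down\n",
    x$mode, x$contrast, x$reference, nrow(x$results),
    sum(x$results$excluded), sum(x$results$up), sum(x$results$down)
  ))
  invisible(x)
}

#' Select misspliced introns: up-regulated introns in non-up genes
#'
#' An intron is selected iff its adjusted p-value is below the intron
#' threshold (0.05) with log2FC > 0.5, and its host gene's log2FC is
#' negative (down-regulated transcripts only, excluding transcription-
#' activation effects). Introns whose host gene has no usable result are
#' dropped with a warning.
#'
#' @param intron_de,gene_de [differential()] results for introns and genes.
#' @param intron_gene Tibble mapping `intron_id` to `gene_id`.
#' @return The intron result tibble with `gene_log2fc` and the selection
#'   flag `misspliced`; selected rows have `misspliced = TRUE`.
#' @export
select_misspliced <- function(intron_de, gene_de, intron_gene) {
  ires <- intron_de$results
  gres <- gene_de$results
  map <- intron_gene$gene_id[match(ires$feature_id, intron_gene$intron_id)]
  glfc <- gres$log2fc[match(map, gres$feature_id)]
  no_gene <- is.na(map) | !(map %in% gres$feature_id)
  if (any(no_gene)) {
    warn(sprintf(
      "%d intron(s) without a host-gene result were excluded",
      sum(no_gene)
    ))
  }
  ires |>
    mutate(
      gene_id = map,
      gene_log2fc = glfc,
      misspliced = !.data$excluded & !is.na(.data$padj) &
        .data$padj < intron_de$alpha &
        .data$log2fc > intron_de$lfc_threshold &
        !is.na(glfc) & glfc < 0
    )
}

#' Fraction of target introns that are misspliced
#'
#' @param misspliced Character vector of misspliced intron ids.
#' @param targets Character vector of target intron ids (introns with a
#'   reproducible CLIP peak at their 5'SS).
#' @return Percent: `100 * |misspliced intersect targets| / |targets|`.
#' @export
target_fraction <- function(misspliced, targets) {
  if (length(targets) == 0) abort("target set is empty")
  100 * length(intersect(misspliced, targets)) / length(targets)
}
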