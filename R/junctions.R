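# Donor-overlapping read classification, per-donor spliced/unspliced ratios,
# and cryptic (novel) splice-site detection from junction reads.

#' Classify donor-overlapping reads as spliced or unspliced
#'
#' A read is *spliced* for a donor when it carries an alignment gap whose 5'
#' edge coincides exactly with the donor and whose 3' edge matches the
#' acceptor of the same intron (i.e. the gap equals the annotated intron).
#' A read is *unspliced* when it is contiguous and spans the exon-intron
#' boundary with at least `k` nt aligned on each side. All other
#' donor-overlapping reads are ignored, so the three outcomes partition the
#' reads.
#'
#' @param reads Read tibble.
#' @param intron One-row tibble (or list) with `chrom`, `strand`, `start`,
#'   `end` describing the annotated intron whose donor is interrogated.
#' @param k Minimum overhang (nt) on each side of the boundary for the
#'   unspliced call (default 5).
#' @return A list with `spliced` and `unspliced` counts and `class`, the
#'   per-read factor (`spliced`/`unspliced`/`ignored`).
#' @export
classify_donor_reads <- function(reads, intron, k = 5L) {
  reads <- check_read_tbl(reads)
  if (is.null(intron$chrom) || is.null(intron$start)) {
    abort("intron must carry chrom/strand/start/end")
  }
  d <- if (intron$strand == "+") intron$start else intron$end - 1L
  on_chrom <- reads$chrom == intron$chrom & reads$strand == intron$strand
  spliced <- on_chrom &
    !is.na(reads$gap_start) &
    reads$gap_start == intron$start &
    reads$gap_end == intron$end
  # contiguous and >= k nt on both the exonic and the intronic side of the
  # boundary: for a + donor at d, covered positions d-k .. d+k-1
  if (intron$strand == "+") {
    lo <- d - k
    hi <- d + k
  } else {
    lo <- d - k + 1L
    hi <- d + k + 1L
  }
  unspliced <- on_chrom & is.na(reads$gap_start) &
    reads$start <= lo & reads$end >= hi
  cls <- rep("ignored", nrow(reads))
  cls[unspliced] <- "unspliced"
  cls[spliced] <- "spliced"
  list(
    spliced = sum(spliced), unspliced = sum(unspliced),
    class = factor(cls, levels = c("spliced", "unspliced", "ignored"))
  )
}

#' Per-donor spliced/unspliced ratio table with filters
#'
#' For every donor of an intron longer than `min_intron_length`, counts
#' spliced and unspliced reads (summed over all samples) and applies the two
#' selection filters: the +/-`region_flank` nt window around the donor must
#' hold at least `region_min` reads in total over all samples, and both the
#' spliced and the unspliced count must exceed `count_min`. Surviving donors
#' carry `log2fc = log2(spliced/unspliced)`.
#'
#' @param reads Read tibble over all samples.
#' @param introns Intron tibble (from [extract_introns()] or the expressed
#'   donor set) with `chrom`, `strand`, `start`, `end`, `donor`, `length`.
#' @param min_intron_length Introns at or below this length are excluded
#'   (default 1000 nt).
#' @param region_flank,region_min The region filter: +/-100 bp and >= 50
#'   reads by default. All reads overlapping the window are counted.
#' @param count_min Both spliced and unspliced counts must be strictly
#'   greater than this (default 10).
#' @param k Unspliced overhang passed to [classify_donor_reads()].
#' @return A tibble with one row per eligible donor: counts, filter flags
#'   (`pass_length`, `pass_region`, `pass_counts`, `kept`) and `log2fc`
#'   (NA when a count is zero).
#' @export
junction_ratio_table <- function(reads, introns, min_intron_length = 1000L,
                                 region_flank = 100L, region_min = 50L,
                                 count_min = 10L, k = 5L) {
  reads <- check_read_tbl(reads)
  rows <- purrr::map(seq_len(nrow(introns)), function(i) {
    intr <- introns[i, ]
    cl <- classify_donor_reads(reads, intr, k = k)
    d <- intr$donor
    win_lo <- d - region_flank
    win_hi <- d + region_flank + 1L
    region_reads <- sum(
      reads$chrom == intr$chrom &
        reads$start < win_hi & reads$end > win_lo
    )
    tibble(
      intron_id = intr$intron_id %||% sprintf(
        "%s:%d-%d:%s", intr$chrom, intr$start, intr$end, intr$strand
      ),
      chrom = intr$chrom, strand = intr$strand, donor = d,
      intron_length = intr$length,
      spliced = cl$spliced, unspliced = cl$unspliced,
      region_reads = region_reads
    )
  }) |> bind_rows()
  rows |>
    mutate(
      pass_length = .data$intron_length > min_intron_length,
      pass_region = .data$region_reads >= region_min,
      pass_counts = .data$spliced > count_min & .data$unspliced > count_min,
      kept = .data$pass_length & .data$pass_region & .data$pass_counts,
      log2fc = ifelse(.data$spliced > 0 & .data$unspliced > 0,
        log2(.data$spliced / .data$unspliced), NA_real_
      )
    )
}

# Junction (gap) counts per unique gap, per condition, pooled over replicates.
gap_counts_by_condition <- function(reads) {
  reads |>
    filter(!is.na(.data$gap_start)) |>
    count(
      .data$chrom, .data$strand, .data$gap_start, .data$gap_end,
      .data$condition,
      name = "reads"
    )
}

#' Detect cryptic (novel) splice sites and retained introns
#'
#' Compares two conditions. For each annotated intron, every observed
#' junction gap sharing the intron's acceptor edge but not its donor edge
#' defines a novel-5'SS candidate (symmetrically for novel 3'SSs); the
#' retained-intron event uses unspliced vs spliced donor-overlapping reads.
#' Inclusion level per condition is novel/(novel + annotated) junction reads
#' (unspliced/(unspliced + spliced) for retention). Events are kept when the
#' total read count across samples exceeds `min_total`, the inclusion-level
#' difference exceeds `min_dincl`, and the Benjamini-Hochberg FDR of a
#' per-event Fisher 2x2 test (event vs annotated counts x condition,
#' replicates pooled) is below `fdr`.
#'
#' @param reads Read tibble with a `condition` column (exactly two
#'   conditions required).
#' @param introns Intron tibble.
#' @param min_total Events need strictly more than this many reads summed
#'   over all samples (default 30).
#' @param min_dincl Minimum absolute inclusion-level difference (default
#'   0.1).
#' @param fdr BH-adjusted p-value cutoff (default 0.01).
#' @param k Overhang for the retention classification.
#' @return A tibble of events: `event_class` (`novel_5ss`, `novel_3ss`,
#'   `retained_intron`), per-condition event/annotated counts and inclusion
#'   levels, `dincl` (condition 2 minus condition 1), `p`, `padj`, and
#'   `kept`.
#' @export
detect_novel_donors <- function(reads, introns, min_total = 30L,
                                min_dincl = 0.1, fdr = 0.01, k = 5L) {
  reads <- check_read_tbl(reads)
  conds <- sort(unique(reads$condition))
  if (length(conds) != 2) {
    abort(sprintf(
      "exactly two conditions required, got: %s", paste(conds, collapse = ", ")
    ))
  }
  gaps <- gap_counts_by_condition(reads)

  events <- purrr::map(seq_len(nrow(introns)), function(i) {
    intr <- introns[i, ]
    ig <- gaps |>
      filter(.data$chrom == intr$chrom, .data$strand == intr$strand)
    ann <- ig |>
      filter(.data$gap_start == intr$start, .data$gap_end == intr$end)
    ann_n <- setNames(rep(0L, 2), conds)
    ann_n[ann$condition] <- ann$reads
    id <- intr$intron_id %||% sprintf(
      "%s:%d-%d:%s", intr$chrom, intr$start, intr$end, intr$strand
    )

    # novel 5'SS: same acceptor edge, different donor edge
    acc_is_end <- intr$strand == "+"
    n5 <- if (acc_is_end) {
      ig |> filter(.data$gap_end == intr$end, .data$gap_start != intr$start)
    } else {
      ig |> filter(.data$gap_start == intr$start, .data$gap_end != intr$end)
    }
    n3 <- if (acc_is_end) {
      ig |> filter(.data$gap_start == intr$start, .data$gap_end != intr$end)
    } else {
      ig |> filter(.data$gap_end == intr$end, .data$gap_start != intr$start)
    }
    novel_rows <- function(cand, class) {
      if (nrow(cand) == 0) {
        return(NULL)
      }
      cand |>
        group_by(.data$gap_start, .data$gap_end) |>
        summarise(
          e1 = sum(.data$reads[.data$condition == conds[1]]),
          e2 = sum(.data$reads[.data$condition == conds[2]]),
          .groups = "drop"
        ) |>
        mutate(
          event_class = class, intron_id = id,
          chrom = intr$chrom, strand = intr$strand,
          site = ifelse(rep(class == "novel_5ss", n()),
            ifelse(acc_is_end, .data$gap_start, .data$gap_end - 1L),
            ifelse(acc_is_end, .data$gap_end - 1L, .data$gap_start)
          ),
          a1 = unname(ann_n[1]), a2 = unname(ann_n[2])
        )
    }
    ri <- {
      r1 <- classify_donor_reads(
        reads[reads$condition == conds[1], ], intr, k = k
      )
      r2 <- classify_donor_reads(
        reads[reads$condition == conds[2], ], intr, k = k
      )
      tibble(
        gap_start = intr$start, gap_end = intr$end,
        e1 = r1$unspliced, e2 = r2$unspliced,
        event_class = "retained_intron", intron_id = id,
        chrom = intr$chrom, strand = intr$strand,
        site = NA_integer_, a1 = r1$spliced, a2 = r2$spliced
      )
    }
    bind_rows(novel_rows(n5, "novel_5ss"), novel_rows(n3, "novel_3ss"), ri)
  }) |> bind_rows()

  if (nrow(events) == 0) {
    return(tibble())
  }
  events <- events |>
    mutate(
      incl1 = ifelse(.data$e1 + .data$a1 > 0,
        .data$e1 / (.data$e1 + .data$a1), NA_real_
      ),
      incl2 = ifelse(.data$e2 + .data$a2 > 0,
        .data$e2 / (.data$e2 + .data$a2), NA_real_
      ),
      dincl = .data$incl2 - .data$incl1,
      total_reads = .data$e1 + .data$e2 + .data$a1 + .data$a2
    )
  events$p <- vapply(seq_len(nrow(events)), function(i) {
    m <- matrix(
      c(events$e1[i], events$a1[i], events$e2[i], events$a2[i]),
      nrow = 2
    )
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      return(1)
    }
    fisher.test(m)$p.value
  }, numeric(1))
  events |>
    mutate(
      padj = p.adjust(.data$p, method = "BH"),
      kept = .data$total_reads > min_total &
        !is.na(.data$dincl) & abs(.data$dincl) > min_dincl &
        .data$padj < fdr
    ) |>
    rename(condition1 = "e1", condition2 = "e2") |>
    select(
      "event_class", "intron_id", "chrom", "strand", "site",
      "gap_start", "gap_end",
      event_reads_1 = "condition1", event_reads_2 = "condition2",
      annotated_reads_1 = "a1", annotated_reads_2 = "a2",
      "incl1", "incl2", "dincl", "total_reads", "p", "padj", "kept"
    )
}

#' Write novel donor events as BED6
#'
#' @param events Result of [detect_novel_donors()]; only kept novel-5'SS
#'   events with a site coordinate are written.
#' @param path Output path.
#' @export
write_novel_donor_bed <- function(events, path) {
  ev <- events |>
    filter(.data$kept, .data$event_class == "novel_5ss", !is.na(.data$site))
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t0\t%s",
    ev$chrom, ev$site, ev$site + 1L, ev$intron_id, ev$strand
  ), path)
  invisible(path)
}
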