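# Candidate peak calling (threshold run-length caller), replicate
# reproducibility filtering, target-intron assignment, and overlap sets.

# Per-base coverage track for one strand of a chromosome as a tibble.
coverage_track <- function(reads, chrom, strand) {
  reads <- check_read_tbl(reads)
  r <- reads |>
    filter(.data$chrom == !!chrom, .data$strand == !!strand, .data$unique)
  if (nrow(r) == 0) {
    return(tibble(pos = integer(), cov = integer()))
  }
  gr <- reads_to_block_granges(r)
  cov <- GenomicRanges::coverage(gr)[[chrom]]
  tibble(pos = seq_len(length(cov)) - 1L, cov = as.integer(cov))
}

#' Call candidate peaks from a coverage track
#'
#' Maximal runs of per-base coverage at or above `min_height` are reported
#' as candidate peaks; the peak center is the position of maximum coverage
#' within the run (leftmost on ties). The default threshold is the 90th
#' percentile of the nonzero coverage values.
#'
#' @param track Tibble with `pos` (0-based) and `cov`, e.g. from the
#'   per-strand coverage of a library's alignments.
#' @param chrom,strand Labels attached to the candidates.
#' @param min_height Coverage threshold; `NULL` uses the 90th percentile of
#'   nonzero coverage.
#' @param min_width Minimum candidate width in nt (default 1).
#' @return A tibble of candidates: `chrom`, `strand`, `start`, `end`
#'   (0-based half-open), `center`, `width`, `height` (maximum coverage).
#' @export
call_candidate_peaks <- function(track, chrom = "chr", strand = "+",
                                 min_height = NULL, min_width = 1L) {
  empty <- tibble(
    chrom = character(), strand = character(), start = integer(),
    end = integer(), center = integer(), width = integer(),
    height = integer()
  )
  if (nrow(track) == 0 || all(track$cov == 0)) {
    return(empty)
  }
  if (is.null(min_height)) {
    min_height <- as.numeric(quantile(track$cov[track$cov > 0], 0.9))
  }
  above <- track$cov >= min_height & track$cov > 0
  if (!any(above)) {
    return(empty)
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  rows <- purrr::map(keep, function(i) {
    idx <- starts[i]:ends[i]
    pos <- track$pos[idx]
    cov <- track$cov[idx]
    tibble(
      chrom = chrom, strand = strand,
      start = pos[1], end = pos[length(pos)] + 1L,
      center = pos[which.max(cov)],
      width = length(pos), height = max(cov)
    )
  }) |> bind_rows()
  rows |> filter(.data$width >= min_width)
}

# Reads overlapping [center - half, center + half) on the candidate's strand.
window_read_count <- function(reads, chrom, strand, center, half = 25L) {
  sum(
    reads$chrom == chrom & reads$strand == strand &
      reads$start < center + half & reads$end > center - half
  )
}

#' Replicate-reproducibility filter for candidate peaks
#'
#' A candidate is kept iff (a) it overlaps a candidate of the other
#' replicate by at least 1 bp, (b) its width is strictly greater than
#' `min_width` nt, and (c) the combined replicate read count within the
#' `window`-bp window around its own center is strictly greater than
#' `min_reads`. Kept overlapping pairs are merged and reported as the union
#' interval.
#'
#' @param cand1,cand2 Candidate tibbles from [call_candidate_peaks()] for
#'   the two replicates.
#' @param reads1,reads2 Read tibbles of the two replicates.
#' @param min_width Width threshold, exclusive (default 35 nt).
#' @param min_reads Window read-count threshold, exclusive (default 5).
#' @param window Window width around the center (default 50 bp, i.e.
#'   center +/- 25).
#' @return A tibble of kept peaks (union intervals) with `window_reads`,
#'   the combined count at the merged peak's maximum-supported center.
#' @export
filter_reproducible <- function(cand1, cand2, reads1, reads2,
                                min_width = 35L, min_reads = 5L,
                                window = 50L) {
  reads1 <- check_read_tbl(reads1, "reads1")
  reads2 <- check_read_tbl(reads2, "reads2")
  half <- as.integer(window / 2)
  pass <- function(cand, other) {
    if (nrow(cand) == 0) {
      return(cand[0, ])
    }
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      ov <- any(
        other$chrom == cand$chrom[i] & other$strand == cand$strand[i] &
          other$start < cand$end[i] & other$end > cand$start[i]
      )
      if (!ov) {
        return(FALSE)
      }
      if (cand$width[i] <= min_width) {
        return(FALSE)
      }
      n <- window_read_count(
        reads1, cand$chrom[i], cand$strand[i], cand$center[i], half
      ) + window_read_count(
        reads2, cand$chrom[i], cand$strand[i], cand$center[i], half
      )
      n > min_reads
    }, logical(1))
    cand[keep, , drop = FALSE]
  }
  kept <- bind_rows(pass(cand1, cand2), pass(cand2, cand1))
  if (nrow(kept) == 0) {
    return(kept |> mutate(window_reads = integer()))
  }
  # merge overlapping kept peaks into union intervals
  gr <- GenomicRanges::GRanges(
    kept$chrom, IRanges::IRanges(kept$start + 1L, kept$end), kept$strand
  )
  red <- GenomicRanges::reduce(gr)
  merged <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    strand = as.character(GenomicRanges::strand(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  ) |>
    mutate(width = .data$end - .data$start)
  hits <- GenomicRanges::findOverlaps(red, gr)
  merged$center <- vapply(seq_len(nrow(merged)), function(i) {
    members <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    centers <- kept$center[members]
    heights <- kept$height[members]
    centers[order(-heights, centers)][1]
  }, integer(1))
  merged$window_reads <- vapply(seq_len(nrow(merged)), function(i) {
    window_read_count(
      reads1, merged$chrom[i], merged$strand[i], merged$center[i], half
    ) + window_read_count(
      reads2, merged$chrom[i], merged$strand[i], merged$center[i], half
    )
  }, integer(1))
  merged
}

#' Assign kept peaks to target introns
#'
#' An intron is a target iff some kept peak interval intersects the window
#' `[donor + window[1], donor + window[2])` in transcript orientation
#' (default donor - 100 to donor + 50, matching the upstream-shifted CLIP
#' signal geometry with its intronic tail).
#'
#' @param peaks Kept peak tibble.
#' @param donors Donor tibble (`chrom`, `strand`, `donor`, `intron_id`).
#' @param window Integer length-2 window in transcript-oriented offsets.
#' @return A tibble of target introns (subset of `donors` rows) of class
#'   `target_set`, with the supporting peak count.
#' @export
assign_targets <- function(peaks, donors, window = c(-100L, 50L)) {
  hit <- vapply(seq_len(nrow(donors)), function(i) {
    d <- donors$donor[i]
    if (donors$strand[i] == "+") {
      lo <- d + window[1]
      hi <- d + window[2]
    } else {
      lo <- d - window[2] + 1L
      hi <- d - window[1] + 1L
    }
    sum(
      peaks$chrom == donors$chrom[i] & peaks$strand == donors$strand[i] &
        peaks$start < hi & peaks$end > lo
    )
  }, numeric(1))
  out <- donors |> mutate(n_peaks = as.integer(hit)) |> filter(hit > 0)
  class(out) <- c("target_set", class(out))
  out
}

#' Overlap statistics of intron sets
#'
#' Pairwise intersection counts and Jaccard indices, and inclusion-
#' exclusion counts for up to three sets over a shared universe.
#'
#' @param sets Named list of character vectors (e.g. intron ids).
#' @param universe Character vector every set must be contained in.
#' @return A list with `sizes`, `pairwise` (tibble set1/set2/intersection/
#'   union/jaccard) and `exclusive` (tibble region/count over the
#'   inclusion-exclusion regions).
#' @export
overlap_sets <- function(sets, universe = Reduce(union, sets)) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("sets must be named")
  }
  for (nm in names(sets)) {
    out <- setdiff(sets[[nm]], universe)
    if (length(out) > 0) {
      abort(sprintf(
        "set '%s' contains %d element(s) outside the universe",
        nm, length(out)
      ))
    }
  }
  nms <- names(sets)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(p) {
    a <- sets[[p[1]]]
    b <- sets[[p[2]]]
    tibble(
      set1 = p[1], set2 = p[2],
      intersection = length(intersect(a, b)),
      union = length(union(a, b)),
      jaccard = if (length(union(a, b)) == 0) {
        NA_real_
      } else {
        length(intersect(a, b)) / length(union(a, b))
      }
    )
  }) |> bind_rows()
  membership <- vapply(sets, function(s) universe %in% s,
    logical(length(universe))
  )
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  key <- apply(membership, 1, function(m) {
    paste(ifelse(m, nms, sprintf("not_%s", nms)), collapse = "&")
  })
  exclusive <- tibble(region = key) |>
    count(.data$region, name = "count")
  list(
    sizes = tibble(set = nms, size = lengths(sets)),
    pairwise = pairwise, exclusive = exclusive
  )
}

#' Write peaks as BED6
#'
#' Score is the combined window read count when present.
#'
#' @param peaks Peak tibble.
#' @param path Output path.
#' @export
write_peak_bed <- function(peaks, path) {
  score <- if ("window_reads" %in% names(peaks)) peaks$window_reads else 0L
  writeLines(sprintf(
    "%s\t%d\t%d\tpeak%d\t%d\t%s",
    peaks$chrom, peaks$start, peaks$end, seq_len(nrow(peaks)),
    score, peaks$strand
  ), path)
  invisible(path)
}
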