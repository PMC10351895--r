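track_from <- function(cov) tibble::tibble(pos = seq_along(cov) - 1L, cov = cov)

test_that("a rectangular bump yields one candidate of its full width", {
  cov <- c(rep(0L, 10), rep(10L, 50), rep(0L, 10))
  cand <- call_candidate_peaks(track_from(cov), min_height = 5)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$width, 50L)
  expect_equal(cand$start, 10L)
  expect_equal(cand$center, 10L) # leftmost maximum on a plateau
})

test_that("a flat zero track yields no candidates", {
  expect_equal(nrow(call_candidate_peaks(track_from(rep(0L, 100)))), 0L)
  expect_equal(
    nrow(call_candidate_peaks(tibble::tibble(pos = integer(), cov = integer()))),
    0L
  )
})

test_that("candidates equal a brute-force run-length scan on random tracks", {
  set.seed(31)
  for (rep in 1:5) {
    cov <- as.integer(pmax(0, round(rnorm(300, 2, 3))))
    thr <- 4
    cand <- call_candidate_peaks(track_from(cov), min_height = thr)
    # oracle: position-by-position scan
    above <- which(cov >= thr)
    runs <- split(above, cumsum(c(1, diff(above) != 1)))
    expect_equal(nrow(cand), length(runs))
    for (i in seq_along(runs)) {
      r <- runs[[i]]
      expect_equal(cand$start[i], r[1] - 1L)
      expect_equal(cand$end[i], r[length(r)])
      expect_equal(cand$center[i], r[which.max(cov[r])] - 1L)
    }
  }
})

test_that("raising the threshold keeps candidates within lower-threshold runs", {
  set.seed(32)
  cov <- as.integer(pmax(0, round(rnorm(400, 3, 4))))
  lo <- call_candidate_peaks(track_from(cov), min_height = 3)
  hi <- call_candidate_peaks(track_from(cov), min_height = 6)
  for (i in seq_len(nrow(hi))) {
    expect_true(any(hi$start[i] >= lo$start & hi$end[i] <= lo$end))
  }
})

mk_peak_reads <- function(center, n, chrom = "c1", strand = "+", lib = "l") {
  purrr::map(seq_len(n), ~ mk_read(
    chrom, strand, center - 15L, center + 15L, lib = lib
  )) |> dplyr::bind_rows()
}

test_that("reproducibility filter applies width, overlap and read rules strictly", {
  cand <- function(start, width) tibble::tibble(
    chrom = "c1", strand = "+", start = as.integer(start),
    end = as.integer(start + width), center = as.integer(start + width %/% 2),
    width = as.integer(width), height = 10L
  )
  r1 <- mk_peak_reads(118L, 3L)
  r2 <- mk_peak_reads(118L, 3L)
  # width 35 exactly -> rejected
  kept <- filter_reproducible(cand(100, 35), cand(100, 35), r1, r2)
  expect_equal(nrow(kept), 0L)
  # width 36, 6 combined reads -> kept
  kept2 <- filter_reproducible(cand(100, 36), cand(100, 36), r1, r2)
  expect_equal(nrow(kept2), 1L)
  expect_equal(kept2$window_reads, 6L)
  # only 5 combined reads -> rejected
  kept3 <- filter_reproducible(
    cand(100, 36), cand(100, 36), r1, mk_peak_reads(118L, 2L)
  )
  expect_equal(nrow(kept3), 0L)
  # no replicate overlap -> rejected
  kept4 <- filter_reproducible(
    cand(100, 40), cand(300, 40), r1, r2
  )
  expect_equal(nrow(kept4), 0L)
  # overlapping passing pair merges to the union interval
  kept5 <- filter_reproducible(
    cand(100, 40), cand(120, 40), mk_peak_reads(120L, 4L),
    mk_peak_reads(140L, 4L)
  )
  expect_equal(nrow(kept5), 1L)
  expect_equal(kept5$start, 100L)
  expect_equal(kept5$end, 160L)
})

test_that("filter decision matches a brute-force oracle on random fixtures", {
  set.seed(33)
  for (rep in 1:3) {
    n1 <- 30L
    starts1 <- sample(0:2000, n1)
    w1 <- sample(20:60, n1, replace = TRUE)
    cand1 <- tibble::tibble(
      chrom = "c1", strand = "+", start = starts1, end = starts1 + w1,
      center = starts1 + w1 %/% 2L, width = w1, height = 5L
    )
    starts2 <- sample(0:2000, n1)
    cand2 <- tibble::tibble(
      chrom = "c1", strand = "+", start = starts2, end = starts2 + w1,
      center = starts2 + w1 %/% 2L, width = w1, height = 5L
    )
    reads <- purrr::map(sample(0:2000, 400, replace = TRUE), ~ mk_read(
      "c1", "+", .x, .x + 30L
    )) |> dplyr::bind_rows()
    kept <- filter_reproducible(cand1, cand2, reads, reads)
    # oracle: recompute kept candidates then union intervals
    oracle_keep <- function(ca, cb) {
      keep <- logical(nrow(ca))
      for (i in seq_len(nrow(ca))) {
        ov <- any(mapply(
          oracle_intersects, ca$start[i], ca$end[i], cb$start, cb$end
        ))
        wd <- ca$width[i] > 35
        nr <- 2 * sum(
          reads$start < ca$center[i] + 25 & reads$end > ca$center[i] - 25
        )
        keep[i] <- ov && wd && nr > 5
      }
      ca[keep, ]
    }
    ok <- dplyr::bind_rows(oracle_keep(cand1, cand2), oracle_keep(cand2, cand1))
    if (nrow(ok) == 0) {
      expect_equal(nrow(kept), 0L)
    } else {
      # every oracle-kept candidate is inside a reported union interval
      inside <- vapply(seq_len(nrow(ok)), function(i) {
        any(kept$start <= ok$start[i] & kept$end >= ok$end[i])
      }, logical(1))
      expect_true(all(inside))
      # and every reported interval is a union of oracle-kept candidates
      expect_equal(sum(kept$end - kept$start >= 0), nrow(kept))
      covered <- vapply(seq_len(nrow(kept)), function(i) {
        any(ok$start < kept$end[i] & ok$end > kept$start[i])
      }, logical(1))
      expect_true(all(covered))
    }
  }
})

test_that("target assignment uses the transcript-oriented donor window", {
  donors <- tibble::tibble(
    chrom = "c1", strand = c("+", "+", "+", "-"),
    donor = c(1000L, 2000L, 3000L, 5000L),
    intron_id = c("a", "b", "c", "d")
  )
  peaks <- tibble::tibble(
    chrom = "c1", strand = c("+", "+", "+", "-"),
    start = c(995L, 2900L, 3500L, 5005L),
    end = c(1005L, 2910L, 3510L, 5090L)
  )
  # peak over donor a; peak at donor-90 for c... (2900 is donor-100 for 3000)
  ts <- assign_targets(peaks, donors, window = c(-100L, 50L))
  expect_true("a" %in% ts$intron_id)
  expect_true("c" %in% ts$intron_id) # [2900,2910) intersects [2900,3050)
  expect_false("b" %in% ts$intron_id) # 1 kb inside the intron
  # minus-strand: window is genomic [donor-49, donor+101)
  expect_true("d" %in% ts$intron_id)
  # brute-force oracle over all donors
  for (i in seq_len(nrow(donors))) {
    d <- donors$donor[i]
    if (donors$strand[i] == "+") {
      lo <- d - 100L
      hi <- d + 50L
    } else {
      lo <- d - 49L
      hi <- d + 101L
    }
    hit <- any(
      peaks$strand == donors$strand[i] &
        mapply(oracle_intersects, peaks$start, peaks$end, lo, hi)
    )
    expect_equal(donors$intron_id[i] %in% ts$intron_id, hit)
  }
})

test_that("overlap sets match brute-force set arithmetic", {
  universe <- sprintf("i%03d", 1:100)
  expect_equal(
    overlap_sets(
      list(a = universe[1:30], b = universe[1:30]), universe
    )$pairwise$jaccard, 1
  )
  expect_equal(
    overlap_sets(
      list(a = universe[1:30], b = universe[31:60]), universe
    )$pairwise$intersection, 0L
  )
  set.seed(5)
  sets <- list(
    a = sample(universe, 40), b = sample(universe, 30),
    c = sample(universe, 20)
  )
  ov <- overlap_sets(sets, universe)
  expect_equal(
    ov$pairwise$intersection[ov$pairwise$set1 == "a" & ov$pairwise$set2 == "b"],
    length(intersect(sets$a, sets$b))
  )
  triple <- ov$exclusive$count[ov$exclusive$region == "a&b&c"]
  expect_equal(
    if (length(triple) == 0) 0L else triple,
    length(Reduce(intersect, sets))
  )
  expect_equal(sum(ov$exclusive$count), length(universe))
  expect_error(
    overlap_sets(list(a = "zzz"), universe), "outside the universe"
  )
})

test_that("planted bound donors are recovered by the peak pipeline", {
  s <- shared_sim()
  clip <- simulate_clip_reads(s$cfg, s$genome)
  reps <- split(
    clip$reads[clip$reads$protein == "P1", ],
    clip$reads$replicate[clip$reads$protein == "P1"]
  )
  cands <- lapply(reps, function(r) {
    dplyr::bind_rows(lapply(c("+", "-"), function(st) {
      tr <- spliceclip:::coverage_track(r, "chrS", st)
      call_candidate_peaks(tr,
        chrom = "chrS", strand = st,
        min_height = as.numeric(quantile(tr$cov[tr$cov > 0], 0.5))
      )
    }))
  })
  kept <- filter_reproducible(cands[[1]], cands[[2]], reps[[1]], reps[[2]])
  targets <- assign_targets(kept, s$introns)
  truth <- s$truth
  weak_ids <- truth$intron_id[truth$class == "weak"]
  # every weak (always-bound) intron with expression should be recovered
  expect_gte(
    length(intersect(weak_ids, targets$intron_id)) / length(weak_ids), 0.95
  )
})
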