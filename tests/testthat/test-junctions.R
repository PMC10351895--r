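# A plus-strand intron [1000, 2000) with donor at 1000; minus-strand mirror
# [3000, 4000) with donor at 3999.
intron_p <- tibble::tibble(
  intron_id = "ip", chrom = "c1", strand = "+",
  start = 1000L, end = 2000L, donor = 1000L, length = 1000L
)
intron_m <- tibble::tibble(
  intron_id = "im", chrom = "c1", strand = "-",
  start = 3000L, end = 4000L, donor = 3999L, length = 1000L
)

test_that("gapped reads matching the intron are spliced, boundary reads unspliced", {
  reads <- dplyr::bind_rows(
    mk_read("c1", "+", 960, 2040, gap_start = 1000, gap_end = 2000), # spliced
    mk_read("c1", "+", 990, 1010), # 10 exonic + 10 intronic -> unspliced
    mk_read("c1", "+", 970, 1002), # 2 nt into the intron -> ignored (k=5)
    mk_read("c1", "+", 960, 2040, gap_start = 1000, gap_end = 1990), # wrong acceptor
    mk_read("c1", "+", 1200, 1260) # internal intronic -> ignored
  )
  cl <- classify_donor_reads(reads, intron_p, k = 5L)
  expect_equal(cl$spliced, 1L)
  expect_equal(cl$unspliced, 1L)
  expect_equal(as.character(cl$class),
    c("spliced", "unspliced", "ignored", "ignored", "ignored"))
})

test_that("classification is strand-symmetric", {
  reads <- dplyr::bind_rows(
    mk_read("c1", "-", 2960, 4040, gap_start = 3000, gap_end = 4000),
    mk_read("c1", "-", 3990, 4010), # 10 each side of the minus donor
    mk_read("c1", "-", 3998, 4030) # 2 nt intronic -> ignored
  )
  cl <- classify_donor_reads(reads, intron_m, k = 5L)
  expect_equal(cl$spliced, 1L)
  expect_equal(cl$unspliced, 1L)
  expect_equal(as.character(cl$class[3]), "ignored")
})

test_that("classification matches a brute-force interval oracle on random reads", {
  set.seed(21)
  for (intron in list(intron_p, intron_m)) {
    starts <- sample(900:2100, 300, replace = TRUE) +
      ifelse(intron$strand == "-", 2000L, 0L)
    lens <- sample(10:80, 300, replace = TRUE)
    gap <- runif(300) < 0.3
    reads <- tibble::tibble(
      qname = sprintf("r%03d", 1:300), lib = "l",
      condition = NA_character_, replicate = 1L,
      chrom = "c1", strand = intron$strand,
      start = as.integer(starts), end = as.integer(starts + lens),
      gap_start = ifelse(gap, intron$start, NA_integer_),
      gap_end = ifelse(gap, intron$end, NA_integer_),
      unique = TRUE, nm = 0L
    )
    # gapped reads must bracket the gap
    reads$start[gap] <- intron$start - sample(5:40, sum(gap), replace = TRUE)
    reads$end[gap] <- intron$end + sample(5:40, sum(gap), replace = TRUE)
    cl <- classify_donor_reads(reads, intron, k = 5L)
    expected <- vapply(seq_len(nrow(reads)), function(i) {
      oracle_classify_one(reads[i, ], intron, k = 5)
    }, character(1))
    expect_equal(as.character(cl$class), expected)
  }
})

test_that("junction table filters match the published thresholds", {
  # donor with 49 region reads -> excluded even with good counts
  mk_cov <- function(intron, n_spliced, n_unspliced, extra = 0L) {
    dplyr::bind_rows(
      purrr::map(seq_len(n_spliced), ~ mk_read(
        "c1", intron$strand, intron$start - 20L, intron$end + 20L,
        gap_start = intron$start, gap_end = intron$end
      )),
      purrr::map(seq_len(n_unspliced), ~ mk_read(
        "c1", intron$strand, intron$donor - 10L, intron$donor + 11L
      )),
      purrr::map(seq_len(extra), ~ mk_read(
        "c1", intron$strand, intron$donor - 60L, intron$donor - 30L
      ))
    )
  }
  long <- intron_p
  long$length <- 1200L
  # 20 + 20 + 9 = 49 reads in the region: region filter fails
  jt <- junction_ratio_table(mk_cov(long, 20L, 20L, 9L), long)
  expect_equal(jt$region_reads, 49L)
  expect_false(jt$pass_region)
  expect_false(jt$kept)
  # 50 reads: passes; both counts > 10; log2fc 0 when equal
  jt2 <- junction_ratio_table(mk_cov(long, 20L, 20L, 10L), long)
  expect_true(jt2$kept)
  expect_equal(jt2$log2fc, 0)
  # exactly 10 spliced fails the strict count rule
  jt3 <- junction_ratio_table(mk_cov(long, 10L, 40L, 10L), long)
  expect_false(jt3$pass_counts)
  # short intron excluded regardless of counts
  short <- intron_p
  short$length <- 900L
  jt4 <- junction_ratio_table(mk_cov(short, 40L, 40L), short)
  expect_false(jt4$pass_length)
  expect_false(jt4$kept)
  # 1000 exactly is not > 1 kb
  kb <- intron_p
  kb$length <- 1000L
  expect_false(junction_ratio_table(mk_cov(kb, 40L, 40L), kb)$pass_length)
})

test_that("estimated spliced fractions recover the planted truth", {
  cfg <- simulation_config(
    seed = 31L, n_genes = 12L, n_reads_per_library = 15000L,
    spliced_fraction = list(
      WT = c(strong = 0.9, medium = 0.5, weak = 0.1),
      KO = c(strong = 0.9, medium = 0.5, weak = 0.1)
    )
  )
  g <- generate_genome(cfg)
  clip <- simulate_clip_reads(cfg, g)
  truth <- simulation_truth(cfg)
  jt <- junction_ratio_table(
    clip$reads, truth,
    min_intron_length = 0L, region_min = 0L, count_min = 0L
  )
  n <- jt$spliced + jt$unspliced
  est <- jt$spliced / n
  p <- truth$spliced_fraction_WT[match(jt$intron_id, truth$intron_id)]
  informative <- n >= 200
  dev <- abs(est - p)[informative]
  tol <- (3 * sqrt(p * (1 - p) / n))[informative]
  expect_gte(mean(dev <= tol + 0.02), 0.95)
})

test_that("a planted cryptic donor used in one condition only is detected", {
  intron <- intron_p
  mk_j <- function(gap_start, gap_end, n, cond) {
    purrr::map(seq_len(n), ~ mk_read(
      "c1", "+", gap_start - 20L, gap_end + 20L,
      gap_start = gap_start, gap_end = gap_end, condition = cond
    )) |> dplyr::bind_rows()
  }
  reads <- dplyr::bind_rows(
    mk_j(1000L, 2000L, 100L, "WT"), # annotated junction, WT
    mk_j(1000L, 2000L, 50L, "KO"),
    mk_j(1060L, 2000L, 100L, "KO") # cryptic donor at 1060, KO only
  )
  ev <- detect_novel_donors(reads, intron)
  n5 <- ev[ev$event_class == "novel_5ss", ]
  expect_equal(nrow(n5), 1L)
  expect_equal(n5$site, 1060L)
  expect_true(n5$kept)
  expect_equal(abs(n5$dincl), 2 / 3, tolerance = 1e-9)
  # extreme case: only-KO usage gives inclusion difference 1
  reads2 <- dplyr::bind_rows(
    mk_j(1000L, 2000L, 100L, "WT"),
    mk_j(1060L, 2000L, 100L, "KO")
  )
  ev2 <- detect_novel_donors(reads2, intron)
  n52 <- ev2[ev2$event_class == "novel_5ss", ]
  expect_equal(abs(n52$dincl), 1)
  expect_true(n52$kept)
})

test_that("events with 30 or fewer reads across samples are excluded", {
  intron <- intron_p
  mk_j <- function(gap_start, n, cond) {
    purrr::map(seq_len(n), ~ mk_read(
      "c1", "+", gap_start - 20L, 2020L,
      gap_start = gap_start, gap_end = 2000L, condition = cond
    )) |> dplyr::bind_rows()
  }
  reads <- dplyr::bind_rows(
    mk_j(1000L, 15L, "WT"), mk_j(1060L, 15L, "KO")
  )
  ev <- detect_novel_donors(reads, intron)
  expect_false(any(ev$kept[ev$event_class == "novel_5ss"]))
  reads31 <- dplyr::bind_rows(
    mk_j(1000L, 15L, "WT"), mk_j(1060L, 16L, "KO")
  )
  ev31 <- detect_novel_donors(reads31, intron)
  expect_equal(
    ev31$total_reads[ev31$event_class == "novel_5ss"], 31L
  )
})

test_that("identical junction usage across conditions is not reported", {
  intron <- intron_p
  mk_j <- function(gap_start, n, cond) {
    purrr::map(seq_len(n), ~ mk_read(
      "c1", "+", gap_start - 20L, 2020L,
      gap_start = gap_start, gap_end = 2000L, condition = cond
    )) |> dplyr::bind_rows()
  }
  reads <- dplyr::bind_rows(
    mk_j(1000L, 50L, "WT"), mk_j(1060L, 50L, "WT"),
    mk_j(1000L, 50L, "KO"), mk_j(1060L, 50L, "KO")
  )
  ev <- detect_novel_donors(reads, intron)
  n5 <- ev[ev$event_class == "novel_5ss", ]
  expect_equal(n5$dincl, 0)
  expect_false(n5$kept)
})

test_that("single-condition input is rejected", {
  reads <- mk_read("c1", "+", 900, 2100,
    gap_start = 1000, gap_end = 2000, condition = "WT"
  )
  expect_error(detect_novel_donors(reads, intron_p), "two conditions")
})
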