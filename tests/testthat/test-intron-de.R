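mk_counts <- function(mat, conds = c("WT", "WT", "KO", "KO")) {
  libs <- sprintf("%s_rep%d", conds, ave(seq_along(conds), conds, FUN = seq_along))
  colnames(mat) <- libs
  structure(
    list(
      counts = mat,
      samples = tibble::tibble(
        lib = libs, condition = conds,
        replicate = as.integer(ave(seq_along(conds), conds, FUN = seq_along))
      )
    ),
    class = "counts_table"
  )
}

test_that("intron-mode counting requires a 10 nt overlap", {
  introns <- tibble::tibble(
    intron_id = "i1", chrom = "c1", strand = "+", start = 1000L, end = 2000L
  )
  reads <- dplyr::bind_rows(
    mk_read("c1", "+", 991, 1009, lib = "l1", condition = "WT"), # 9 nt in
    mk_read("c1", "+", 990, 1010, lib = "l1", condition = "WT"), # 10 nt in
    mk_read("c1", "+", 1500, 1550, lib = "l1", condition = "WT")
  )
  ct <- count_features(reads, introns, "intron")
  expect_equal(unname(ct$counts["i1", ]), 2L)
})

test_that("gapped reads contribute only block overlap, not the gap", {
  introns <- tibble::tibble(
    intron_id = "i1", chrom = "c1", strand = "+", start = 1000L, end = 2000L
  )
  # spliced read: blocks [950,1000) + [2000,2050): zero intron overlap
  reads <- mk_read("c1", "+", 950, 2050,
    gap_start = 1000, gap_end = 2000, lib = "l1", condition = "WT"
  )
  ct <- count_features(reads, introns, "intron")
  expect_equal(unname(ct$counts["i1", ]), 0L)
})

test_that("gene-mode counting drops reads overlapping two genes", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "c1", strand = "+",
    start = c(0L, 1040L), end = c(1050L, 2000L)
  )
  reads <- dplyr::bind_rows(
    mk_read("c1", "+", 1035, 1060, lib = "l1", condition = "WT"), # both genes
    mk_read("c1", "+", 100, 150, lib = "l1", condition = "WT"), # g1 only
    mk_read("c1", "-", 200, 260, lib = "l1", condition = "WT"), # wrong strand
    mk_read("c1", "+", 300, 360, lib = "l1", condition = "WT", unique = FALSE)
  )
  ct <- count_features(reads, genes, "gene")
  expect_equal(unname(ct$counts["g1", ]), 1L)
  expect_equal(unname(ct$counts["g2", ]), 0L)
})

test_that("counts equal a brute-force interval sweep on a 10-read fixture", {
  set.seed(41)
  introns <- tibble::tibble(
    intron_id = c("i1", "i2"), chrom = "c1", strand = c("+", "-"),
    start = c(100L, 500L), end = c(300L, 800L)
  )
  starts <- sample(50:850, 10)
  reads <- purrr::map(starts, ~ mk_read(
    "c1", sample(c("+", "-"), 1), .x, .x + 40L,
    lib = "l1", condition = "WT"
  )) |> dplyr::bind_rows()
  ct <- count_features(reads, introns, "intron")
  for (i in 1:2) {
    expected <- sum(vapply(seq_len(nrow(reads)), function(r) {
      ov <- min(reads$end[r], introns$end[i]) -
        max(reads$start[r], introns$start[i])
      reads$strand[r] == introns$strand[i] && ov >= 10
    }, logical(1)))
    expect_equal(unname(ct$counts[introns$intron_id[i], "l1"]), expected)
  }
})

test_that("the intron prefilter excludes totals below 110", {
  set.seed(42)
  mat <- matrix(rnbinom(40, mu = 200, size = 20), 10, 4)
  mat[1, ] <- c(27L, 27L, 27L, 28L) # total 109 -> excluded
  mat[2, ] <- c(28L, 27L, 27L, 28L) # total 110 -> tested
  rownames(mat) <- sprintf("i%02d", 1:10)
  de <- differential(mk_counts(mat), "intron")
  expect_true(de$results$excluded[1])
  expect_false(de$results$excluded[2])
  expect_true(is.na(de$results$p[1]))
})

test_that("identical counts across libraries give log2FC 0 and p near 1", {
  mat <- matrix(150L, 8, 4)
  rownames(mat) <- sprintf("i%02d", 1:8)
  de <- differential(mk_counts(mat), "intron")
  expect_true(all(de$results$log2fc == 0))
  expect_true(all(de$results$p > 0.99))
})

test_that("a single replicate per condition is rejected", {
  mat <- matrix(150L, 5, 2)
  rownames(mat) <- sprintf("i%02d", 1:5)
  expect_error(
    differential(mk_counts(mat, conds = c("WT", "KO"))),
    "two replicates"
  )
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(43)
  mat <- matrix(rnbinom(400, mu = 120, size = 10), 100, 4)
  rownames(mat) <- sprintf("i%03d", 1:100)
  de <- differential(mk_counts(mat), "intron")
  res <- de$results[!de$results$excluded, ]
  expect_true(all(res$padj >= res$p - 1e-12))
  o <- order(res$p)
  expect_true(all(diff(res$padj[o]) >= -1e-12))
  # matches the closed form
  expect_equal(res$padj, oracle_bh(res$p))
})

test_that("scaling one library rescales its size factor, fold changes exact", {
  set.seed(44)
  base <- matrix(rnbinom(400, mu = 300, size = 50), 100, 4)
  rownames(base) <- sprintf("i%03d", 1:100)
  scaled <- base
  scaled[, 1] <- base[, 1] * 3L
  de1 <- differential(mk_counts(base), "intron")
  de2 <- differential(mk_counts(scaled), "intron")
  expect_equal(
    unname(de2$size_factors[1] / de1$size_factors[1]), 3,
    tolerance = 1e-9
  )
  expect_equal(de1$results$log2fc, de2$results$log2fc, tolerance = 1e-12)
  # p-values agree within dispersion-estimate noise
  expect_equal(de1$results$p, de2$results$p, tolerance = 1e-2)
})

test_that("misspliced selection is the brute-force set intersection", {
  set.seed(45)
  n <- 60
  imat <- matrix(rnbinom(4 * n, mu = 150, size = 15), n, 4)
  # plant strong up effects in 10 introns
  imat[1:10, 3:4] <- imat[1:10, 3:4] * 4L
  rownames(imat) <- sprintf("i%03d", 1:n)
  gmat <- matrix(rnbinom(4 * n, mu = 500, size = 50), n, 4)
  rownames(gmat) <- sprintf("g%03d", 1:n)
  ide <- differential(mk_counts(imat), "intron")
  gde <- differential(mk_counts(gmat), "gene")
  map <- tibble::tibble(
    intron_id = rownames(imat), gene_id = rownames(gmat)
  )
  sel <- select_misspliced(ide, gde, map)
  expected <- ide$results$padj < 0.05 & ide$results$log2fc > 0.5 &
    !ide$results$excluded &
    gde$results$log2fc[match(map$gene_id, gde$results$feature_id)] < 0
  expected[is.na(expected)] <- FALSE
  expect_equal(sel$misspliced, expected)
  expect_gt(sum(sel$misspliced), 0)
})

test_that("an up intron in an up gene is rejected, in a down gene kept", {
  ide <- list(
    results = tibble::tibble(
      feature_id = c("i1", "i2"), base_mean = 100,
      log2fc = c(1.2, 1.2), p = 0.001, padj = 0.004,
      excluded = FALSE, up = TRUE, down = FALSE
    ),
    alpha = 0.05, lfc_threshold = 0.5
  )
  gde <- list(results = tibble::tibble(
    feature_id = c("gA", "gB"), base_mean = 500,
    log2fc = c(0.2, -0.3), p = 0.5, padj = 0.7,
    excluded = FALSE, up = FALSE, down = FALSE
  ))
  map <- tibble::tibble(intron_id = c("i1", "i2"), gene_id = c("gA", "gB"))
  sel <- select_misspliced(ide, gde, map)
  expect_false(sel$misspliced[sel$feature_id == "i1"])
  expect_true(sel$misspliced[sel$feature_id == "i2"])
})

test_that("target fraction arithmetic", {
  targets <- sprintf("t%03d", 1:500)
  expect_equal(target_fraction(targets[1:29], targets), 5.8)
  expect_equal(target_fraction(targets, targets[1:50]), 100)
  expect_equal(target_fraction("none", targets), 0)
  expect_error(target_fraction("x", character(0)), "empty")
})

test_that("gene and ribo prefilters follow their own thresholds", {
  mat <- matrix(60L, 3, 4)
  rownames(mat) <- c("a", "b", "c")
  mat[1, ] <- c(49L, 50L, 50L, 50L) # total 199
  de_gene <- differential(mk_counts(mat), "gene")
  expect_true(de_gene$results$excluded[1])
  expect_false(de_gene$results$excluded[2])
  de_chx <- differential(mk_counts(mat), "gene", chx = TRUE)
  expect_false(de_chx$results$excluded[1]) # 199 >= 80
  mat2 <- matrix(3L, 2, 4)
  rownames(mat2) <- c("a", "b")
  mat2[1, ] <- c(2L, 2L, 2L, 3L) # total 9 < 10
  de_ribo <- differential(mk_counts(mat2), "ribo")
  expect_true(de_ribo$results$excluded[1])
  expect_false(de_ribo$results$excluded[2])
})

test_that("planted weak-intron effects are recovered with high recall", {
  cfg <- simulation_config(
    seed = 51L, n_genes = 20L, n_reads_per_library = 60000L,
    planted_intron_log2fc = 1
  )
  g <- generate_genome(cfg)
  rna <- simulate_rnaseq_reads(cfg, g)
  truth <- simulation_truth(cfg)
  ann <- generate_annotation(cfg, g)
  introns <- extract_introns(ann)
  gene_ct <- count_features(rna$reads, ann$genes, "gene")
  intron_ct <- count_features(rna$reads, introns, "intron")
  gde <- differential(gene_ct, "gene", reference = "WT")
  ide <- differential(intron_ct, "intron", reference = "WT")
  sel <- select_misspliced(
    ide, gde, introns[, c("intron_id", "gene_id")]
  )
  weak <- truth$intron_id[truth$class == "weak"]
  testable <- sel$feature_id[!sel$excluded]
  recall <- length(intersect(sel$feature_id[sel$misspliced], weak)) /
    length(intersect(weak, testable))
  expect_gte(recall, 0.8)
  # specificity: no non-weak intron is called misspliced
  called_other <- setdiff(sel$feature_id[sel$misspliced], weak)
  expect_lte(length(called_other), 2L)
})

test_that("tidy and glance methods expose counts and DE summaries", {
  mat <- matrix(150L, 4, 4)
  rownames(mat) <- sprintf("i%02d", 1:4)
  ct <- mk_counts(mat)
  td <- tidy(ct)
  expect_equal(nrow(td), 16L)
  expect_true(all(c("feature_id", "lib", "condition", "count") %in% names(td)))
  de <- differential(ct, "intron")
  expect_equal(nrow(tidy(de)), 4L)
  gl <- glance(de)
  expect_equal(gl$n_features, 4L)
  expect_equal(gl$alpha, 0.05)
})
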