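# End-to-end orchestration on synthetic (or pre-aligned real) inputs.

#' Pipeline configuration
#'
#' Bundles the simulation configuration, stage toggles and all stage
#' parameters. The defaults are the analysis' published thresholds: flank
#' 200 nt, intron length > 1 kb, region total >= 50 reads, both junction
#' counts > 10, peak width > 35 nt with > 5 reads in a 50-bp window, target
#' window donor-100..+50, gene DE padj < 0.01 & |log2FC| > 1 with prefilter
#' 200 (80 CHX), intron DE padj < 0.05 & log2FC > 0.5 with prefilter 110
#' (40 CHX).
#'
#' @param sim A [simulation_config()].
#' @param stages Named logical list toggling `classify`, `junctions`,
#'   `profile`, `peaks`, `strength`, `introndiff`.
#' @param flank Coverage half-window (nt).
#' @param min_intron_length,region_min,count_min Junction-table filters.
#' @param peak_min_width,peak_min_reads,peak_window Reproducibility filters.
#' @param peak_height_quantile Candidate-calling threshold, as a quantile of
#'   the nonzero per-base coverage (default 0.5: the run-length caller then
#'   reports the full extent of enriched clusters rather than their summits,
#'   which is what the downstream width filter expects).
#' @param target_window Offsets of the peak-at-5'SS window.
#' @param novel_min_total,novel_min_dincl,novel_fdr Novel-event filters.
#' @param outdir Output directory (`NULL` = no files, metrics only).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            stages = list(
                              classify = TRUE, junctions = TRUE,
                              profile = TRUE, peaks = TRUE,
                              strength = TRUE, introndiff = TRUE
                            ),
                            flank = 200L,
                            min_intron_length = 1000L,
                            region_min = 50L, count_min = 10L,
                            peak_min_width = 35L, peak_min_reads = 5L,
                            peak_window = 50L, peak_height_quantile = 0.5,
                            target_window = c(-100L, 50L),
                            novel_min_total = 30L, novel_min_dincl = 0.1,
                            novel_fdr = 0.01,
                            outdir = NULL) {
  structure(
    list(
      sim = sim, stages = stages, flank = flank,
      min_intron_length = min_intron_length,
      region_min = region_min, count_min = count_min,
      peak_min_width = peak_min_width, peak_min_reads = peak_min_reads,
      peak_window = peak_window,
      peak_height_quantile = peak_height_quantile,
      target_window = target_window,
      novel_min_total = novel_min_total,
      novel_min_dincl = novel_min_dincl, novel_fdr = novel_fdr,
      outdir = outdir
    ),
    class = "pipeline_config"
  )
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> classify -> junctions -> profile -> peaks ->
#' strength -> introndiff, collecting a metrics list (ms-snRNA fractions,
#' metaplot peak offset, per-protein target counts, misspliced fractions,
#' overlap counts, rank-sum p for donor strength of misspliced vs unaffected
#' targets) and, when `outdir` is set, per-stage TSV/BED files plus a
#' `metrics.json`. Identical configuration and seed give byte-identical
#' metrics output.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with the stage outputs and
#'   `metrics`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  on_stage <- function(name) isTRUE(st[[name]])
  metrics <- list(seed = config$sim$seed)
  out <- list(config = config)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(outdir)) {
      utils::write.table(df, file.path(outdir, name),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }

  # simulate
  genome <- generate_genome(config$sim)
  annotation <- generate_annotation(config$sim, genome)
  truth <- simulation_truth(config$sim)
  clip <- simulate_clip_reads(config$sim, genome)
  rna <- simulate_rnaseq_reads(config$sim, genome)
  introns <- extract_introns(annotation, genome$genome)
  expr_genes <- genome$layout$genes |>
    select("gene_id", count = "expr")
  expr_tx <- annotation$transcripts |>
    mutate(abundance = expr_genes$count[
      match(.data$gene_id, expr_genes$gene_id)
    ]) |>
    select("transcript_id", "abundance")
  expressed <- select_expressed(annotation, expr_genes, expr_tx,
    genome = genome$genome
  )
  out$genome <- genome
  out$annotation <- annotation
  out$truth <- truth
  out$clip <- clip
  out$rna <- rna
  out$expressed <- expressed
  if (!is.null(outdir)) {
    Biostrings::writeXStringSet(
      c(genome$genome, genome$contaminants),
      file.path(outdir, "genome.fa")
    )
    write_gtf(annotation, file.path(outdir, "annotation.gtf"))
    emit(truth, "truth.tsv")
    seqlens <- c(
      stats::setNames(
        Biostrings::width(genome$genome), names(genome$genome)
      ),
      contaminant_lengths()
    )
    for (lb in unique(clip$reads$lib)) {
      write_sam(
        clip$reads |> filter(.data$lib == lb),
        file.path(outdir, sprintf("clip_%s.sam", lb)), seqlens
      )
    }
    for (lb in unique(rna$reads$lib)) {
      write_sam(
        rna$reads |> filter(.data$lib == lb),
        file.path(outdir, sprintf("rna_%s.sam", lb)), seqlens
      )
    }
  }
  donors <- expressed$donors

  if (on_stage("classify")) {
    lib1 <- unique(clip$reads$lib)[1]
    t1 <- clip$truth |> filter(.data$lib == lib1)
    tally <- categorize_hierarchical(
      t1$qname,
      list(
        rRNA = t1$qname[t1$ref %in% "rRNA"],
        mRNA = t1$qname[t1$origin == "gene"],
        genome = t1$qname[t1$origin == "contaminant" & !(t1$ref %in% "rRNA")]
      )
    )
    snr <- snrna_profile(
      clip$reads |> filter(.data$lib == lib1),
      contaminant_lengths()[ms_snrnas()],
      total_reads = sum(clip$reads$lib == lib1)
    )
    out$category_tally <- tally
    out$snrna <- snr
    metrics$read_categories <- as.list(
      setNames(tally$count, tally$category)
    )
    metrics$ms_snrna_fraction <- snr$ms_fraction
    metrics$snrna_shares <- as.list(
      setNames(round(snr$counts$share, 6), snr$counts$snrna)
    )
    emit(tally, "read_categories.tsv")
    emit(snr$counts, "snrna_counts.tsv")
  }

  if (on_stage("junctions")) {
    jt <- junction_ratio_table(
      clip$reads, donors,
      min_intron_length = config$min_intron_length,
      region_min = config$region_min, count_min = config$count_min
    )
    out$junction_table <- jt
    metrics$junction_donors_kept <- sum(jt$kept)
    metrics$junction_median_log2fc <- round(
      median(jt$log2fc[jt$kept], na.rm = TRUE), 6
    )
    emit(jt, "junction_ratios.tsv")
  }

  if (on_stage("profile")) {
    p1 <- config$sim$proteins[1]
    creads <- clip$reads |> filter(.data$protein == p1)
    stack <- coverage_around_sites(creads, donors, flank = config$flank)
    lib_sizes <- creads |>
      filter(.data$unique) |>
      count(.data$lib) |>
      (\(d) setNames(d$n, d$lib))()
    cpm <- normalize_cpm(stack, lib_sizes)
    mp <- metaplot(order_rows(cpm))
    out$coverage <- cpm
    out$metaplot <- mp
    metrics$metaplot_peak_offset <- peak_offset(mp)
    if (!is.null(outdir)) {
      write_profile_tsv(mp, file.path(outdir, "metaplot.tsv"))
    }
  }

  target_sets <- NULL
  if (on_stage("peaks")) {
    target_sets <- list()
    for (p in config$sim$proteins) {
      reps <- clip$reads |>
        filter(.data$protein == p) |>
        (\(d) split(d, d$replicate))()
      if (length(reps) < 2) abort("need two replicates for peak filtering")
      cands <- lapply(reps[1:2], function(r) {
        bind_rows(lapply(c("+", "-"), function(strand) {
          tr <- coverage_track(r, "chrS", strand)
          h <- if (any(tr$cov > 0)) {
            as.numeric(quantile(
              tr$cov[tr$cov > 0], config$peak_height_quantile
            ))
          } else {
            NULL
          }
          call_candidate_peaks(tr,
            chrom = "chrS", strand = strand, min_height = h
          )
        }))
      })
      kept <- filter_reproducible(
        cands[[1]], cands[[2]], reps[[1]], reps[[2]],
        min_width = config$peak_min_width,
        min_reads = config$peak_min_reads,
        window = config$peak_window
      )
      targets <- assign_targets(kept, donors, window = config$target_window)
      target_sets[[p]] <- targets$intron_id
      metrics[[paste0("targets_", p)]] <- nrow(targets)
      emit(kept, sprintf("peaks_%s.tsv", p))
      if (!is.null(outdir)) {
        write_peak_bed(kept, file.path(outdir, sprintf("peaks_%s.bed", p)))
      }
    }
    out$target_sets <- target_sets
    if (length(target_sets) >= 2) {
      ov <- overlap_sets(target_sets, universe = donors$intron_id)
      out$target_overlap <- ov
      metrics$target_overlap <- ov$pairwise$intersection[1]
    }
  }

  features <- NULL
  if (on_stage("strength")) {
    features <- intron_feature_table(donors, genome$genome)
    out$features <- features
    emit(
      features |>
        select(
          "intron_id", "donor_score", "acceptor_score", "branch_score",
          "length", "gc"
        ),
      "intron_features.tsv"
    )
  }

  if (on_stage("introndiff")) {
    gene_counts <- count_features(rna$reads, annotation$genes, "gene")
    intron_counts <- count_features(rna$reads, donors, "intron")
    gene_de <- differential(gene_counts, "gene",
      reference = config$sim$conditions[1]
    )
    intron_de <- differential(intron_counts, "intron",
      reference = config$sim$conditions[1]
    )
    sel <- select_misspliced(
      intron_de, gene_de,
      donors |> select("intron_id", "gene_id")
    )
    out$gene_de <- gene_de
    out$intron_de <- intron_de
    out$misspliced <- sel
    miss_ids <- sel$feature_id[sel$misspliced]
    metrics$misspliced_introns <- length(miss_ids)
    emit(sel, "intron_de.tsv")
    emit(gene_de$results, "gene_de.tsv")
    if (!is.null(target_sets)) {
      for (p in names(target_sets)) {
        tf <- if (length(target_sets[[p]]) > 0) {
          target_fraction(miss_ids, target_sets[[p]])
        } else {
          NA_real_
        }
        metrics[[paste0("misspliced_target_fraction_", p)]] <- round(tf, 4)
      }
      ov2 <- overlap_sets(
        c(target_sets, list(misspliced = miss_ids)),
        universe = donors$intron_id
      )
      out$target_misspliced_overlap <- ov2
    }
    if (!is.null(features) && !is.null(target_sets)) {
      tset <- target_sets[[1]]
      up_t <- intersect(miss_ids, tset)
      un_t <- setdiff(tset, miss_ids)
      if (length(up_t) > 0 && length(un_t) > 0) {
        cmpr <- stratify_and_compare(features, up_t, un_t, "donor_score")
        out$strength_comparison <- cmpr
        metrics$upregulated_vs_unaffected_donor_p <- signif(cmpr$p, 6)
        metrics$upregulated_median_donor_score <- round(cmpr$median_a, 6)
        metrics$unaffected_median_donor_score <- round(cmpr$median_b, 6)
      }
    }
  }

  out$metrics <- metrics
  if (!is.null(outdir)) {
    jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  utils::str(x$metrics, give.attr = FALSE)
  invisible(x)
}
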