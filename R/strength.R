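# Splice-site strength scoring with trained log-odds position weight
# matrices, intron feature tables, and rank-sum comparisons.

site_kind_lengths <- c(donor = 9L, acceptor = 23L, branch = 7L)

#' Train a position weight matrix from aligned site sequences
#'
#' Builds a column-stochastic 4 x L probability matrix with pseudocount
#' (default 1 per base per position) from same-length training sequences.
#' Site kinds fix the expected length: donors are 9-mers (3 exonic + 6
#' intronic), acceptors 23-mers (20 intronic + 3 exonic), branch points
#' 7-mers.
#'
#' @param seqs Character vector of training sequences (ACGT), all the same
#'   kind-appropriate length; at least 2.
#' @param kind One of `"donor"`, `"acceptor"`, `"branch"`.
#' @param pseudocount Added to every base count (default 1).
#' @param background Named base probabilities (default uniform 0.25).
#' @return An object of class `pwm_model` with elements `kind`, `prob`
#'   (4 x L matrix), `background`, `consensus` (per-position argmax).
#' @export
train_pwm <- function(seqs, kind = c("donor", "acceptor", "branch"),
                      pseudocount = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  kind <- match.arg(kind)
  L <- site_kind_lengths[[kind]]
  if (length(seqs) < 2) abort("need at least 2 training sequences")
  if (any(nchar(seqs) != L)) {
    abort(sprintf(
      "%s sites must be %d nt; got lengths %s", kind, L,
      paste(unique(nchar(seqs)), collapse = ", ")
    ))
  }
  bases <- c("A", "C", "G", "T")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  counts <- vapply(seq_len(L), function(j) {
    tab <- table(factor(m[, j], levels = bases))
    as.integer(tab)
  }, integer(4))
  rownames(counts) <- bases
  prob <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  consensus <- paste(bases[apply(prob, 2, which.max)], collapse = "")
  structure(
    list(
      kind = kind, prob = prob, background = background[bases],
      consensus = consensus, n_train = length(seqs)
    ),
    class = "pwm_model"
  )
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf(
    "<pwm_model> %s (%d nt), %d training sites, consensus %s\n",
    x$kind, ncol(x$prob), x$n_train, x$consensus
  ))
  invisible(x)
}

#' Score a sequence against a PWM (log-odds, bits)
#'
#' Sum over positions of `log2(p(base | position) / background(base))`.
#'
#' @param model A [train_pwm()] model.
#' @param seq Character vector of sequences, each of the model's length.
#' @param on_ambiguous `"error"` (default) rejects non-ACGT bases; `"skip"`
#'   drops those positions from the sum.
#' @return Numeric vector of scores in bits.
#' @export
score_site <- function(model, seq, on_ambiguous = c("error", "skip")) {
  on_ambiguous <- match.arg(on_ambiguous)
  L <- ncol(model$prob)
  if (any(nchar(seq) != L)) {
    abort(sprintf("sequence length must be %d", L))
  }
  lod <- log2(sweep(model$prob, 1, model$background, "/"))
  vapply(toupper(seq), function(s) {
    b <- strsplit(s, "")[[1]]
    idx <- match(b, rownames(model$prob))
    if (anyNA(idx)) {
      if (on_ambiguous == "error") {
        abort(sprintf("ambiguous base in '%s'", s))
      }
      keep <- !is.na(idx)
      return(sum(lod[cbind(idx[keep], which(keep))]))
    }
    sum(lod[cbind(idx, seq_len(L))])
  }, numeric(1), USE.NAMES = FALSE)
}

# Extract donor 9-mers (offsets -3..+5 around the donor) for a set of
# introns from the genome.
donor_site_sequences <- function(introns, genome) {
  anchored_sequence(
    introns$chrom, introns$donor, introns$strand, -3L, 9L, genome
  )
}

acceptor_site_sequences <- function(introns, genome) {
  acc_anchor <- ifelse(
    introns$strand == "+", introns$end, introns$start - 1L
  )
  anchored_sequence(
    introns$chrom, acc_anchor, introns$strand, -20L, 23L, genome
  )
}

# Branch-point training heptamers at the canonical anchor (-30..-24 from the
# first downstream exonic base).
branch_anchor_sequences <- function(introns, genome) {
  acc_anchor <- ifelse(
    introns$strand == "+", introns$end, introns$start - 1L
  )
  anchored_sequence(
    introns$chrom, acc_anchor, introns$strand, -30L, 7L, genome
  )
}

# Best branch heptamer score within the 3' intron search window: heptamers
# fully inside 18-44 nt upstream of the intron end.
best_branch_score <- function(model, introns, genome) {
  acc_anchor <- ifelse(
    introns$strand == "+", introns$end, introns$start - 1L
  )
  starts <- -44L:-25L # heptamer offsets start .. start+6 <= -18
  vapply(seq_len(nrow(introns)), function(i) {
    seqs <- vapply(starts, function(o) {
      anchored_sequence(
        introns$chrom[i], acc_anchor[i], introns$strand[i], o, 7L, genome
      )
    }, character(1))
    max(score_site(model, seqs))
  }, numeric(1))
}

#' Intron feature table: splice-site strengths, length, GC
#'
#' Trains donor, acceptor and branch-point PWMs on the annotated sites of
#' the supplied introns (pseudocount 1, uniform background) and scores every
#' intron: donor and acceptor scores at the annotated positions, branch
#' score as the best heptamer window 18-44 nt upstream of the acceptor,
#' plus intron length and GC fraction and the percentile rank of every
#' feature.
#'
#' @param introns Intron tibble (from [extract_introns()]).
#' @param genome [Biostrings::DNAStringSet] of chromosome sequences.
#' @param models Optional named list of pre-trained `pwm_model`s
#'   (`donor`, `acceptor`, `branch`); trained from the introns when absent.
#' @return A tibble of class `intron_features` with score columns
#'   (`donor_score`, `acceptor_score`, `branch_score`, `length`, `gc`) and
#'   matching `*_pct` percentile columns; the trained models are attached as
#'   attribute `models`.
#' @export
intron_feature_table <- function(introns, genome, models = NULL) {
  if (nrow(introns) < 2) abort("need at least 2 introns")
  dseq <- donor_site_sequences(introns, genome)
  aseq <- acceptor_site_sequences(introns, genome)
  bseq <- branch_anchor_sequences(introns, genome)
  if (is.null(models)) {
    models <- list(
      donor = train_pwm(dseq, "donor"),
      acceptor = train_pwm(aseq, "acceptor"),
      branch = train_pwm(bseq, "branch")
    )
  }
  if (!"gc" %in% names(introns)) {
    seqs <- intron_sequences(introns, genome)
    introns$gc <- vapply(seqs, function(s) {
      mean(strsplit(s, "")[[1]] %in% c("G", "C"))
    }, numeric(1), USE.NAMES = FALSE)
  }
  pct <- function(x) 100 * (rank(x, ties.method = "average") - 0.5) / length(x)
  out <- introns |>
    mutate(
      donor_seq = dseq,
      donor_score = score_site(models$donor, dseq),
      acceptor_score = score_site(models$acceptor, aseq),
      branch_score = best_branch_score(models$branch, introns, genome),
      donor_score_pct = pct(.data$donor_score),
      acceptor_score_pct = pct(.data$acceptor_score),
      branch_score_pct = pct(.data$branch_score),
      length_pct = pct(.data$length),
      gc_pct = pct(.data$gc)
    )
  structure(out,
    class = c("intron_features", class(out)),
    models = models
  )
}

#' Compare a feature between two intron sets (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test of `feature` between two disjoint intron sets:
#' exact when both sets have at most 10 members (and no ties), otherwise the
#' tie-corrected normal approximation.
#'
#' @param features An [intron_feature_table()] (or any tibble with
#'   `intron_id` and the feature column).
#' @param set_a,set_b Character vectors of intron ids.
#' @param feature Feature column name (e.g. `"donor_score"`).
#' @return A one-row tibble: `feature`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `statistic` (rank-sum W), `p`.
#' @export
stratify_and_compare <- function(features, set_a, set_b,
                                 feature = "donor_score") {
  if (length(set_a) == 0 || length(set_b) == 0) {
    abort("both intron sets must be nonempty")
  }
  if (length(intersect(set_a, set_b)) > 0) {
    abort("intron sets must be disjoint")
  }
  xa <- features[[feature]][match(set_a, features$intron_id)]
  xb <- features[[feature]][match(set_b, features$intron_id)]
  if (anyNA(xa) || anyNA(xb)) abort("set ids missing from feature table")
  exact <- length(xa) <= 10 && length(xb) <= 10 &&
    !any(duplicated(c(xa, xb)))
  wt <- suppressWarnings(wilcox.test(
    xa, xb,
    alternative = "two.sided", exact = exact, correct = !exact
  ))
  tibble(
    feature = feature,
    n_a = length(xa), n_b = length(xb),
    median_a = median(xa), median_b = median(xb),
    statistic = unname(wt$statistic), p = wt$p.value
  )
}

#' Partition introns by combined splice-signal strength
#'
#' Splits introns into those with all three splice signals (donor, acceptor,
#' branch score) above their medians, all three below, or mixed.
#'
#' @param features An [intron_feature_table()].
#' @return `features` with an added `strength_group` column
#'   (`all_above` / `all_below` / `mixed`).
#' @export
strength_partition <- function(features) {
  above <- cbind(
    features$donor_score > median(features$donor_score),
    features$acceptor_score > median(features$acceptor_score),
    features$branch_score > median(features$branch_score)
  )
  grp <- ifelse(rowSums(above) == 3, "all_above",
    ifelse(rowSums(!above) == 3, "all_below", "mixed")
  )
  features$strength_group <- grp
  features
}
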