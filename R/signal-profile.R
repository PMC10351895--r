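# 5'SS-anchored coverage matrices and metaprofiles.
#
# Offset convention: column offset 0 is the first intronic base; negative
# offsets are exonic/upstream in transcript orientation. Minus-strand sites
# are mirrored so their rows read the same way as plus-strand rows.

#' Per-replicate coverage matrices around anchored sites
#'
#' Computes per-base read-footprint coverage in the +/-`flank` window around
#' each site, in transcript orientation. Only uniquely mapping reads on the
#' site's strand (sense) are counted by default; `sense_only = FALSE` gives
#' the literal genomic-forward interpretation used by some stranded
#' protocols.
#'
#' @param reads Read tibble (with a `lib` column; one matrix is produced per
#'   library).
#' @param sites Tibble with `chrom`, `strand` and `donor` (anchor position,
#'   0-based).
#' @param flank Half-window width in nt (default 200); columns run from
#'   -flank to flank-1.
#' @param unique_only Drop multi-mapping reads (default TRUE).
#' @param sense_only Count only reads on the site's strand (default TRUE).
#' @param mode `"footprint"` adds 1 over the full aligned blocks of a read;
#'   `"crosslink"` adds 1 only at the read's 5' (cross-link-proxy) base.
#' @return A named list of integer matrices (sites x 2*flank), one per
#'   library, with offset column names; class `coverage_stack`.
#' @export
coverage_around_sites <- function(reads, sites, flank = 200L,
                                  unique_only = TRUE, sense_only = TRUE,
                                  mode = c("footprint", "crosslink")) {
  mode <- match.arg(mode)
  if (flank <= 0) abort("flank must be positive")
  reads <- check_read_tbl(reads)
  if (!"lib" %in% names(reads)) reads$lib <- "lib1"
  if (unique_only) reads <- reads |> filter(.data$unique)
  if (mode == "crosslink") {
    # collapse each read to its 5' base in transcript orientation
    five <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
    reads$start <- five
    reads$end <- five + 1L
    reads$gap_start <- NA_integer_
    reads$gap_end <- NA_integer_
  }
  offsets <- seq(-flank, flank - 1L)
  libs <- sort(unique(reads$lib))
  out <- lapply(libs, function(lb) {
    r <- reads |> filter(.data$lib == lb)
    mat <- matrix(0L, nrow = nrow(sites), ncol = 2L * flank,
      dimnames = list(NULL, offsets)
    )
    for (ch in unique(sites$chrom)) {
      for (st in c("+", "-")) {
        si <- which(sites$chrom == ch & sites$strand == st)
        if (length(si) == 0) next
        rr <- r |> filter(.data$chrom == ch)
        if (sense_only) rr <- rr |> filter(.data$strand == st)
        if (nrow(rr) == 0) next
        gr <- reads_to_block_granges(rr)
        cov <- GenomicRanges::coverage(gr)[[ch]]
        clen <- length(cov)
        covv <- as.integer(cov)
        for (j in si) {
          a <- sites$donor[j]
          gpos <- if (st == "+") a + offsets else a - offsets
          inb <- gpos >= 0L & gpos < clen
          row <- integer(2L * flank)
          row[inb] <- covv[gpos[inb] + 1L]
          mat[j, ] <- row
        }
      }
    }
    mat
  })
  names(out) <- libs
  structure(out, class = "coverage_stack", flank = flank)
}

#' Normalize coverage to cpm and average replicates
#'
#' Each library's matrix is scaled by `1e6 / library_size` and the scaled
#' matrices are averaged elementwise.
#'
#' @param stack A [coverage_around_sites()] result (or a plain list of
#'   matrices).
#' @param library_sizes Named numeric vector of uniquely mapped read counts
#'   per library, in the same order/names as the stack.
#' @return A numeric matrix of class `coverage_matrix` (sites x offsets),
#'   average cpm across replicates.
#' @export
normalize_cpm <- function(stack, library_sizes) {
  mats <- unclass(stack)
  if (!is.null(names(mats)) && !is.null(names(library_sizes))) {
    missing <- setdiff(names(mats), names(library_sizes))
    if (length(missing) > 0) {
      abort(sprintf(
        "library_sizes missing: %s", paste(missing, collapse = ", ")
      ))
    }
    library_sizes <- library_sizes[names(mats)]
  }
  if (any(library_sizes <= 0)) abort("library sizes must be positive")
  scaled <- purrr::map2(mats, library_sizes, function(m, n) m * (1e6 / n))
  avg <- Reduce(`+`, scaled) / length(scaled)
  structure(avg,
    class = c("coverage_matrix", class(avg)),
    flank = attr(stack, "flank", exact = TRUE) %||% (ncol(avg) / 2L)
  )
}

#' Order matrix rows by decreasing signal
#'
#' Sorts rows in descending order of `key` (ties keep their original order).
#' The returned permutation can be applied to other matrices to display
#' different samples in a shared site order.
#'
#' @param mat A coverage matrix.
#' @param key Numeric vector, one value per row; defaults to the row means
#'   of `mat` itself.
#' @return The row-permuted matrix with attribute `row_order` (the
#'   permutation applied).
#' @export
order_rows <- function(mat, key = rowMeans(mat)) {
  if (length(key) != nrow(mat)) {
    abort("key length must equal the number of rows")
  }
  ord <- order(-key, seq_along(key))
  out <- mat[ord, , drop = FALSE]
  attr(out, "row_order") <- ord
  attr(out, "flank") <- attr(mat, "flank", exact = TRUE)
  class(out) <- class(mat)
  out
}

#' Metaprofile of a coverage matrix
#'
#' Column means over sites, with the peak offset (argmax; ties resolved to
#' the smallest offset). A flat matrix is flagged degenerate.
#'
#' @param mat A coverage matrix with offset column names.
#' @return A tibble (`offset`, `signal`) of class `ss_metaplot` with
#'   attributes `peak_offset` and `degenerate`.
#' @export
metaplot <- function(mat) {
  if (is.null(dim(mat)) || nrow(mat) == 0) abort("matrix is empty")
  prof <- colMeans(mat)
  offs <- as.integer(colnames(mat))
  if (anyNA(offs)) offs <- seq_along(prof) - 1L
  peak <- offs[which.max(prof)]
  out <- tibble(offset = offs, signal = unname(prof))
  structure(out,
    class = c("ss_metaplot", class(out)),
    peak_offset = peak,
    degenerate = isTRUE(diff(range(prof)) == 0)
  )
}

#' Peak offset of a metaprofile
#'
#' @param x A [metaplot()] result.
#' @return Integer offset (nt) of the profile maximum.
#' @export
peak_offset <- function(x) attr(x, "peak_offset", exact = TRUE)

#' Write a coverage matrix or metaprofile as TSV
#'
#' @param x A `coverage_matrix` or `ss_metaplot`.
#' @param path Output path.
#' @export
write_profile_tsv <- function(x, path) {
  if (inherits(x, "ss_metaplot")) {
    utils::write.table(as.data.frame(x), path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  } else {
    utils::write.table(as.data.frame(unclass(x)), path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
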