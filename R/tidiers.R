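# broom-style tidiers for the package's fitted/result objects.

#' Tidy a PWM model into a long tibble
#'
#' @param x A `pwm_model`.
#' @param ... Unused.
#' @return A tibble with `position`, `base`, `prob` and `log_odds` (bits).
#' @export
tidy.pwm_model <- function(x, ...) {
  lod <- log2(sweep(x$prob, 1, x$background, "/"))
  tidyr::expand_grid(
    position = seq_len(ncol(x$prob)), base = rownames(x$prob)
  ) |>
    mutate(
      prob = x$prob[cbind(
        match(.data$base, rownames(x$prob)), .data$position
      )],
      log_odds = lod[cbind(
        match(.data$base, rownames(lod)), .data$position
      )]
    )
}

#' One-line summary of a PWM model
#'
#' @param x A `pwm_model`.
#' @param ... Unused.
#' @export
glance.pwm_model <- function(x, ...) {
  tibble(
    kind = x$kind, width = ncol(x$prob), n_train = x$n_train,
    consensus = x$consensus,
    max_score = sum(apply(
      log2(sweep(x$prob, 1, x$background, "/")), 2, max
    ))
  )
}

#' Per-feature results of a differential analysis
#'
#' @param x An `nb_de` object.
#' @param ... Unused.
#' @return The per-feature results tibble.
#' @export
tidy.nb_de <- function(x, ...) x$results

#' One-line summary of a differential analysis
#'
#' @param x An `nb_de` object.
#' @param ... Unused.
#' @export
glance.nb_de <- function(x, ...) {
  tibble(
    mode = x$mode, reference = x$reference, contrast = x$contrast,
    n_features = nrow(x$results),
    n_excluded = sum(x$results$excluded),
    n_up = sum(x$results$up), n_down = sum(x$results$down),
    alpha = x$alpha, lfc_threshold = x$lfc_threshold
  )
}

#' Long-format counts of a counts table
#'
#' @param x A `counts_table`.
#' @param ... Unused.
#' @return A tibble with `feature_id`, `lib`, `condition`, `replicate`,
#'   `count`.
#' @export
tidy.counts_table <- function(x, ...) {
  as_tibble(x$counts, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "lib", values_to = "count") |>
    left_join(x$samples, by = "lib")
}

#' Metaprofile as a plain tibble
#'
#' @param x An `ss_metaplot`.
#' @param ... Unused.
#' @export
tidy.ss_metaplot <- function(x, ...) {
  tibble(offset = x$offset, signal = x$signal)
}

#' Peak-offset summary of a metaprofile
#'
#' @param x An `ss_metaplot`.
#' @param ... Unused.
#' @export
glance.ss_metaplot <- function(x, ...) {
  tibble(
    peak_offset = attr(x, "peak_offset", exact = TRUE),
    max_signal = max(x$signal),
    degenerate = attr(x, "degenerate", exact = TRUE)
  )
}
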