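# broom-style tidiers and ggplot2 autoplot methods for design results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pegRNA design result
#'
#' Returns the candidate table as a plain tibble (one row per candidate or
#' untargetable variant).
#'
#' @param x A `peg_design`.
#' @param ... Unused.
#' @export
tidy.peg_design <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a pegRNA design result
#'
#' @param x A `peg_design`.
#' @param ... Unused.
#' @return A tibble with `n_variants`, `n_targetable` (variants with at
#'   least one candidate), `n_candidates`, `best_score`,
#'   `targetable_fraction`.
#' @export
glance.peg_design <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  per_var <- dplyr::summarise(
    dplyr::group_by(tb, .data$variant_name),
    targetable = any(.data$status == "targetable"),
    .groups = "drop"
  )
  tibble::tibble(
    n_variants = nrow(per_var),
    n_targetable = sum(per_var$targetable),
    n_candidates = sum(tb$status == "targetable"),
    best_score = if (any(tb$status == "targetable")) {
      max(tb$score, na.rm = TRUE)
    } else {
      NA_integer_
    },
    targetable_fraction = mean(per_var$targetable)
  )
}

#' @export
tidy.be_design <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tb$bystanders <- vapply(tb$bystanders, paste, character(1L),
    collapse = ",")
  tb
}

#' @export
glance.be_design <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  ok <- tb$status == "targetable"
  tibble::tibble(
    n_candidates = sum(ok),
    n_editors = length(unique(tb$editor[ok])),
    min_bystanders = if (any(ok)) min(tb$n_bystanders[ok]) else NA_integer_,
    editable = any(ok)
  )
}

#' Plot pegRNA candidate scores with their penalty breakdown
#'
#' Stacked bars of the (negative) penalty components per candidate, ordered
#' by total score, so a glance shows which design rule costs each pegRNA.
#'
#' @param object A `peg_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peg_design <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  tb <- tb[tb$status == "targetable", ]
  if (nrow(tb) == 0L) {
    stop("no targetable candidates to plot", call. = FALSE)
  }
  tb$candidate <- factor(
    paste0(tb$variant_name, " ", tb$protospacer, " (", tb$strand, ")"),
    levels = unique(paste0(
      tb$variant_name, " ", tb$protospacer, " (", tb$strand, ")"
    )[order(-tb$score)])
  )
  long <- tidyr::pivot_longer(
    tb,
    cols = dplyr::starts_with("penalty_"),
    names_to = "penalty", names_prefix = "penalty_", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$candidate, y = .data$value, fill = .data$penalty)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "penalty contribution",
      title = "pegRNA score breakdown"
    ) +
    ggplot2::theme_minimal()
}

#' Plot base-editor candidates by bystander load
#'
#' @param object A `be_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.be_design <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  tb <- tb[tb$status == "targetable", ]
  if (nrow(tb) == 0L) {
    stop("no targetable candidates to plot", call. = FALSE)
  }
  tb$label <- paste0(tb$editor, " pos", tb$edit_position, " (", tb$strand, ")")
  ggplot2::ggplot(
    tb,
    ggplot2::aes(
      x = stats::reorder(.data$label, .data$n_bystanders),
      y = .data$n_bystanders, fill = .data$class
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "bystander bases in window",
      title = "Base-editor candidates (fewer bystanders = cleaner)"
    ) +
    ggplot2::theme_minimal()
}

#' Targetable fraction across RTT lengths
#'
#' Re-designs a batch at each RTT length and reports the fraction of
#' variants with at least one pegRNA — longer templates cover more distant
#' PAMs, so the fraction is monotone non-decreasing.
#'
#' @param jobs Jobs tibble (see [design_pegrna_batch()]).
#' @param genome FASTA path for genomic jobs.
#' @param rtt_lengths Integer vector of RTT lengths to sweep (default
#'   10:20).
#' @param flank Genomic context per side.
#' @return A tibble: `rtt_len`, `n_targetable`, `n_variants`, `fraction`.
#' @export
rtt_sweep <- function(jobs, genome = NULL, rtt_lengths = 10:20,
                      flank = 150L) {
  purrr::map_dfr(rtt_lengths, function(rl) {
    j <- dplyr::mutate(jobs, rtt_len = as.integer(rl))
    res <- design_pegrna_batch(j, genome = genome, show_all = FALSE,
      flank = flank)
    g <- glance(res)
    tibble::tibble(
      rtt_len = as.integer(rl),
      n_targetable = g$n_targetable,
      n_variants = g$n_variants,
      fraction = g$targetable_fraction
    )
  })
}

#' Plot an RTT-length sweep
#'
#' @param sweep Output of [rtt_sweep()].
#' @return A ggplot object.
#' @export
plot_rtt_sweep <- function(sweep) {
  ggplot2::ggplot(
    sweep,
    ggplot2::aes(x = .data$rtt_len, y = 100 * .data$fraction)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "RTT length (nt)", y = "targetable variants (%)",
      title = "Variant targetability vs RTT length"
    ) +
    ggplot2::theme_minimal()
}
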