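# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a bait design
#'
#' @param x a `bait_design` from [select_markers()].
#' @param ... unused.
#' @return The bait layout: one row per probe with `marker_id`,
#'   `exon_index`, `start`, `end` (0-based half-open on the target).
#' @method tidy bait_design
#' @export
tidy.bait_design <- function(x, ...) x$baits

#' One-row summary of a bait design
#'
#' @param x a `bait_design`.
#' @param ... unused.
#' @return Tibble with `n_markers`, `n_baits`, `bait_len`,
#'   `total_bait_len`, `coverage`, `capture_footprint`
#'   (total bait length / coverage, the conventional capture-footprint
#'   arithmetic), `targeted_len` (cumulative targetable exon length) and
#'   `rank_mode`.
#' @method glance bait_design
#' @export
glance.bait_design <- function(x, ...) {
  tibble::tibble(
    n_markers = length(x$marker_ids),
    n_baits = x$n_baits,
    bait_len = x$bait_len,
    total_bait_len = x$total_bait_len,
    coverage = x$coverage,
    capture_footprint = x$capture_footprint,
    targeted_len = x$targeted_len,
    rank_mode = x$rank_mode
  )
}

#' Plot a bait design
#'
#' Histogram of per-marker predicted lengths with the per-marker bait
#' counts mapped to fill.
#'
#' @param object a `bait_design`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot bait_design
#' @export
autoplot.bait_design <- function(object, ...) {
  sel <- object$selected
  ggplot2::ggplot(sel, ggplot2::aes(x = .data$predicted_len,
                                    fill = .data$n_baits_needed)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "predicted marker length (bp)", y = "markers",
                  fill = "baits") +
    ggplot2::theme_minimal()
}

#' Compare selected marker-length distributions across ranking modes
#'
#' Mirrors the study's headline comparison: ranking on predicted
#' exon+intron length admits more, shorter markers than ranking on exon
#' length alone.
#'
#' @param designs named list of `bait_design` objects (names used as
#'   panel labels).
#' @return A ggplot.
#' @export
plot_mode_comparison <- function(designs) {
  df <- dplyr::bind_rows(lapply(names(designs), function(nm) {
    sel <- designs[[nm]]$selected
    tibble::tibble(mode = nm, exon_len = sel$exon_len_total,
                   predicted_len = sel$predicted_len)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$exon_len)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "selected exon length (bp)") +
    ggplot2::theme_minimal()
}

#' Tidy merged contigs
#'
#' @param x a `merged_contigs` from [merge_contigs()].
#' @param ... unused.
#' @return Tibble of merged sequences plus the ambiguity table columns
#'   joined in (`NA` where a sequence has no ambiguities).
#' @method tidy merged_contigs
#' @export
tidy.merged_contigs <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$target_id <- attr(x, "target_id")
  out$sample <- attr(x, "sample")
  out
}

#' One-row summary of merged contigs
#'
#' @param x a `merged_contigs`.
#' @param ... unused.
#' @return Tibble with `target_id`, `sample`, `n_sequences`,
#'   `n_copy_groups`, `n_ambiguities`, `total_len`.
#' @method glance merged_contigs
#' @export
glance.merged_contigs <- function(x, ...) {
  tibble::tibble(
    target_id = attr(x, "target_id"),
    sample = attr(x, "sample"),
    n_sequences = nrow(x),
    n_copy_groups = length(unique(x$copy_group)),
    n_ambiguities = nrow(attr(x, "ambiguities")),
    total_len = sum(nchar(x$seq))
  )
}

#' Plot per-marker variability
#'
#' Scatter of predicted marker length against percent variable sites, the
#' package's analogue of a length-versus-variability diagnostic.
#'
#' @param reports tibble binding [variability()] rows, with a
#'   `predicted_len` column joined on.
#' @return A ggplot.
#' @export
plot_variability <- function(reports) {
  ggplot2::ggplot(reports, ggplot2::aes(x = .data$predicted_len,
                                        y = 100 * .data$pct_variable)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "predicted marker length (bp)",
                  y = "variable sites (%)") +
    ggplot2::theme_minimal()
}
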