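# Stage 2: rank candidates by (predicted) length or variability, exclude
# sub-bait-length exons from targeting, and greedily fill the bait budget.

#' Mean intron length across candidates
#'
#' Arithmetic mean of all intron lengths pooled over all candidates' gene
#' models (the ranking uses this single global mean rather than each
#' marker's own introns, to avoid favouring markers with unusually large
#' introns).  With `scope = "per_marker"` the mean is instead computed per
#' marker and the pooled value returned is the mean of those means.
#'
#' @param candidates candidate tibble from [discover_markers()].
#' @param scope `"global"` or `"per_marker"`.
#' @return Mean intron length, bp.
#' @export
mean_intron_length <- function(candidates, scope = c("global", "per_marker")) {
  scope <- match.arg(scope)
  lens <- candidates$intron_lens
  all_lens <- unlist(lens)
  if (length(all_lens) == 0) {
    stop("no candidate has an intron; rank markers with rank_mode = \"exon_length\"",
         call. = FALSE)
  }
  if (scope == "global") {
    mean(all_lens)
  } else {
    mean(vapply(lens[lengths(lens) > 0], mean, 0))
  }
}

#' Predicted capture length of a marker
#'
#' `exon_length` mode ignores introns: the prediction is the total exon
#' length.  `exon_plus_intron` mode adds `n_introns` times the (rounded)
#' mean intron length `mu_intron`, crediting markers for the flanking
#' intron sequence that hybrid capture tends to recover without needing
#' matching baits.
#'
#' @param exon_len_total total exon length, bp (vectorised).
#' @param n_introns intron count (vectorised).
#' @param mu_intron mean intron length, bp (see [mean_intron_length()]).
#' @param mode `"exon_length"` or `"exon_plus_intron"`.
#' @return Predicted length, bp (integer).
#' @examples
#' predict_marker_length(2000, 3, 400, "exon_plus_intron")  # 3200
#' @export
predict_marker_length <- function(exon_len_total, n_introns, mu_intron = 0,
                                  mode = c("exon_length", "exon_plus_intron")) {
  mode <- match.arg(mode)
  if (mode == "exon_length") {
    as.integer(exon_len_total)
  } else {
    as.integer(exon_len_total + n_introns * round(mu_intron))
  }
}

#' Tile baits across one exon
#'
#' Baits of `bait_len` bp start at offsets `0, step, 2*step, ...` with
#' `step = bait_len / coverage`; the final bait is right-aligned to end
#' exactly at `exon_len`, so every targetable base is covered at least
#' once.  The bait count is `ceiling((exon_len - bait_len) / step) + 1`.
#'
#' @param exon_len exon length, bp; must be >= `bait_len` (shorter exons
#'   must be excluded by the caller).
#' @param bait_len probe length, bp.
#' @param coverage tiling depth.
#' @return List with `n_baits` and integer `offsets` (0-based starts
#'   within the exon).
#' @examples
#' tile_baits(150, 120, 4)  # offsets 0, 30
#' tile_baits(135, 120, 4)  # offsets 0, 15 (last bait right-aligned)
#' @export
tile_baits <- function(exon_len, bait_len = 120L, coverage = 4L) {
  if (bait_len %% coverage != 0) {
    stop("bait_len must be divisible by coverage", call. = FALSE)
  }
  if (exon_len < bait_len) {
    stop("exon shorter than a bait cannot be tiled; exclude it first",
         call. = FALSE)
  }
  step <- bait_len %/% coverage
  offsets <- seq(0L, exon_len - bait_len, by = step)
  last <- as.integer(exon_len - bait_len)
  if (offsets[length(offsets)] != last) offsets <- c(offsets, last)
  list(n_baits = length(offsets), offsets = as.integer(offsets))
}

#' @noRd
targetable_exons <- function(candidate_row, min_exon_len) {
  q <- candidate_row$exons_q[[1]]
  lens <- q[, 2] - q[, 1]
  keep <- lens >= min_exon_len
  list(exons_q = q[keep, , drop = FALSE],
       exon_index = which(keep),
       targetable_len = as.integer(sum(lens[keep])))
}

#' Select an optimal marker set under the bait budget
#'
#' Candidates with no exon of at least `cfg$min_exon_len` bp are dropped
#' (exons below that length are never targeted, but do not disqualify a
#' marker that also has longer exons).  The rest are scored according to
#' `cfg$rank_mode`: predicted length for `exon_length` /
#' `exon_plus_intron`, the supplied per-marker fraction for `variability`,
#' or their product for `length_times_variability`; sorted by descending
#' score (ties: fewer baits needed, then lexicographic `marker_id`); and
#' added greedily while the cumulative bait count stays within
#' `cfg$max_baits`, skipping candidates that do not fit and continuing
#' down the list (first fit decreasing).
#'
#' @param candidates candidate tibble from [discover_markers()].
#' @param cfg a [run_config()].
#' @param variability named numeric vector (fraction per `marker_id`);
#'   required by the two variability modes.
#' @return A `bait_design` object; `$selected` holds the ranked selected
#'   candidates, `$baits` the tiled probe layout (coordinates on the
#'   marker's target sequence, 0-based half-open).  See also
#'   [design_report()], [tidy.bait_design()], [glance.bait_design()].
#' @export
select_markers <- function(candidates, cfg = run_config(), variability = NULL) {
  stopifnot(nrow(candidates) > 0)
  mode <- cfg$rank_mode
  if (mode %in% c("variability", "length_times_variability") &&
      is.null(variability)) {
    stop("rank_mode \"", mode, "\" needs a named `variability` vector",
         call. = FALSE)
  }
  tg <- lapply(seq_len(nrow(candidates)), function(i) {
    targetable_exons(candidates[i, ], cfg$min_exon_len)
  })
  keep <- vapply(tg, function(x) nrow(x$exons_q) > 0, TRUE)
  cand <- candidates[keep, ]
  tg <- tg[keep]
  if (nrow(cand) == 0) {
    return(new_bait_design(cand, empty_baits(), cfg))
  }
  cand$targetable_exon_len <- vapply(tg, function(x) x$targetable_len, 1L)
  cand$n_baits_needed <- vapply(tg, function(x) {
    sum(vapply(seq_len(nrow(x$exons_q)), function(k) {
      tile_baits(x$exons_q[k, 2] - x$exons_q[k, 1],
                 cfg$bait_len, cfg$tiling_coverage)$n_baits
    }, 1L))
  }, 1L)
  # with no introns anywhere the intron-aware mode degenerates to plain
  # exon length (mu = 0) rather than failing
  mu <- if (mode == "exon_plus_intron" && sum(lengths(cand$intron_lens)) > 0) {
    mean_intron_length(cand, scope = cfg$mean_intron_scope)
  } else 0
  cand$predicted_len <- predict_marker_length(
    cand$exon_len_total, cand$n_introns, mu,
    mode = if (mode == "exon_plus_intron") "exon_plus_intron" else "exon_length")
  cand$rank_score <- switch(
    mode,
    exon_length = as.double(cand$predicted_len),
    exon_plus_intron = as.double(cand$predicted_len),
    variability = unname(variability[cand$marker_id]),
    length_times_variability =
      as.double(cand$predicted_len) * unname(variability[cand$marker_id])
  )
  if (anyNA(cand$rank_score)) {
    stop("variability is missing for marker(s): ",
         paste(head(cand$marker_id[is.na(cand$rank_score)], 5), collapse = ", "),
         call. = FALSE)
  }
  o <- order(-cand$rank_score, cand$n_baits_needed, cand$marker_id)
  cand <- cand[o, ]
  used <- 0L
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (used + cand$n_baits_needed[i] <= cfg$max_baits) {
      take[i] <- TRUE
      used <- used + cand$n_baits_needed[i]
    }
  }
  sel <- cand[take, ]
  baits <- if (nrow(sel) == 0) empty_baits() else dplyr::bind_rows(
    lapply(seq_len(nrow(sel)), function(i) {
      lay <- targetable_exons(sel[i, ], cfg$min_exon_len)
      dplyr::bind_rows(lapply(seq_len(nrow(lay$exons_q)), function(k) {
        q0 <- lay$exons_q[k, 1]
        len <- lay$exons_q[k, 2] - q0
        t <- tile_baits(len, cfg$bait_len, cfg$tiling_coverage)
        tibble::tibble(marker_id = sel$marker_id[i],
                       exon_index = lay$exon_index[k],
                       start = as.integer(q0 + t$offsets),
                       end = as.integer(q0 + t$offsets + cfg$bait_len))
      }))
    }))
  new_bait_design(sel, baits, cfg)
}

#' @noRd
empty_baits <- function() {
  tibble::tibble(marker_id = character(), exon_index = integer(),
                 start = integer(), end = integer())
}

#' @noRd
new_bait_design <- function(selected, baits, cfg) {
  n_baits <- nrow(baits)
  structure(list(
    selected = selected,
    baits = baits,
    marker_ids = selected$marker_id,
    n_baits = n_baits,
    total_bait_len = n_baits * cfg$bait_len,
    targeted_len = if ("targetable_exon_len" %in% names(selected)) {
      as.integer(sum(selected$targetable_exon_len))
    } else 0L,
    capture_footprint = n_baits * cfg$bait_len / cfg$tiling_coverage,
    coverage = cfg$tiling_coverage,
    bait_len = cfg$bait_len,
    max_baits = cfg$max_baits,
    rank_mode = cfg$rank_mode
  ), class = "bait_design")
}

#' @export
print.bait_design <- function(x, ...) {
  cat("<bait_design>\n")
  cat(sprintf("  %d markers, %d baits x %d bp (budget %d)\n",
              length(x$marker_ids), x$n_baits, x$bait_len, x$max_baits))
  cat(sprintf("  total bait length %d bp; capture footprint %s bp at %dx\n",
              x$total_bait_len, format(x$capture_footprint, big.mark = ","),
              x$coverage))
  cat(sprintf("  cumulative targeted exon length %d bp; rank_mode %s\n",
              x$targeted_len, x$rank_mode))
  invisible(x)
}

#' Per-marker design report
#'
#' One row per selected marker (exon counts, targetable and predicted
#' length, baits needed) plus totals carried in the `totals` attribute and
#' in [glance.bait_design()].
#'
#' @param design a `bait_design` from [select_markers()].
#' @return Tibble with per-marker rows; attribute `totals` holds the
#'   one-row summary.
#' @export
design_report <- function(design) {
  sel <- design$selected
  per <- if (nrow(sel) == 0) {
    tibble::tibble(marker_id = character(), n_exons = integer(),
                   n_exons_targeted = integer(), targetable_len = integer(),
                   predicted_len = integer(), n_baits = integer())
  } else {
    tibble::tibble(
      marker_id = sel$marker_id,
      n_exons = vapply(sel$exons_q, nrow, 1L),
      n_exons_targeted = vapply(
        split(design$baits$exon_index, design$baits$marker_id)[sel$marker_id],
        function(x) length(unique(x)), 1L),
      targetable_len = sel$targetable_exon_len,
      predicted_len = sel$predicted_len,
      n_baits = sel$n_baits_needed
    )
  }
  attr(per, "totals") <- glance(design)
  per
}

#' Extract bait sequences
#'
#' One record per tiled probe, id `marker:exon:offset`.
#'
#' @param design a `bait_design`.
#' @return Sequence tibble of `bait_len`-bp probes.
#' @export
bait_seqs <- function(design) {
  b <- design$baits
  sel <- design$selected
  if (nrow(b) == 0) stop("design has no baits", call. = FALSE)
  seqs <- substring(sel$seq[match(b$marker_id, sel$marker_id)],
                    b$start + 1L, b$end)
  seq_tbl(sprintf("%s:%d:%d", b$marker_id, b$exon_index, b$start),
          seqs, source = "baits", role = "target")
}

#' Write bait placements as BED
#'
#' 0-based half-open intervals on the marker target sequences.
#'
#' @param design a `bait_design`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_baits_bed <- function(design, path) {
  b <- design$baits
  writeLines(sprintf("%s\t%d\t%d\t%s:%d:%d", b$marker_id, b$start, b$end,
                     b$marker_id, b$exon_index, b$start), path)
  invisible(path)
}
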