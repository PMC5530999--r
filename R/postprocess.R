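# Empirical-data processing: match assembled contigs to targets, merge
# compatible contigs with IUPAC ambiguity coding, filter alignment columns
# and compute per-marker variability.

#' Match captured contigs to their targets
#'
#' Each contig is assigned to its best target by alignment score.  Matches
#' with aligned target span >= `cfg$min_target_overlap` (100 bp) and
#' identity >= `cfg$min_identity` (75%) pass the filter; matches failing
#' either criterion are kept on a rescue list (`rescue = TRUE`) and are
#' only merged in after the confident contigs.  Contigs on the minus
#' strand are reverse-complemented so that every returned contig is in
#' target orientation; `placed_start` is the contig's start on the target
#' coordinate axis (may be negative when the contig carries flanking
#' sequence beyond the target).
#'
#' @param contigs sequence tibble of assembled contigs; `source` is used
#'   as the sample label.
#' @param targets sequence tibble of selected target sequences.
#' @param cfg a [run_config()].
#' @return Tibble: `sample`, `contig_id`, `target_id`, `overlap_len`,
#'   `identity`, `strand`, `rescue`, `placed_start`, `seq` (oriented).
#' @export
match_contigs <- function(contigs, targets, cfg = run_config()) {
  stopifnot(nrow(contigs) > 0, nrow(targets) > 0)
  hits <- find_homologues(contigs, targets, min_identity = 0,
                          min_hit_len = min(20L, min(nchar(contigs$seq))),
                          cfg = cfg, split_subject_gaps = FALSE)
  if (nrow(hits) == 0) return(empty_matches())
  best <- dplyr::slice_max(dplyr::group_by(hits, .data$query_id),
                           order_by = .data$score, n = 1, with_ties = FALSE)
  best <- dplyr::ungroup(best)
  idx <- match(best$query_id, contigs$id)
  seq_fwd <- ifelse(best$strand == "+", contigs$seq[idx],
                    revcomp(contigs$seq[idx]))
  clen <- nchar(seq_fwd)
  # query coordinates of the hit on the oriented contig
  q0 <- ifelse(best$strand == "+", best$q_start, clen - best$q_end)
  placed <- as.integer(best$s_start - q0)
  # similarity is assessed over the contig's full overlap with the target
  # at its placement, not over the (possibly trimmed) local hit: a
  # uniformly diverged contig must not pass the filter on the strength of
  # a short high-identity core
  tlen <- nchar(targets$seq[match(best$subject_id, targets$id)])
  ov <- vapply(seq_len(nrow(best)), function(i) {
    lo <- max(0L, placed[i])
    hi <- min(tlen[i], placed[i] + clen[i])
    if (hi <= lo) return(c(0, 0))
    tchars <- strsplit(substr(targets$seq[match(best$subject_id[i], targets$id)],
                              lo + 1L, hi), "")[[1]]
    cchars <- strsplit(substr(seq_fwd[i], lo - placed[i] + 1L,
                              hi - placed[i]), "")[[1]]
    c(hi - lo, mean(tchars == cchars))
  }, c(0, 0))
  out <- tibble::tibble(
    sample = contigs$source[idx],
    contig_id = best$query_id,
    target_id = best$subject_id,
    overlap_len = as.integer(ov[1, ]),
    identity = ov[2, ],
    strand = best$strand,
    rescue = !(ov[1, ] >= cfg$min_target_overlap &
                 ov[2, ] >= cfg$min_identity),
    placed_start = placed,
    seq = seq_fwd
  )
  out[order(out$sample, out$target_id, out$placed_start, out$contig_id), ]
}

#' @noRd
empty_matches <- function() {
  tibble::tibble(sample = character(), contig_id = character(),
                 target_id = character(), overlap_len = integer(),
                 identity = double(), strand = character(),
                 rescue = logical(), placed_start = integer(),
                 seq = character())
}

#' @noRd
column_sets <- function(seq) strsplit(IUPAC_SETS[strsplit(seq, "")[[1]]], "")

# Compare two placed contigs; returns overlap length and conflicting
# columns (positions, global axis) where the IUPAC base sets differ.
#' @noRd
overlap_conflicts <- function(a, b) {
  lo <- max(a$start, b$start)
  hi <- min(a$start + length(a$sets), b$start + length(b$sets))
  if (hi <= lo) return(list(overlap = 0L, conflicts = integer(0)))
  ia <- (lo - a$start + 1L):(hi - a$start)
  ib <- (lo - b$start + 1L):(hi - b$start)
  differ <- !mapply(setequal, a$sets[ia], b$sets[ib])
  list(overlap = hi - lo, conflicts = (lo:(hi - 1L))[differ])
}

#' Merge captured contigs for one target and sample
#'
#' Contigs are placed on target coordinates and merged iteratively: a pair
#' is combined when it overlaps by at least `cfg$min_merge_overlap` (30 bp)
#' and the overlapping columns are identical, or differ at exactly one
#' column -- that column is coded with the IUPAC ambiguity code of the
#' union of observed bases (unions accumulate across successive merges).
#' Pairs differing at two or more columns, or overlapping too little, stay
#' separate.  Merging proceeds to a fixpoint, longest-overlap pairs first
#' (ties by leftmost placement), which makes the result independent of
#' input order.  Rescue-listed fragments are attempted last under the same
#' rules.
#'
#' @param matches rows of [match_contigs()] sharing one `target_id` and
#'   `sample`.
#' @param cfg a [run_config()].
#' @return A `merged_contigs` object: tibble of merged sequences
#'   (`seq_index`, `start`, `seq`, `n_ambig`, `copy_group`) with
#'   attributes `ambiguities` (tibble `seq_index`, `position`, `code`;
#'   positions on the target axis, 0-based) and `target_id`, `sample`.
#' @export
merge_contigs <- function(matches, cfg = run_config()) {
  stopifnot(nrow(matches) > 0)
  if (length(unique(matches$target_id)) != 1 ||
      length(unique(matches$sample)) != 1) {
    stop("merge_contigs() expects matches of one target and one sample",
         call. = FALSE)
  }
  mk <- function(row) list(start = row$placed_start,
                           sets = column_sets(row$seq))
  pool <- lapply(seq_len(nrow(matches))[!matches$rescue],
                 function(i) mk(matches[i, ]))
  merge_pool <- function(pool) {
    repeat {
      n <- length(pool)
      if (n < 2) break
      best <- NULL
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          oc <- overlap_conflicts(pool[[i]], pool[[j]])
          if (oc$overlap >= cfg$min_merge_overlap &&
              length(oc$conflicts) <= 1) {
            key <- c(-oc$overlap, min(pool[[i]]$start, pool[[j]]$start),
                     max(pool[[i]]$start, pool[[j]]$start), i, j)
            if (is.null(best) || isTRUE(vec_less(key, best$key))) {
              best <- list(key = key, i = i, j = j, oc = oc)
            }
          }
        }
      }
      if (is.null(best)) break
      a <- pool[[best$i]]; b <- pool[[best$j]]
      lo <- min(a$start, b$start)
      hi <- max(a$start + length(a$sets), b$start + length(b$sets))
      sets <- vector("list", hi - lo)
      put <- function(sets, x) {
        for (p in seq_along(x$sets)) {
          g <- x$start - lo + p
          sets[[g]] <- if (is.null(sets[[g]])) x$sets[[p]]
                       else sort(union(sets[[g]], x$sets[[p]]))
        }
        sets
      }
      sets <- put(put(sets, a), b)
      pool <- c(pool[-c(best$i, best$j)], list(list(start = lo, sets = sets)))
    }
    pool
  }
  pool <- merge_pool(pool)
  rescue_rows <- which(matches$rescue)
  if (length(rescue_rows) > 0) {
    pool <- merge_pool(c(pool, lapply(rescue_rows, function(i) mk(matches[i, ]))))
  }
  # deterministic output order: leftmost placement, then sequence
  seqs <- vapply(pool, function(x) {
    paste(vapply(x$sets, function(s) IUPAC_FROM_SET[[paste(s, collapse = "")]],
                 ""), collapse = "")
  }, "")
  o <- order(vapply(pool, function(x) x$start, 1L), seqs)
  pool <- pool[o]; seqs <- seqs[o]
  amb <- dplyr::bind_rows(lapply(seq_along(pool), function(k) {
    amb_at <- which(lengths(pool[[k]]$sets) > 1)
    if (length(amb_at) == 0) return(NULL)
    tibble::tibble(seq_index = k,
                   position = pool[[k]]$start + amb_at - 1L,
                   code = substring(seqs[k], amb_at, amb_at))
  }))
  if (is.null(amb) || nrow(amb) == 0) {
    amb <- tibble::tibble(seq_index = integer(), position = integer(),
                          code = character())
  }
  out <- tibble::tibble(
    seq_index = seq_along(pool),
    start = vapply(pool, function(x) x$start, 1L),
    seq = seqs,
    n_ambig = vapply(seq_along(pool),
                     function(k) sum(amb$seq_index == k), 1L)
  )
  out$copy_group <- segregate_copies(out, cfg)
  structure(out, class = c("merged_contigs", class(out)),
            ambiguities = amb,
            target_id = matches$target_id[1], sample = matches$sample[1])
}

#' @noRd
vec_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

# Merged sequences overlapping each other but < paralog_split_identity
# identical are putative paralogs; single-linkage groups by identity.
#' @noRd
segregate_copies <- function(merged, cfg) {
  n <- nrow(merged)
  if (n <= 1) return(rep(1L, n))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      lo <- max(merged$start[i], merged$start[j])
      hi <- min(merged$start[i] + nchar(merged$seq[i]),
                merged$start[j] + nchar(merged$seq[j]))
      if (hi <= lo) next
      a <- substring(merged$seq[i], lo - merged$start[i] + 1L,
                     hi - merged$start[i])
      b <- substring(merged$seq[j], lo - merged$start[j] + 1L,
                     hi - merged$start[j])
      if (percent_identity(a, b) >= cfg$paralog_split_identity) {
        g <- igraph::add_edges(g, c(i, j))
      }
    }
  }
  comp <- igraph::components(g)$membership
  as.integer(match(comp, unique(comp)))
}

#' Merge contigs for every target/sample combination
#'
#' @param matches full tibble from [match_contigs()].
#' @param cfg a [run_config()].
#' @return Tibble binding each [merge_contigs()] result with `target_id`
#'   and `sample` columns; attribute `ambiguities` binds the per-set
#'   ambiguity tables.
#' @export
merge_all_contigs <- function(matches, cfg = run_config()) {
  key <- paste(matches$target_id, matches$sample, sep = "\r")
  parts <- lapply(split(seq_len(nrow(matches)), key), function(idx) {
    m <- merge_contigs(matches[idx, ], cfg = cfg)
    amb <- attr(m, "ambiguities")
    amb$target_id <- attr(m, "target_id")
    amb$sample <- attr(m, "sample")
    res <- tibble::as_tibble(m)
    res$target_id <- attr(m, "target_id")
    res$sample <- attr(m, "sample")
    list(res = res, amb = amb)
  })
  out <- dplyr::bind_rows(lapply(parts, `[[`, "res"))
  attr(out, "ambiguities") <- dplyr::bind_rows(lapply(parts, `[[`, "amb"))
  out
}

#' Remove alignment columns with indels or missing data
#'
#' Columns containing `-`, `N` or `?` in any row are excluded; row order
#' is preserved.
#'
#' @param alignment tibble with columns `id` and `seq`, all sequences the
#'   same length (gaps `-`, missing `N`/`?`).
#' @return The alignment with offending columns removed; attribute
#'   `removed` counts them.
#' @export
filter_alignment_columns <- function(alignment) {
  stopifnot(nrow(alignment) > 0)
  lens <- nchar(alignment$seq)
  if (length(unique(lens)) != 1) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(alignment$seq, ""))
  bad <- apply(m == "-" | m == "N" | m == "?", 2, any)
  kept <- m[, !bad, drop = FALSE]
  seqs <- if (ncol(kept) == 0) rep("", nrow(kept)) else
    apply(kept, 1, paste, collapse = "")
  out <- tibble::tibble(id = alignment$id, seq = seqs)
  attr(out, "removed") <- sum(bad)
  out
}

#' Per-marker variability
#'
#' Filters the alignment columns ([filter_alignment_columns()]), restricts
#' to the ingroup rows, and counts variable columns.  A column is variable
#' iff its row base-sets (IUPAC codes expanded) cannot be reconciled: the
#' intersection over all ingroup rows is empty.  A column of `{A, R}` is
#' therefore not variable (R is reconcilable with A), while `{A, G}` or
#' `{R, Y}` are.
#'
#' @param alignment tibble with `id`, `seq` (equal lengths); may still
#'   contain gap/missing columns, which are filtered out first.
#' @param ingroup ids of the rows over which variability is assessed; at
#'   least two must be present.
#' @param target_id optional label for the report.
#' @return One-row tibble: `target_id`, `aln_len_total`,
#'   `aln_len_filtered`, `n_variable`, `pct_variable` (fraction).
#' @export
variability <- function(alignment, ingroup = alignment$id, target_id = NA) {
  total <- nchar(alignment$seq[1])
  filt <- filter_alignment_columns(alignment)
  rows <- filt[filt$id %in% ingroup, ]
  if (nrow(rows) < 2) {
    stop("variability needs at least two ingroup rows", call. = FALSE)
  }
  width <- nchar(rows$seq[1])
  n_var <- 0L
  if (width > 0) {
    mats <- do.call(rbind, strsplit(rows$seq, ""))
    for (j in seq_len(width)) {
      sets <- strsplit(IUPAC_SETS[mats[, j]], "")
      inter <- Reduce(intersect, sets)
      if (length(inter) == 0) n_var <- n_var + 1L
    }
  }
  tibble::tibble(target_id = as.character(target_id),
                 aln_len_total = total,
                 aln_len_filtered = width,
                 n_variable = n_var,
                 pct_variable = if (width > 0) n_var / width else NA_real_)
}

#' Stack merged sequences into a coordinate alignment
#'
#' Builds a per-target alignment directly from coordinate placement: one
#' row per sample (the sample's first copy group merged sequence),
#' columns are target positions, positions a sample does not cover are
#' `N`.  Samples whose merged set still holds several sequences in the
#' first copy group contribute their longest one.  This is the trivially
#' alignable route used for synthetic data; empirically derived alignments
#' from an external aligner can be fed to [variability()] directly.
#'
#' @param merged tibble from [merge_all_contigs()] for one target.
#' @param target_len length of the target sequence, bp.
#' @return Alignment tibble (`id` = sample, `seq`).
#' @export
coordinate_alignment <- function(merged, target_len) {
  stopifnot(length(unique(merged$target_id)) == 1)
  rows <- lapply(split(merged, merged$sample), function(m) {
    m <- m[m$copy_group == m$copy_group[1], ]
    m <- m[order(-nchar(m$seq)), ][1, ]
    chars <- rep("N", target_len)
    pos <- seq(m$start, m$start + nchar(m$seq) - 1L)
    inside <- pos >= 0 & pos < target_len
    chars[pos[inside] + 1L] <- strsplit(m$seq, "")[[1]][inside]
    tibble::tibble(id = m$sample, seq = paste(chars, collapse = ""))
  })
  dplyr::bind_rows(rows)
}
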