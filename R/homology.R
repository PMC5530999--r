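# Local-similarity search: the contract BLASTn fulfils in the original
# pipeline.  `local_align` is the exact Smith-Waterman reference;
# `find_homologues` is the k-mer seeded production search.

#' @noRd
aln_to_row <- function(x) {
  bl <- x$blocks
  diag_cols <- if (nrow(bl)) sum(bl[, "q1"] - bl[, "q0"]) else 0L
  tibble::tibble(
    q_start = x$q_start, q_end = x$q_end,
    s_start = x$s_start, s_end = x$s_end,
    aln_len = x$aln_len, matches = x$matches,
    identity = x$matches / x$aln_len,
    score = x$score,
    gaps = x$aln_len - diag_cols,
    gap_opens = max(0L, nrow(bl) - 1L),
    blocks = list(bl)
  )
}

#' Optimal local alignment (exact Smith-Waterman)
#'
#' Gotoh affine-gap local alignment; the first base of a gap costs
#' `gap_open`, each further base `gap_ext`.  Ties between equal-scoring
#' optima are broken deterministically by smallest `q_start`, then
#' `s_start`.  Ambiguity codes (including N) never match.
#'
#' @param a,b non-empty nucleotide strings (query, subject).
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @return One-row tibble with 0-based half-open spans `q_start`, `q_end`,
#'   `s_start`, `s_end`, plus `aln_len` (alignment columns including gaps),
#'   `matches`, `identity` (= matches / aln_len), `score` and a `blocks`
#'   list column of gapless alignment blocks -- or `NULL` when no
#'   positive-scoring local alignment exists.
#' @examples
#' local_align("ACGTACGTACGT", "ACGTACGTACGT")
#' local_align("AAAA", "TTTT")  # NULL
#' @export
local_align <- function(a, b, match = 1L, mismatch = -1L,
                        gap_open = -2L, gap_ext = -1L) {
  stopifnot(nzchar(a), nzchar(b))
  x <- cpp_sw_align(toupper(a), toupper(b), match, mismatch, gap_open, gap_ext)
  if (!x$found) return(NULL)
  aln_to_row(x)
}

#' Global alignment percent identity
#'
#' Identity of the optimal global (Needleman-Wunsch) alignment with end
#' gaps penalised, defined as matches over alignment columns including
#' gaps.  This is the quantity the >= 75% similarity filter is applied to
#' when two full-length candidate homologues are compared.
#'
#' Among equal-scoring global alignments the traceback picks one
#' deterministically, so the pair is ordered canonically before aligning
#' to make the reported identity exactly symmetric.
#'
#' @inheritParams local_align
#' @return Fraction in \[0, 1\].
#' @examples
#' percent_identity("ACGT", "ACGA")  # 0.75
#' @export
percent_identity <- function(a, b, match = 1L, mismatch = -1L,
                             gap_open = -2L, gap_ext = -1L) {
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  x <- cpp_nw_stats(a, b, match, mismatch, gap_open, gap_ext)
  x$matches / x$aln_len
}

# Two-tier seeded search for one oriented pair: the primary pass uses the
# configured seed length; if it leaves at least min_hit_len of the query
# uncovered, a rescue pass with a shorter seed and an ungapped-extension
# prefilter sweeps up borderline (~75% identity) homologues the long seed
# can miss entirely.
#' @noRd
seeded_pair_hits <- function(qseq, sseq, cfg, min_hit_len = cfg$min_hit_len) {
  raw <- cpp_seeded_hits(qseq, sseq, cfg$seed_len, cfg$seed_band,
                         cfg$seed_max_gap, cfg$seed_pad, 0L,
                         cfg$match, cfg$mismatch, cfg$gap_open, cfg$gap_ext)
  hits <- if (length(raw) == 0) NULL else
    dplyr::bind_rows(lapply(raw, aln_to_row))
  covered <- if (is.null(hits)) 0L else
    interval_union_len(hits$q_start, hits$q_end)
  if (nchar(qseq) - covered >= min_hit_len && cfg$rescue_seed_len > 0) {
    raw2 <- cpp_seeded_hits(qseq, sseq, cfg$rescue_seed_len, cfg$rescue_band,
                            cfg$rescue_max_gap, cfg$seed_pad,
                            cfg$rescue_min_ungapped,
                            cfg$match, cfg$mismatch, cfg$gap_open, cfg$gap_ext)
    if (length(raw2) > 0) {
      hits <- dplyr::bind_rows(hits, dplyr::bind_rows(lapply(raw2, aln_to_row)))
    }
  }
  hits
}

# Split a hit at subject-side gaps >= split_gap (intron-scale deletions in
# the subject relative to the query); each run of blocks between such gaps
# becomes its own hit.
#' @noRd
split_hit_at_subject_gaps <- function(hit, split_gap) {
  bl <- hit$blocks[[1]]
  if (nrow(bl) <= 1) return(hit)
  sgap <- bl[-1, "s0"] - bl[-nrow(bl), "s1"]
  cut <- which(sgap >= split_gap)
  if (length(cut) == 0) return(hit)
  grp <- cumsum(c(0, as.integer(seq_len(nrow(bl) - 1) %in% cut)))
  parts <- lapply(split(seq_len(nrow(bl)), grp), function(idx) {
    sub <- bl[idx, , drop = FALSE]
    # alignment columns within this run: block widths plus internal gaps
    widths <- sum(sub[, "q1"] - sub[, "q0"])
    qg <- if (nrow(sub) > 1) sum(sub[-1, "q0"] - sub[-nrow(sub), "q1"]) else 0L
    sg <- if (nrow(sub) > 1) sum(sub[-1, "s0"] - sub[-nrow(sub), "s1"]) else 0L
    m <- sum(sub[, "matches"])
    al <- widths + qg + sg
    tibble::tibble(
      q_start = sub[1, "q0"], q_end = sub[nrow(sub), "q1"],
      s_start = sub[1, "s0"], s_end = sub[nrow(sub), "s1"],
      aln_len = al, matches = m, identity = m / al,
      score = NA_integer_, gaps = al - widths,
      gap_opens = max(0L, nrow(sub) - 1L), blocks = list(sub)
    )
  })
  out <- dplyr::bind_rows(parts)
  # rescore sub-hits under the same scheme (no terminal gaps by construction)
  out$score <- out$matches - (out$aln_len - out$gaps - out$matches) +
    ifelse(out$gaps > 0, -out$gap_opens - out$gaps, 0L)
  out
}

#' Seeded homology search
#'
#' K-mer seeded (default seed length 11) local search of every query
#' against both strands of every subject, with exact Smith-Waterman
#' realignment inside each seed-cluster window.  Multiple non-overlapping
#' hits of one query on one subject are reported separately (as needed for
#' exon mapping and copy-number calls); hits whose alignment crosses a
#' subject-side gap of intron scale (>= `cfg$min_intron_len`) are split at
#' the gap.
#'
#' @param queries,subjects sequence tibbles (see [seq_tbl()]).
#' @param min_identity minimum `matches / aln_len` for a reported hit;
#'   defaults to `cfg$min_identity`.
#' @param min_hit_len minimum aligned query span, bp.
#' @param cfg a [run_config()].
#' @param split_subject_gaps set `FALSE` to keep spliced hits intact.
#' @return Tibble of hits, one row each, sorted by `query_id` then
#'   descending `score`: `query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end` (0-based half-open, query always forward, subject
#'   coordinates on the forward strand), `strand` (subject strand),
#'   `aln_len`, `matches`, `identity`, `score`, `gaps`, `gap_opens` and a
#'   `blocks` list column.
#' @export
find_homologues <- function(queries, subjects,
                            min_identity = cfg$min_identity,
                            min_hit_len = cfg$min_hit_len,
                            cfg = run_config(),
                            split_subject_gaps = TRUE) {
  stopifnot(nrow(queries) > 0, nrow(subjects) > 0)
  res <- vector("list", nrow(queries) * nrow(subjects) * 2)
  k <- 0L
  for (qi in seq_len(nrow(queries))) {
    qseq <- queries$seq[qi]
    for (si in seq_len(nrow(subjects))) {
      slen <- nchar(subjects$seq[si])
      for (strand in c("+", "-")) {
        sseq <- if (strand == "+") subjects$seq[si] else revcomp(subjects$seq[si])
        hits <- seeded_pair_hits(qseq, sseq, cfg, min_hit_len = min_hit_len)
        if (is.null(hits)) next
        if (split_subject_gaps) {
          hits <- dplyr::bind_rows(lapply(
            split(hits, seq_len(nrow(hits))),
            split_hit_at_subject_gaps, split_gap = cfg$min_intron_len))
        }
        if (strand == "-") {
          s0 <- slen - hits$s_end
          hits$s_end <- slen - hits$s_start
          hits$s_start <- s0
          hits$blocks <- lapply(hits$blocks, function(bl) {
            if (nrow(bl) == 0) return(bl)
            new <- bl
            new[, "s0"] <- slen - bl[nrow(bl):1, "s1"]
            new[, "s1"] <- slen - bl[nrow(bl):1, "s0"]
            new[, "q0"] <- bl[nrow(bl):1, "q0"]
            new[, "q1"] <- bl[nrow(bl):1, "q1"]
            new[, "matches"] <- bl[nrow(bl):1, "matches"]
            new
          })
        }
        hits$query_id <- queries$id[qi]
        hits$subject_id <- subjects$id[si]
        hits$strand <- strand
        k <- k + 1L
        res[[k]] <- hits
      }
    }
  }
  if (k == 0L) return(empty_hits())
  out <- dplyr::bind_rows(res[seq_len(k)])
  out <- out[out$identity >= min_identity & (out$q_end - out$q_start) >= min_hit_len, ]
  if (nrow(out) == 0) return(empty_hits())
  out <- dedup_hits(out)
  out <- out[order(out$query_id, -out$score, out$subject_id, out$q_start, out$s_start), ]
  cols <- c("query_id", "subject_id", "q_start", "q_end", "s_start", "s_end",
            "strand", "aln_len", "matches", "identity", "score",
            "gaps", "gap_opens", "blocks")
  tibble::as_tibble(out[, cols])
}

#' @noRd
empty_hits <- function() {
  tibble::tibble(query_id = character(), subject_id = character(),
                 q_start = integer(), q_end = integer(),
                 s_start = integer(), s_end = integer(),
                 strand = character(), aln_len = integer(),
                 matches = integer(), identity = double(),
                 score = integer(), gaps = integer(), gap_opens = integer(),
                 blocks = list())
}

# Adjacent seed clusters can re-discover the same alignment; drop a hit when
# a higher-scoring hit of the same pair and strand overlaps it by more than
# half on both axes.
#' @noRd
dedup_hits <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  key <- paste(hits$query_id, hits$subject_id, hits$strand, sep = "\r")
  for (grp in split(seq_len(nrow(hits)), key)) {
    grp <- grp[order(-hits$score[grp], hits$q_start[grp], hits$s_start[grp])]
    kept <- integer(0)
    for (i in grp) {
      dup <- FALSE
      for (j in kept) {
        qo <- min(hits$q_end[i], hits$q_end[j]) - max(hits$q_start[i], hits$q_start[j])
        so <- min(hits$s_end[i], hits$s_end[j]) - max(hits$s_start[i], hits$s_start[j])
        qlen <- hits$q_end[i] - hits$q_start[i]
        slen <- hits$s_end[i] - hits$s_start[i]
        if (qo > 0.5 * qlen && so > 0.5 * slen) { dup <- TRUE; break }
      }
      if (dup) keep[i] <- FALSE else kept <- c(kept, i)
    }
  }
  hits[keep, ]
}
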