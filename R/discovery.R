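# Stage 1: find homologues shared by >= 2 transcriptomes, call copy number
# against WGS or a single-copy catalogue, apply the identity filter, and
# infer exon/intron structure by spliced mapping to the genome.

#' Length pre-filter
#'
#' Removes sequences strictly shorter than `min_len`; a sequence of exactly
#' `min_len` is retained.  Order is preserved.
#'
#' @param records sequence tibble.
#' @param min_len minimum length, bp.
#' @return Filtered sequence tibble.
#' @export
prefilter_by_length <- function(records, min_len) {
  records[nchar(records$seq) >= min_len, ]
}

#' Cluster homologous transcripts across transcriptomes
#'
#' Clusters are connected components of the graph whose edges connect
#' sequences of *different* sources that (i) share a local homology hit
#' (identity >= `min_identity`, aligned query span >= `min_hit_len`) and
#' (ii) are confirmed at >= `min_identity` full-length global identity --
#' the same quantity the similarity filter uses, so that a short
#' high-identity core in an otherwise diverged pair does not link it.
#' Each cross-source pair is aligned once, so edges are reciprocal by
#' construction.  Components spanning fewer than `min_shared` distinct
#' sources are discarded.
#' Within-source duplicates remain in the cluster (the copy-number call
#' inspects them).  The representative is the longest member (ties by
#' lexicographic id) and `min_pairwise_identity` is the minimum global
#' alignment identity over all member pairs -- the quantity the >= 75%
#' similarity filter is applied to.
#'
#' @param transcriptomes list of sequence tibbles, one per transcriptome,
#'   each with a distinct `source`.
#' @param min_identity,min_hit_len edge thresholds.
#' @param min_shared minimum number of distinct sources per cluster.
#' @param cfg a [run_config()] supplying defaults and alignment settings.
#' @return Tibble with `cluster_id`, `members` (list of tibbles with
#'   `source`, `id`, `seq`), `n_members`, `n_sources`,
#'   `representative_source`, `representative_id`, `representative_seq`,
#'   `min_pairwise_identity`, `intra_source_dup` (any same-source pair
#'   below `cfg$intra_source_identity` identity).
#' @export
cluster_homologues <- function(transcriptomes,
                               min_identity = cfg$min_identity,
                               min_hit_len = cfg$min_hit_len,
                               min_shared = cfg$min_shared_transcriptomes,
                               cfg = run_config()) {
  if (length(transcriptomes) < 2) {
    stop("at least two transcriptomes are required", call. = FALSE)
  }
  sources <- vapply(transcriptomes, function(x) x$source[1], "")
  if (anyDuplicated(sources)) {
    stop("transcriptome sources must be distinct", call. = FALSE)
  }
  all_seq <- dplyr::bind_rows(transcriptomes)
  all_seq$key <- paste(all_seq$source, all_seq$id, sep = "\r")
  edges <- list()
  for (i in seq_along(transcriptomes)) {
    for (j in seq_along(transcriptomes)) {
      if (i >= j) next
      hits <- find_homologues(transcriptomes[[i]], transcriptomes[[j]],
                              min_identity = min_identity,
                              min_hit_len = min_hit_len, cfg = cfg)
      if (nrow(hits) == 0) next
      pairs <- unique(hits[, c("query_id", "subject_id")])
      # confirm each candidate edge at full length
      confirmed <- vapply(seq_len(nrow(pairs)), function(p) {
        qs <- transcriptomes[[i]]$seq[match(pairs$query_id[p],
                                            transcriptomes[[i]]$id)]
        ss <- transcriptomes[[j]]$seq[match(pairs$subject_id[p],
                                            transcriptomes[[j]]$id)]
        percent_identity(qs, ss, cfg$match, cfg$mismatch,
                         cfg$gap_open, cfg$gap_ext) >= min_identity
      }, TRUE)
      pairs <- pairs[confirmed, ]
      if (nrow(pairs) == 0) next
      edges[[length(edges) + 1L]] <- tibble::tibble(
        from = paste(sources[i], pairs$query_id, sep = "\r"),
        to = paste(sources[j], pairs$subject_id, sep = "\r"))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(all_seq), name = all_seq$key)
  if (length(edges) > 0) {
    e <- unique(dplyr::bind_rows(edges))
    g <- igraph::add_edges(g, rbind(e$from, e$to))
  }
  comp <- igraph::components(g)
  all_seq$component <- comp$membership[all_seq$key]
  clusters <- lapply(split(all_seq, all_seq$component), function(mem) {
    if (length(unique(mem$source)) < min_shared) return(NULL)
    o <- order(-nchar(mem$seq), mem$id)
    rep_row <- mem[o[1], ]
    n <- nrow(mem)
    pid <- 1
    intra_dup <- FALSE
    for (a in seq_len(n - 1)) {
      for (b in seq(a + 1, n)) {
        p <- percent_identity(mem$seq[a], mem$seq[b],
                              cfg$match, cfg$mismatch, cfg$gap_open, cfg$gap_ext)
        pid <- min(pid, p)
        if (mem$source[a] == mem$source[b] && p < cfg$intra_source_identity) {
          intra_dup <- TRUE
        }
      }
    }
    tibble::tibble(
      members = list(mem[, c("source", "id", "seq")]),
      n_members = n,
      n_sources = length(unique(mem$source)),
      representative_source = rep_row$source,
      representative_id = rep_row$id,
      representative_seq = rep_row$seq,
      min_pairwise_identity = pid,
      intra_source_dup = intra_dup
    )
  })
  clusters <- dplyr::bind_rows(clusters)
  if (nrow(clusters) == 0) {
    return(tibble::tibble(cluster_id = character(), members = list(),
                          n_members = integer(), n_sources = integer(),
                          representative_source = character(),
                          representative_id = character(),
                          representative_seq = character(),
                          min_pairwise_identity = double(),
                          intra_source_dup = logical()))
  }
  clusters <- clusters[order(clusters$representative_id,
                             clusters$representative_source), ]
  clusters$cluster_id <- sprintf("cluster_%s", clusters$representative_id)
  dup <- duplicated(clusters$cluster_id)
  if (any(dup)) {
    clusters$cluster_id <- make.unique(clusters$cluster_id, sep = "_")
  }
  dplyr::relocate(clusters, "cluster_id")
}

#' @noRd
chain_loci <- function(hits, cfg) {
  # group hits on one genome into loci: same subject sequence, hits closer
  # than locus_merge_gap on the genome are one locus (strand-agnostic, so an
  # inverted duplication still counts as one place in the genome)
  hits <- hits[order(hits$subject_id, hits$s_start), ]
  locus <- integer(nrow(hits))
  cur <- 0L
  last_end <- -Inf
  last_subj <- ""
  for (i in seq_len(nrow(hits))) {
    if (hits$subject_id[i] != last_subj ||
        hits$s_start[i] - last_end > cfg$locus_merge_gap) {
      cur <- cur + 1L
      last_end <- hits$s_end[i]
    } else {
      last_end <- max(last_end, hits$s_end[i])
    }
    last_subj <- hits$subject_id[i]
    locus[i] <- cur
  }
  hits$locus <- locus
  hits
}

#' Call copy number for a homologue cluster
#'
#' WGS route: the representative is mapped to the genome and distinct
#' genomic loci are counted (hit chains separated by more than
#' `cfg$locus_merge_gap` bp, or on different genome sequences); a locus
#' counts when its chained identity is >= `cfg$min_identity` and it covers
#' >= 50% of the query.  One locus is `single`, two or more `multi`.
#' Catalogue route: `single` iff the best catalogue match (identity >=
#' `cfg$catalogue_min_identity`) is flagged single/mostly-single copy and
#' the second-best match scores below 0.9 x the best; `unknown` when
#' nothing in the catalogue matches.  Independently of the route, a cluster
#' holding two members of one transcriptome source below
#' `cfg$intra_source_identity` identity is `multi`.
#'
#' @param cluster one row of the tibble from [cluster_homologues()].
#' @param genome sequence tibble of genome/WGS contigs, or `NULL`.
#' @param catalogue catalogue tibble from [read_catalogue()], or `NULL`.
#' @param cfg a [run_config()].
#' @return `"single"`, `"multi"` or `"unknown"`.
#' @export
call_copy_number <- function(cluster, genome = NULL, catalogue = NULL,
                             cfg = run_config()) {
  if (is.null(genome) && is.null(catalogue)) {
    stop("copy-number calling needs a genome or a single-copy catalogue",
         call. = FALSE)
  }
  if (isTRUE(cluster$intra_source_dup)) return("multi")
  rep_tbl <- seq_tbl(cluster$representative_id, cluster$representative_seq,
                     source = cluster$representative_source)
  qlen <- nchar(cluster$representative_seq)
  if (!is.null(genome)) {
    # a duplicate locus diverged from the genome's own taxon can fall below
    # the identity floor for a distant cluster member while the conspecific
    # member still sees it, so every member is mapped: any member finding
    # two qualifying loci makes the cluster multi copy
    mem <- if (!is.null(cluster$members)) cluster$members[[1]] else
      tibble::tibble(source = cluster$representative_source,
                     id = cluster$representative_id,
                     seq = cluster$representative_seq)
    mem <- mem[order(mem$source, mem$id), ]
    n_loci_all <- vapply(seq_len(nrow(mem)), function(k) {
      qtbl <- seq_tbl(mem$id[k], mem$seq[k], source = mem$source[k])
      ql <- nchar(mem$seq[k])
      hits <- find_homologues(qtbl, genome, min_identity = cfg$min_identity,
                              min_hit_len = min(cfg$min_hit_len, ql), cfg = cfg)
      if (nrow(hits) == 0) return(0L)
      hits <- chain_loci(hits, cfg)
      good <- vapply(split(hits, hits$locus), function(h) {
        ident <- sum(h$matches) / sum(h$aln_len)
        cov <- interval_union_len(h$q_start, h$q_end) / ql
        ident >= cfg$min_identity && cov >= 0.5
      }, TRUE)
      sum(good)
    }, 1L)
    if (any(n_loci_all >= 2)) return("multi")
    if (any(n_loci_all == 1)) return("single")
    return("unknown")
  }
  hits <- find_homologues(rep_tbl, catalogue,
                          min_identity = cfg$catalogue_min_identity,
                          min_hit_len = min(cfg$min_hit_len, qlen), cfg = cfg)
  if (nrow(hits) == 0) return("unknown")
  by_subj <- dplyr::summarise(dplyr::group_by(hits, .data$subject_id),
                              score = max(.data$score), .groups = "drop")
  by_subj <- by_subj[order(-by_subj$score, by_subj$subject_id), ]
  best <- by_subj$subject_id[1]
  best_single <- catalogue$single_copy[match(best, catalogue$id)]
  second_ok <- nrow(by_subj) < 2 || by_subj$score[2] < 0.9 * by_subj$score[1]
  if (isTRUE(best_single) && second_ok) "single" else "multi"
}

#' Infer an exon/intron gene model by spliced mapping
#'
#' Maps a transcript to its genomic locus and chains homology hits into a
#' maximal colinear spliced alignment (same genome sequence and strand,
#' non-overlapping and monotone in both coordinate systems, maximising
#' total matched bases; ties broken by leftmost genomic start).  Chained
#' hit intervals on the genome become exons; inter-exon genomic gaps
#' >= `cfg$min_intron_len` become introns, while smaller gaps are absorbed
#' into a single exon.  The model is rejected (returns `NULL`) when more
#' than `cfg$max_unaligned_gap` bp of transcript remain unaligned inside or
#' at the ends of the chain.
#'
#' @param transcript one-row sequence tibble (or a row of a cluster
#'   representative).
#' @param genome sequence tibble of genome contigs.
#' @param cfg a [run_config()].
#' @return A list with `genome_id`, `strand`, `exons` (integer matrix,
#'   columns `g_start`, `g_end`, 0-based half-open, ascending),
#'   `exons_q` (matching transcript intervals), `introns` (matrix),
#'   `intron_lens`, `exon_len_total` -- or `NULL`.
#' @export
infer_gene_model <- function(transcript, genome, cfg = run_config()) {
  qlen <- nchar(transcript$seq[1])
  hits <- find_homologues(transcript[1, ], genome,
                          min_identity = cfg$min_identity,
                          min_hit_len = min(50L, qlen), cfg = cfg)
  if (nrow(hits) == 0) return(NULL)
  hits <- chain_loci(hits, cfg)
  # pick the locus with most matched bases, ties by leftmost genomic start
  stats <- dplyr::summarise(dplyr::group_by(hits, .data$locus),
                            matches = sum(.data$matches),
                            subject_id = .data$subject_id[1],
                            s_min = min(.data$s_start), .groups = "drop")
  stats <- stats[order(-stats$matches, stats$subject_id, stats$s_min), ]
  h <- hits[hits$locus == stats$locus[1], ]
  # within the locus, chain per strand and keep the better chain
  best <- NULL
  for (strand in unique(h$strand)) {
    hs <- h[h$strand == strand, ]
    chain <- chain_colinear(hs, strand)
    if (is.null(best) || chain$matches > best$matches ||
        (chain$matches == best$matches && chain$s_min < best$s_min)) {
      best <- chain
      best$strand <- strand
    }
  }
  ch <- best$hits
  gseq <- genome$seq[match(ch$subject_id[1], genome$id)]
  ch <- refine_junctions(ch, best$strand, transcript$seq[1], gseq)
  if (isTRUE(attr(ch, "bad_junction"))) return(NULL)
  # transcript-side unaligned gaps: chain-internal plus both ends
  qgaps <- c(min(ch$q_start), qlen - max(ch$q_end))
  if (nrow(ch) > 1) {
    o <- order(ch$q_start)
    qgaps <- c(qgaps, ch$q_start[o][-1] - ch$q_end[o][-nrow(ch)])
  }
  if (max(qgaps) > cfg$max_unaligned_gap) return(NULL)
  o <- order(ch$s_start)
  g0 <- ch$s_start[o]; g1 <- ch$s_end[o]
  q0 <- ch$q_start[o]; q1 <- ch$q_end[o]
  # absorb genomic gaps shorter than min_intron_len into one exon
  ex <- list(c(g0[1], g1[1], q0[1], q1[1]))
  if (length(g0) > 1) {
    for (i in seq(2, length(g0))) {
      prev <- ex[[length(ex)]]
      if (g0[i] - prev[2] < cfg$min_intron_len) {
        ex[[length(ex)]] <- c(prev[1], g1[i], min(prev[3], q0[i]), max(prev[4], q1[i]))
      } else {
        ex[[length(ex)]] <- prev
        ex[[length(ex) + 1L]] <- c(g0[i], g1[i], q0[i], q1[i])
      }
    }
  }
  ex <- do.call(rbind, ex)
  exons <- ex[, 1:2, drop = FALSE]
  colnames(exons) <- c("g_start", "g_end")
  exons_q <- ex[, 3:4, drop = FALSE]
  colnames(exons_q) <- c("q_start", "q_end")
  n_ex <- nrow(exons)
  introns <- if (n_ex > 1) {
    cbind(g_start = exons[-n_ex, "g_end"], g_end = exons[-1, "g_start"])
  } else {
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("g_start", "g_end")))
  }
  list(genome_id = ch$subject_id[1],
       strand = best$strand,
       exons = exons,
       exons_q = exons_q,
       introns = introns,
       intron_lens = as.integer(introns[, "g_end"] - introns[, "g_start"]),
       exon_len_total = as.integer(sum(exons[, "g_end"] - exons[, "g_start"])),
       chain_matches = as.integer(best$matches))
}

# Maximum-matches colinear chain of hits on one strand of one locus.
# Adjacent exon hits can overlap on the transcript: the local aligner
# keeps any net-positive tail, and against intron sequence a gapped tail of
# up to roughly the seed-window padding can stay net-positive.  Overlaps up
# to `tol` (set to twice the window padding) are therefore allowed and
# discounted; the true boundary is restored afterwards by
# refine_junctions().
#' @noRd
chain_colinear <- function(hs, strand, tol = 400L) {
  hs <- hs[order(hs$q_start, hs$s_start), ]
  n <- nrow(hs)
  score <- hs$matches
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      qo <- hs$q_end[j] - hs$q_start[i]
      ok_q <- qo <= tol
      ok_s <- if (strand == "+") hs$s_start[i] >= hs$s_end[j]
              else hs$s_end[i] <= hs$s_start[j]
      gain <- hs$matches[i] - max(0L, qo)
      if (ok_q && ok_s && score[j] + gain > score[i]) {
        score[i] <- score[j] + gain
        prev[i] <- j
      }
    }
  }
  end <- which.max(score)
  idx <- integer(0)
  while (end != 0L) {
    idx <- c(end, idx)
    end <- prev[end]
  }
  list(hits = hs[idx, ], matches = max(score), s_min = min(hs$s_start[idx]))
}

# Resolve the boundary at each junction between consecutive chained hits.
# A local aligner keeps any net-positive tail, so a hit can carry a short
# spurious (possibly gapped) extension across the exon boundary, and the
# as-aligned path may even misroute the last true exon bases.  Each side
# is therefore re-anchored in its nearest solid gapless block (>=
# `anchor_min` columns) and a single boundary m is chosen on the straight
# diagonals projected from those anchors, maximising the joint score
# (+1 per matching transcript/genome base, -1 otherwise; left diagonal
# left of m, right diagonal from m on).  When the intron bases adjacent
# to a junction differ from the exon continuation -- the recognisable
# boundary real splice sites provide -- this optimum is unique and equals
# the true junction.
#' @noRd
refine_junctions <- function(ch, strand, tseq, gseq,
                             anchor_min = 15L, margin = 150L) {
  if (nrow(ch) < 2) return(ch)
  ch <- ch[order(ch$q_start), ]
  glen <- nchar(gseq)
  tlen <- nchar(tseq)
  gbase <- function(g) {
    b <- substr(gseq, g + 1L, g + 1L)
    if (strand == "-") chartr("ACGT", "TGCA", b) else b
  }
  for (i in seq(2, nrow(ch))) {
    j <- i - 1L
    blj <- ch$blocks[[j]]
    blj <- blj[order(blj[, "q0"]), , drop = FALSE]
    bli <- ch$blocks[[i]]
    bli <- bli[order(bli[, "q0"]), , drop = FALSE]
    wj <- blj[, "q1"] - blj[, "q0"]
    wi <- bli[, "q1"] - bli[, "q0"]
    # an anchor must be a block that is long AND nearly all matches -- a
    # wide diagonal run inside a spurious extension still has random
    # (~25%) identity and would project a junk diagonal
    solid_j <- wj >= anchor_min & blj[, "matches"] >= 0.9 * wj
    solid_i <- wi >= anchor_min & bli[, "matches"] >= 0.9 * wi
    rL <- if (any(solid_j)) max(which(solid_j)) else
      which.max(2L * blj[, "matches"] - wj)
    rR <- if (any(solid_i)) min(which(solid_i)) else
      which.max(2L * bli[, "matches"] - wi)
    # straight diagonals through the anchor blocks
    diagL <- function(t) {
      if (strand == "+") blj[rL, "s0"] + (t - blj[rL, "q0"])
      else blj[rL, "s1"] - 1L - (t - blj[rL, "q0"])
    }
    diagR <- function(t) {
      if (strand == "+") bli[rR, "s0"] + (t - bli[rR, "q0"])
      else bli[rR, "s1"] - 1L - (t - bli[rR, "q0"])
    }
    lo <- max(blj[rL, "q0"] + 1L,
              min(blj[rL, "q1"], bli[rR, "q0"]) - margin, 0L)
    hi <- min(bli[rR, "q1"] - 1L,
              max(blj[rL, "q1"], bli[rR, "q0"]) + margin, tlen)
    if (hi < lo) next
    score_at <- function(t, g) {
      if (g < 0 || g >= glen) return(-1)
      if (substr(tseq, t + 1L, t + 1L) == gbase(g)) 1 else -1
    }
    if (hi > lo) {
      ts <- seq(lo, hi - 1L)
      sL <- vapply(ts, function(t) score_at(t, diagL(t)), 0)
      sR <- vapply(ts, function(t) score_at(t, diagR(t)), 0)
      # J(m) = sum(sL[t < m]) + sum(sR[t >= m]); argmax, ties -> smallest m
      J <- c(0, cumsum(sL)) + rev(c(0, cumsum(rev(sR))))
      m <- (lo:hi)[which.max(J)]
    } else {
      m <- lo
    }
    # junction quality: a true boundary has a well-matching left diagonal
    # just before m and right diagonal just after; if either flank is junk
    # (random-level identity) the chain bridged a hole in the structure
    flankL <- vapply(seq(max(lo, m - 15L), m - 1L),
                     function(t) score_at(t, diagL(t)), 0)
    flankR <- vapply(seq(m, min(hi - 1L, m + 14L)),
                     function(t) score_at(t, diagR(t)), 0)
    if (mean(flankL) < 0.2 || mean(flankR) < 0.2) {
      attr(ch, "bad_junction") <- TRUE
      return(ch)
    }
    ch$q_end[j] <- m
    if (strand == "+") ch$s_end[j] <- diagL(m - 1L) + 1L
    else ch$s_start[j] <- diagL(m - 1L)
    ch$q_start[i] <- m
    if (strand == "+") ch$s_start[i] <- diagR(m)
    else ch$s_end[i] <- diagR(m) + 1L
  }
  ch
}

#' Discover candidate markers
#'
#' Runs the full first stage: length pre-filter, cross-transcriptome
#' clustering, copy-number calling (multi-copy clusters excluded),
#' similarity filter (clusters whose minimum pairwise identity falls below
#' `cfg$min_identity` excluded), then spliced gene-model inference against
#' the genome when one is supplied.  Output order is deterministic by
#' `marker_id`.
#'
#' @param transcriptomes list of sequence tibbles, one per transcriptome.
#' @param genome sequence tibble of genome/WGS contigs, or `NULL`.
#' @param catalogue catalogue tibble ([read_catalogue()]), or `NULL`.
#'   At least one of `genome`/`catalogue` must be given.
#' @param cfg a [run_config()].
#' @return Tibble of marker candidates: `marker_id`, representative
#'   `source`/`id`/`seq`, `n_members`, `n_sources`,
#'   `min_pairwise_identity`, `copy_number` (always `"single"` here),
#'   `has_model`, `genome_id`, `strand`, `exons`, `exons_q`, `introns`
#'   (list columns), `intron_lens` (list column), `exon_len_total`,
#'   `n_introns`.  Candidates without a gene model keep their full
#'   transcript as a single exon.
#' @export
discover_markers <- function(transcriptomes, genome = NULL, catalogue = NULL,
                             cfg = run_config()) {
  if (is.null(genome) && is.null(catalogue)) {
    stop("discover_markers() needs a genome or a single-copy catalogue",
         call. = FALSE)
  }
  if (length(transcriptomes) < 2) {
    stop("at least two transcriptomes are required", call. = FALSE)
  }
  transcriptomes <- lapply(transcriptomes, prefilter_by_length,
                           min_len = cfg$min_transcript_len)
  transcriptomes <- transcriptomes[vapply(transcriptomes, nrow, 1L) > 0]
  if (length(transcriptomes) < 2) {
    return(empty_candidates())
  }
  clusters <- cluster_homologues(transcriptomes, cfg = cfg)
  if (nrow(clusters) == 0) return(empty_candidates())
  copy <- vapply(seq_len(nrow(clusters)), function(i) {
    call_copy_number(clusters[i, ], genome = genome, catalogue = catalogue,
                     cfg = cfg)
  }, "")
  clusters$copy_number <- copy
  keep <- clusters$copy_number == "single" &
    clusters$min_pairwise_identity >= cfg$min_identity
  clusters <- clusters[keep, ]
  if (nrow(clusters) == 0) return(empty_candidates())
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    # the gene model is inferred from the cluster member whose genomic
    # mapping is strongest (most matched bases) -- the member from the same
    # taxon as the WGS maps cleanly, diverged members lose exon edges; that
    # member also becomes the emitted target sequence, so bait coordinates
    # refer to a sequence the model actually describes
    model <- NULL
    tgt <- list(source = cl$representative_source,
                id = cl$representative_id,
                seq = cl$representative_seq)
    if (!is.null(genome)) {
      mem <- cl$members[[1]]
      mem <- mem[order(-nchar(mem$seq), mem$source, mem$id), ]
      for (k in seq_len(nrow(mem))) {
        m <- infer_gene_model(seq_tbl(mem$id[k], mem$seq[k],
                                      source = mem$source[k]),
                              genome, cfg = cfg)
        if (!is.null(m) &&
            (is.null(model) || m$chain_matches > model$chain_matches)) {
          model <- m
          tgt <- list(source = mem$source[k], id = mem$id[k], seq = mem$seq[k])
        }
      }
    }
    seqlen <- nchar(tgt$seq)
    if (is.null(model)) {
      tibble::tibble(
        marker_id = cl$representative_id,
        source = tgt$source,
        id = tgt$id,
        seq = tgt$seq,
        n_members = cl$n_members,
        n_sources = cl$n_sources,
        min_pairwise_identity = cl$min_pairwise_identity,
        copy_number = cl$copy_number,
        has_model = FALSE,
        genome_id = NA_character_,
        strand = NA_character_,
        exons = list(NULL),
        exons_q = list(cbind(q_start = 0L, q_end = seqlen)),
        introns = list(NULL),
        intron_lens = list(integer(0)),
        exon_len_total = seqlen,
        n_introns = 0L
      )
    } else {
      tibble::tibble(
        marker_id = cl$representative_id,
        source = tgt$source,
        id = tgt$id,
        seq = tgt$seq,
        n_members = cl$n_members,
        n_sources = cl$n_sources,
        min_pairwise_identity = cl$min_pairwise_identity,
        copy_number = cl$copy_number,
        has_model = TRUE,
        genome_id = model$genome_id,
        strand = model$strand,
        exons = list(model$exons),
        exons_q = list(model$exons_q),
        introns = list(model$introns),
        intron_lens = list(model$intron_lens),
        exon_len_total = model$exon_len_total,
        n_introns = length(model$intron_lens)
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$marker_id), ]
}

#' @noRd
empty_candidates <- function() {
  tibble::tibble(marker_id = character(), source = character(),
                 id = character(), seq = character(), n_members = integer(),
                 n_sources = integer(), min_pairwise_identity = double(),
                 copy_number = character(), has_model = logical(),
                 genome_id = character(), strand = character(),
                 exons = list(), exons_q = list(), introns = list(),
                 intron_lens = list(), exon_len_total = integer(),
                 n_introns = integer())
}
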