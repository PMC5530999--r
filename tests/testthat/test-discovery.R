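# Small, fast fixtures; the full default study fixture is exercised in
# test-acceptance.R.

fast_cfg <- function(...) {
  run_config(min_transcript_len = 0L, min_hit_len = 60L, ...)
}

test_that("length pre-filter keeps sequences of exactly the threshold", {
  set.seed(1)
  recs <- seq_tbl(c("a", "b", "c"),
                  vapply(c(999, 1000, 1001), rand_dna, ""), source = "t1")
  kept <- prefilter_by_length(recs, 1000)
  expect_equal(kept$id, c("b", "c"))
  expect_equal(prefilter_by_length(recs, 0)$id, recs$id)
  expect_equal(nrow(prefilter_by_length(recs[0, ], 10)), 0L)
})

test_that("homologue clustering joins shared genes and drops private ones", {
  set.seed(2)
  shared <- rand_dna(300)
  t1 <- seq_tbl(c("g1", "p1"), c(shared, rand_dna(300)), source = "t1")
  t2 <- seq_tbl("g1", substitute_k(shared, 30), source = "t2")
  cl <- cluster_homologues(list(t1, t2), cfg = fast_cfg())
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 2L)
  expect_equal(cl$n_sources, 2L)
  expect_gt(cl$min_pairwise_identity, 0.85)
  expect_error(cluster_homologues(list(t1)), "at least two")
})

test_that("clustering matches brute-force exact-alignment components", {
  set.seed(3)
  n_core <- 5
  cores <- replicate(n_core, rand_dna(150))
  tr <- lapply(1:3, function(t) {
    ids <- sprintf("g%d", seq_len(n_core))
    seqs <- vapply(cores, function(s) substitute_k(s, 15), "")
    # one private gene per transcriptome
    seq_tbl(c(ids, "priv"), c(seqs, rand_dna(150)),
            source = sprintf("t%d", t))
  })
  cl <- cluster_homologues(tr, cfg = fast_cfg())
  expect_equal(nrow(cl), n_core)
  expect_true(all(cl$n_sources == 3))
  # brute force: pure-R local score over all cross-source pairs, an edge
  # where score implies identity >= 0.75 over >= 60 aligned columns
  all_seq <- dplyr::bind_rows(tr)
  n <- nrow(all_seq)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (all_seq$source[i] == all_seq$source[j]) next
      sc <- r_local_score(all_seq$seq[i], all_seq$seq[j])
      # planted homologues at 80% identity over 150 bp score >= 75;
      # unrelated 150-mers stay far below
      adj[i, j] <- adj[j, i] <- sc >= 60
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- table(comp$membership)
  expect_equal(sum(sizes == 3), n_core)
  expect_equal(sum(sizes == 1), 3)
})

test_that("copy number is single for one locus, multi for a planted duplicate", {
  set.seed(4)
  gene <- rand_dna(600)
  t1 <- seq_tbl("g", gene, source = "t1")
  t2 <- seq_tbl("g", substitute_k(gene, 30), source = "t2")
  cfg <- fast_cfg()
  cl <- cluster_homologues(list(t1, t2), cfg = cfg)

  genome1 <- seq_tbl("chr1", paste0(rand_dna(400), gene, rand_dna(400)),
                     source = "wgs", role = "genomic")
  expect_equal(call_copy_number(cl[1, ], genome = genome1, cfg = cfg),
               "single")

  dup <- substitute_k(gene, 90)  # 85% identity duplicate
  genome2 <- seq_tbl(c("chr1", "chr2"),
                     c(paste0(rand_dna(400), gene, rand_dna(400)),
                       paste0(rand_dna(300), dup, rand_dna(300))),
                     source = "wgs", role = "genomic")
  expect_equal(call_copy_number(cl[1, ], genome = genome2, cfg = cfg),
               "multi")
  expect_error(call_copy_number(cl[1, ], cfg = cfg), "genome or")
})

test_that("intra-source duplicates below 99% identity flag a cluster multi", {
  set.seed(5)
  gene <- rand_dna(400)
  t1 <- seq_tbl(c("gA", "gB"), c(gene, substitute_k(gene, 20)), source = "t1")
  t2 <- seq_tbl("g", substitute_k(gene, 20), source = "t2")
  cfg <- fast_cfg()
  cl <- cluster_homologues(list(t1, t2), cfg = cfg)
  expect_equal(nrow(cl), 1L)
  expect_true(cl$intra_source_dup)
  genome <- seq_tbl("chr1", paste0(rand_dna(300), gene, rand_dna(300)),
                    source = "wgs", role = "genomic")
  expect_equal(call_copy_number(cl[1, ], genome = genome, cfg = cfg), "multi")
})

test_that("catalogue route follows the single-copy flag and best-match margin", {
  set.seed(6)
  gene <- rand_dna(500)
  t1 <- seq_tbl("g", gene, source = "t1")
  t2 <- seq_tbl("g", substitute_k(gene, 25), source = "t2")
  cfg <- fast_cfg()
  cl <- cluster_homologues(list(t1, t2), cfg = cfg)

  cat_single <- seq_tbl(c("ref1", "other"),
                        c(substitute_k(gene, 75), rand_dna(500)),
                        source = "catalogue", role = "target")
  cat_single$single_copy <- c(TRUE, FALSE)
  expect_equal(call_copy_number(cl[1, ], catalogue = cat_single, cfg = cfg),
               "single")

  cat_multi <- cat_single
  cat_multi$single_copy <- c(FALSE, FALSE)
  expect_equal(call_copy_number(cl[1, ], catalogue = cat_multi, cfg = cfg),
               "multi")

  # a second catalogue gene nearly as similar: ambiguous, called multi
  cat_close <- seq_tbl(c("ref1", "ref2"),
                       c(substitute_k(gene, 75), substitute_k(gene, 80)),
                       source = "catalogue", role = "target")
  cat_close$single_copy <- c(TRUE, TRUE)
  expect_equal(call_copy_number(cl[1, ], catalogue = cat_close, cfg = cfg),
               "multi")

  cat_none <- seq_tbl("refX", rand_dna(500), source = "catalogue",
                      role = "target")
  cat_none$single_copy <- TRUE
  expect_equal(call_copy_number(cl[1, ], catalogue = cat_none, cfg = cfg),
               "unknown")
})

test_that("a contiguous genomic substring maps to one exon and no introns", {
  set.seed(7)
  tr <- rand_dna(500)
  genome <- seq_tbl("chr1", paste0(rand_dna(300), tr, rand_dna(300)),
                    source = "wgs", role = "genomic")
  m <- infer_gene_model(seq_tbl("t", tr, source = "t1"), genome, fast_cfg())
  expect_equal(nrow(m$exons), 1L)
  expect_equal(length(m$intron_lens), 0L)
  expect_equal(m$exons[1, "g_start"], c(g_start = 300L))
  expect_equal(m$exon_len_total, 500L)
})

# Build a spliced gene on a chosen strand with junction-distinguishable
# intron ends, and return transcript + genome.
plant_gene <- function(exon_lens, intron_lens, strand = "+", flank = 300) {
  exons <- lapply(exon_lens, rand_dna)
  parts <- character(0)
  for (k in seq_along(exons)) {
    parts <- c(parts, exons[[k]])
    if (k < length(exons)) {
      intr <- strsplit(rand_dna(intron_lens[k]), "")[[1]]
      intr[1] <- setdiff(c("A", "C", "G", "T"),
                         substr(exons[[k + 1]], 1, 1))[1]
      intr[length(intr)] <- setdiff(c("A", "C", "G", "T"),
                                    substr(exons[[k]], nchar(exons[[k]]),
                                           nchar(exons[[k]])))[1]
      parts <- c(parts, paste(intr, collapse = ""))
    }
  }
  gene_genomic <- paste(parts, collapse = "")
  placed <- if (strand == "+") gene_genomic else revcomp(gene_genomic)
  list(transcript = paste(unlist(exons), collapse = ""),
       genome = seq_tbl("chr1", paste0(rand_dna(flank), placed,
                                       rand_dna(flank)),
                        source = "wgs", role = "genomic"))
}

test_that("planted multi-exon structures are recovered exactly on both strands", {
  set.seed(8)
  for (strand in c("+", "-")) {
    g <- plant_gene(c(400L, 150L, 500L), c(250L, 800L), strand = strand)
    m <- infer_gene_model(seq_tbl("t", g$transcript, source = "t1"),
                          g$genome, fast_cfg())
    expect_false(is.null(m))
    expect_equal(m$strand, strand)
    lens <- m$exons[, "g_end"] - m$exons[, "g_start"]
    if (strand == "-") lens <- rev(lens)
    expect_equal(unname(as.integer(lens)), c(400L, 150L, 500L))
    ilens <- if (strand == "-") rev(m$intron_lens) else m$intron_lens
    expect_equal(as.integer(ilens), c(250L, 800L))
    expect_equal(m$exon_len_total, 1050L)
  }
})

test_that("a genomic gap below the intron floor is absorbed into one exon", {
  set.seed(9)
  g <- plant_gene(c(400L, 500L), 10L)
  m <- infer_gene_model(seq_tbl("t", g$transcript, source = "t1"),
                        g$genome, fast_cfg())
  expect_equal(nrow(m$exons), 1L)
  expect_equal(length(m$intron_lens), 0L)
  # the absorbed gap widens the genomic exon by the 10 skipped bases
  expect_equal(unname(m$exons[1, "g_end"] - m$exons[1, "g_start"]), 910L)
})

test_that("discovery on identical transcriptomes with a catalogue keeps all genes", {
  set.seed(10)
  genes <- replicate(4, rand_dna(400))
  t1 <- seq_tbl(sprintf("g%d", 1:4), genes, source = "t1")
  t2 <- seq_tbl(sprintf("g%d", 1:4), genes, source = "t2")
  cat <- seq_tbl(sprintf("ref%d", 1:4),
                 vapply(genes, function(s) substitute_k(s, 60), ""),
                 source = "catalogue", role = "target")
  cat$single_copy <- TRUE
  cand <- discover_markers(list(t1, t2), catalogue = cat, cfg = fast_cfg())
  expect_equal(sort(cand$marker_id), sprintf("g%d", 1:4))
  expect_true(all(cand$copy_number == "single"))
  expect_false(any(cand$has_model))

  # disjoint transcriptomes share nothing
  t3 <- seq_tbl("x1", rand_dna(400), source = "t3")
  none <- discover_markers(list(t1, t3), catalogue = cat, cfg = fast_cfg())
  expect_equal(nrow(none), 0L)
  expect_error(discover_markers(list(t1), catalogue = cat), "at least two")
  expect_error(discover_markers(list(t1, t2)), "genome or")
})

test_that("discovery output is invariant to input record order", {
  set.seed(12)
  genes <- replicate(3, rand_dna(350))
  mk <- function(src, perm) {
    seq_tbl(sprintf("g%d", 1:3)[perm],
            vapply(genes, function(s) substitute_k(s, 25), "")[perm],
            source = src)
  }
  cat <- seq_tbl(sprintf("ref%d", 1:3),
                 vapply(genes, function(s) substitute_k(s, 50), ""),
                 source = "catalogue", role = "target")
  cat$single_copy <- TRUE
  set.seed(13)
  a <- discover_markers(list(mk("t1", 1:3), mk("t2", 1:3)),
                        catalogue = cat, cfg = fast_cfg())
  set.seed(13)
  b <- discover_markers(list(mk("t1", c(3, 1, 2)), mk("t2", c(2, 3, 1))),
                        catalogue = cat, cfg = fast_cfg())
  expect_equal(a$marker_id, b$marker_id)
  expect_equal(a$copy_number, b$copy_number)
})

test_that("raising the identity floor never adds candidates", {
  set.seed(14)
  genes <- replicate(4, rand_dna(300))
  divs <- c(15, 40, 70, 90)  # 95%..70% planted identity
  t1 <- seq_tbl(sprintf("g%d", 1:4), genes, source = "t1")
  t2 <- seq_tbl(sprintf("g%d", 1:4),
                mapply(function(s, k) substitute_k(s, k), genes, divs),
                source = "t2")
  cat <- seq_tbl(sprintf("ref%d", 1:4), genes, source = "catalogue",
                 role = "target")
  cat$single_copy <- TRUE
  counts <- vapply(c(0.70, 0.80, 0.90, 0.97), function(mi) {
    nrow(discover_markers(list(t1, t2), catalogue = cat,
                          cfg = fast_cfg(min_identity = mi)))
  }, 1L)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[4])
})
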