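# Helpers to build contig match rows directly on target coordinates.
placed_match <- function(seqs, starts, target_id = "t1", sample = "s1",
                         rescue = FALSE) {
  tibble::tibble(
    sample = sample, contig_id = sprintf("c%d", seq_along(seqs)),
    target_id = target_id,
    overlap_len = nchar(seqs), identity = 1, strand = "+",
    rescue = rescue, placed_start = as.integer(starts), seq = toupper(seqs)
  )
}

test_that("contig matching keeps good matches and rescues weak ones", {
  set.seed(101)
  target <- rand_dna(800)
  targets <- seq_tbl("t1", target, source = "targets", role = "target")
  contigs <- seq_tbl(
    c("exact", "short", "diverged", "minus"),
    c(substr(target, 101, 600),                  # 500 bp exact
      substr(target, 301, 399),                  # 99 bp overlap
      substitute_k(substr(target, 1, 300), 78),  # 74% identity
      revcomp(substr(target, 401, 800))),        # minus strand, exact
    source = "s1", role = "contig")
  m <- match_contigs(contigs, targets, run_config())
  m <- m[match(c("exact", "short", "diverged", "minus"), m$contig_id), ]
  expect_equal(m$rescue, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(m$overlap_len[1], 500L)
  expect_equal(m$identity[1], 1.0)
  expect_equal(m$strand[4], "-")
  # minus-strand contigs come back in target orientation and placement
  expect_equal(m$seq[4], substr(target, 401, 800))
  expect_equal(m$placed_start[4], 400L)
})

test_that("the four canonical merge cases behave as specified", {
  set.seed(102)
  base <- rand_dna(200)

  # identical 40 bp overlap -> one merged sequence spanning the union
  a <- substr(base, 1, 120)
  b <- substr(base, 81, 200)
  res <- merge_contigs(placed_match(c(a, b), c(0, 80)), run_config())
  expect_equal(nrow(res), 1L)
  expect_equal(res$seq, base)
  expect_equal(res$n_ambig, 0L)

  # one A/G conflict in a 50 bp overlap -> merged with an R column
  a <- substr(base, 1, 130)
  b <- substr(base, 81, 200)
  pos <- 100L  # inside the overlap, 0-based target coordinate
  substr(a, pos + 1, pos + 1) <- "A"
  b2 <- b
  substr(b2, pos - 80 + 1, pos - 80 + 1) <- "G"
  res <- merge_contigs(placed_match(c(a, b2), c(0, 80)), run_config())
  expect_equal(nrow(res), 1L)
  expect_equal(substr(res$seq, pos + 1, pos + 1), "R")
  amb <- attr(res, "ambiguities")
  expect_equal(amb$position, pos)
  expect_equal(amb$code, "R")

  # two conflicts -> not merged
  a2 <- a
  substr(a2, 91, 91) <- "A"
  b3 <- b2
  substr(b3, 91 - 80, 91 - 80) <- chartr("A", "C", substr(a2, 91, 91))
  res <- merge_contigs(placed_match(c(a2, b3), c(0, 80)), run_config())
  expect_equal(nrow(res), 2L)

  # identical but only 29 bp overlap -> not merged
  a <- substr(base, 1, 109)
  b <- substr(base, 81, 200)
  res <- merge_contigs(placed_match(c(a, b), c(0, 80)), run_config())
  expect_equal(nrow(res), 2L)
})

test_that("merging conserves observed states and total length", {
  set.seed(103)
  base <- rand_dna(300)
  pieces <- list(c(1, 120), c(90, 210), c(180, 300))
  seqs <- vapply(pieces, function(p) substr(base, p[1], p[2]), "")
  res <- merge_contigs(placed_match(seqs, c(0, 89, 179)), run_config())
  expect_equal(nrow(res), 1L)
  expect_equal(res$seq, base)  # no state invented anywhere
  expect_lte(sum(nchar(res$seq)), sum(nchar(seqs)))
})

test_that("merge result is independent of contig input order", {
  set.seed(104)
  base <- rand_dna(400)
  cuts <- list(c(1, 150), c(120, 260), c(230, 400), c(60, 190))
  seqs <- vapply(cuts, function(p) substr(base, p[1], p[2]), "")
  starts <- vapply(cuts, function(p) as.integer(p[1] - 1L), 1L)
  m1 <- placed_match(seqs, starts)
  perm <- c(3, 1, 4, 2)
  m2 <- placed_match(seqs[perm], starts[perm])
  r1 <- merge_contigs(m1, run_config())
  r2 <- merge_contigs(m2, run_config())
  expect_equal(r1$seq, r2$seq)
  expect_equal(r1$start, r2$start)
})

test_that("rescue fragments are merged last under the same rules", {
  set.seed(105)
  base <- rand_dna(260)
  main <- substr(base, 1, 200)
  tail <- substr(base, 161, 260)  # pretend it failed the overlap filter
  m <- dplyr::bind_rows(placed_match(main, 0),
                        placed_match(tail, 160, rescue = TRUE))
  m$contig_id <- c("a", "b")
  res <- merge_contigs(m, run_config())
  expect_equal(nrow(res), 1L)
  expect_equal(res$seq, base)
})

test_that("divergent merged sequences are segregated into copy groups", {
  set.seed(106)
  base <- rand_dna(250)
  other <- substitute_k(base, 60)  # ~76% identity paralog
  m <- placed_match(c(base, other), c(0, 0))
  res <- merge_contigs(m, run_config())
  expect_equal(nrow(res), 2L)
  expect_equal(length(unique(res$copy_group)), 2L)
})

test_that("column filtering removes indel and missing-data columns", {
  aln <- tibble::tibble(id = c("r1", "r2"), seq = c("AC-T", "ACGT"))
  out <- filter_alignment_columns(aln)
  expect_equal(out$seq, c("ACT", "ACT"))
  expect_equal(attr(out, "removed"), 1L)

  clean <- tibble::tibble(id = c("a", "b"), seq = c("ACGT", "ACGT"))
  expect_equal(filter_alignment_columns(clean)$seq, clean$seq)

  allbad <- tibble::tibble(id = c("a", "b"), seq = c("A-G?", "NC-T"))
  out <- filter_alignment_columns(allbad)
  expect_equal(nchar(out$seq), c(0L, 0L))

  expect_error(filter_alignment_columns(
    tibble::tibble(id = c("a", "b"), seq = c("ACG", "ACGT"))), "unequal")
})

test_that("variability counts irreconcilable columns over the ingroup", {
  # 4 rows, 10 columns; columns 3 (gap) and 10 (missing) are filtered,
  # leaving 8; hand count over the ingroup gives 2 variable columns
  # (original columns 7: G/T/T and 8: T/T/G)
  aln <- tibble::tibble(
    id = c("s1", "s2", "s3", "out"),
    seq = c("ACGTACGTAC",
            "AC-TACTTAN",
            "ACCTACTGAC",
            "TTTTTTTTTT"))
  rep <- variability(aln, ingroup = c("s1", "s2", "s3"))
  expect_equal(rep$aln_len_total, 10L)
  expect_equal(rep$aln_len_filtered, 8L)
  expect_equal(rep$n_variable, 2L)
  expect_equal(rep$pct_variable, 0.25)

  same <- tibble::tibble(id = c("a", "b"), seq = c("ACGT", "ACGT"))
  expect_equal(variability(same)$n_variable, 0L)

  # R is reconcilable with A, not with C
  amb <- tibble::tibble(id = c("a", "b"), seq = c("AC", "RC"))
  expect_equal(variability(amb)$n_variable, 0L)
  amb2 <- tibble::tibble(id = c("a", "b"), seq = c("CA", "RA"))
  expect_equal(variability(amb2)$n_variable, 1L)

  expect_error(variability(same, ingroup = "a"), "two ingroup")
})

test_that("variability is invariant under row permutation", {
  set.seed(107)
  rows <- vapply(1:5, function(i) substitute_k(strrep("ACGT", 25), 8), "")
  aln <- tibble::tibble(id = sprintf("s%d", 1:5), seq = rows)
  r1 <- variability(aln)
  perm <- c(4, 2, 5, 1, 3)
  r2 <- variability(aln[perm, ])
  expect_equal(r1$n_variable, r2$n_variable)
  expect_equal(r1$pct_variable, r2$pct_variable)
})
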