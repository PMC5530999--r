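# Synthetic fixtures with known ground truth: genomes with exon/intron
# gene models, derived transcriptomes at controlled divergence, planted
# paralogs and private genes, and fragmented capture contigs with allelic
# variants.

#' Simulation parameters
#'
#' Defaults are the package's standard validation conditions: 20 gene
#' families over 3 taxa, per-branch divergence drawn from 0.05--0.20 (so
#' realised pairwise identities straddle the 0.75 hybridisation floor),
#' 25% of families duplicated in the genome at 0.10 divergence, 20%
#' private genes, exons of 250--600 bp (2--5 per gene) and introns of
#' 150--1,000 bp.  Divergence is applied per branch from a common
#' ancestor, substitutions only, so planted identities can be counted
#' exactly and are recorded in the truth table.
#'
#' @param n_genes number of shared gene families.
#' @param n_taxa number of transcriptomes.
#' @param exon_count_range,exon_len_range,intron_len_range gene structure
#'   ranges (counts / bp).
#' @param divergence_range per-branch substitution proportion range.
#' @param paralog_fraction fraction of families with a duplicated genomic
#'   locus.
#' @param paralog_divergence substitution proportion of the duplicate.
#' @param private_gene_fraction extra one-transcriptome-only genes, as a
#'   fraction of `n_genes`.
#' @param intergenic_len_range spacer lengths between genes, bp.
#' @param n_chromosomes genome sequences the loci are spread over.
#' @param contig_len_range simulated contig lengths, bp.
#' @param contig_overlap overlap between successive contigs, bp.
#' @param contig_coverage_gap_prob probability a contig is dropped
#'   (coverage gap).
#' @param allele_diff_range range of per-target allele differences (a
#'   draw of 0 means the sample is homozygous for that target).
#' @param allele_window_len window width within which the allele
#'   differences of one target are planted, bp.
#' @param flank_len_range non-target flanking sequence carried by terminal
#'   contigs, bp.
#' @param sample_divergence substitution proportion between a capture
#'   sample and the target.
#' @param n_samples number of capture samples.
#' @param seed integer; fixes all randomness.
#' @return List with class `"sim_params"`.
#' @export
sim_params <- function(n_genes = 20L, n_taxa = 3L,
                       exon_count_range = c(2L, 5L),
                       exon_len_range = c(250L, 600L),
                       intron_len_range = c(150L, 1000L),
                       divergence_range = c(0.05, 0.20),
                       paralog_fraction = 0.25,
                       paralog_divergence = 0.10,
                       private_gene_fraction = 0.20,
                       intergenic_len_range = c(300L, 800L),
                       n_chromosomes = 4L,
                       contig_len_range = c(300L, 500L),
                       contig_overlap = 80L,
                       contig_coverage_gap_prob = 0.1,
                       allele_diff_range = c(0L, 3L),
                       allele_window_len = 40L,
                       flank_len_range = c(0L, 120L),
                       sample_divergence = 0.01,
                       n_samples = 4L,
                       seed = 42L) {
  p <- as.list(environment())
  for (f in c("paralog_fraction", "private_gene_fraction",
              "contig_coverage_gap_prob", "paralog_divergence",
              "sample_divergence")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0, 1]", call. = FALSE)
  }
  if (min(exon_len_range) < 1) stop("exons must be at least 1 bp", call. = FALSE)
  if (min(divergence_range) < 0 || max(divergence_range) > 0.75) {
    stop("divergence_range must lie in [0, 0.75]", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' @noRd
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

#' @noRd
rint <- function(range) if (range[1] >= range[2]) as.integer(range[1]) else
  sample(seq(range[1], range[2]), 1)

# Substitute a fraction d of positions (each to a different base);
# returns the mutated string and the realised substitution count.
#' @noRd
mutate_seq <- function(seq, d) {
  n <- nchar(seq)
  k <- rbinom(1, n, d)
  if (k == 0) return(list(seq = seq, n_sub = 0L))
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  list(seq = paste(ch, collapse = ""), n_sub = k)
}

#' Simulate a genome and matched transcriptomes
#'
#' Genes are built exon by exon from a random ancestor; introns exist in
#' the genome only.  Taxon copies are derived by independent per-branch
#' substitutions at the family's drawn divergence; the genome carries
#' taxon 1's copy (with introns), on a random strand, so transcriptome 1
#' maps back at identity 1.  Paralog families get a second genomic locus
#' diverged by `paralog_divergence`; private genes appear in one
#' transcriptome only and nowhere in the genome.  Fully deterministic
#' given `p$seed`.
#'
#' @param p a [sim_params()].
#' @return List with `genome` (sequence tibble), `transcriptomes` (list of
#'   sequence tibbles, sources `"taxon1"`, ...), and `truth`, a tibble
#'   with one row per planted gene: family class
#'   (`single`/`paralog`/`private`), structure (exon/intron lengths,
#'   strand, chromosome, locus span), realised minimum pairwise identity
#'   between taxon copies, coding length, and `expected_marker` -- whether
#'   the discovery stage run at the default thresholds should emit it.
#' @export
simulate_genome_and_transcriptomes <- function(p = sim_params()) {
  set.seed(p$seed)
  cfg <- run_config()
  n_private <- round(p$n_genes * p$private_gene_fraction)
  n_paralog <- round(p$n_genes * p$paralog_fraction)
  paralog_ids <- sample.int(p$n_genes, n_paralog)
  genes <- vector("list", p$n_genes)
  for (g in seq_len(p$n_genes)) {
    n_ex <- rint(p$exon_count_range)
    exon_lens <- vapply(seq_len(n_ex), function(i) rint(p$exon_len_range), 1L)
    intron_lens <- if (n_ex > 1) {
      vapply(seq_len(n_ex - 1), function(i) rint(p$intron_len_range), 1L)
    } else integer(0)
    ancestor_exons <- lapply(exon_lens, rand_seq)
    # per-branch divergence; families are planted decisively above or
    # below the 75% identity floor (expected pairwise identity outside
    # [0.71, 0.79]).  A family statistically AT the floor has genuinely
    # ambiguous cluster membership -- a single substitution flips it -- so
    # "straddling the floor" means families on both sides of it, not on
    # the line.  Expected pairwise identity under two independent
    # branches: (1-d)^2 + d^2/3 (both branches hitting the same base).
    repeat {
      d <- runif(1, p$divergence_range[1], p$divergence_range[2])
      pred <- (1 - d)^2 + d^2 / 3
      if (pred <= 0.71 || pred >= 0.79) break
    }
    copies <- lapply(seq_len(p$n_taxa), function(t) {
      mutate_seq(paste(unlist(ancestor_exons), collapse = ""), d)$seq
    })
    genes[[g]] <- list(id = sprintf("gene%02d", g), exon_lens = exon_lens,
                       intron_lens = intron_lens, d = d, copies = copies,
                       paralog = g %in% paralog_ids)
  }
  # genome: taxon-1 copies with introns, random strand, round-robin over
  # chromosomes with random intergenic spacers
  chrom_seq <- rep("", p$n_chromosomes)
  truth_rows <- list()
  for (g in seq_len(p$n_genes)) {
    gene <- genes[[g]]
    chrom <- ((g - 1) %% p$n_chromosomes) + 1L
    coding <- gene$copies[[1]]
    # reassemble exon sequences from the taxon-1 coding copy
    ends <- cumsum(gene$exon_lens)
    starts <- c(1L, head(ends, -1) + 1L)
    exon_seqs <- substring(coding, starts, ends)
    genomic_parts <- character(0)
    for (k in seq_along(exon_seqs)) {
      genomic_parts <- c(genomic_parts, exon_seqs[k])
      if (k < length(exon_seqs)) {
        # intron terminal bases must differ from the adjacent exon
        # continuation, mirroring the recognisable splice boundaries of
        # real introns; otherwise the junction position is genuinely
        # ambiguous and exact structure recovery is ill-posed
        intr <- strsplit(rand_seq(gene$intron_lens[k]), "")[[1]]
        next_exon_first <- substr(exon_seqs[k + 1], 1, 1)
        prev_exon_last <- substr(exon_seqs[k], nchar(exon_seqs[k]),
                                 nchar(exon_seqs[k]))
        intr[1] <- sample(setdiff(c("A", "C", "G", "T"), next_exon_first), 1)
        intr[length(intr)] <- sample(setdiff(c("A", "C", "G", "T"),
                                             prev_exon_last), 1)
        genomic_parts <- c(genomic_parts, paste(intr, collapse = ""))
      }
    }
    gene_seq <- paste(genomic_parts, collapse = "")
    strand <- sample(c("+", "-"), 1)
    placed <- if (strand == "+") gene_seq else revcomp(gene_seq)
    spacer <- rand_seq(rint(p$intergenic_len_range))
    locus_start <- nchar(chrom_seq[chrom]) + nchar(spacer)
    chrom_seq[chrom] <- paste0(chrom_seq[chrom], spacer, placed)
    locus_end <- nchar(chrom_seq[chrom])
    n_copies <- 1L
    if (gene$paralog) {
      # dispersed duplicate: placed on a chromosome/position at least
      # locus_merge_gap away from the primary locus, so the two copies are
      # distinct loci under the pipeline's locus chaining (tandem
      # duplications closer than locus_merge_gap would deliberately count
      # as one locus and are not planted here)
      dup <- mutate_seq(gene_seq, p$paralog_divergence)$seq
      ok <- which(seq_len(p$n_chromosomes) != chrom |
                    nchar(chrom_seq) - locus_end > cfg$locus_merge_gap)
      chrom2 <- ok[sample.int(length(ok), 1)]
      spacer2 <- rand_seq(rint(p$intergenic_len_range))
      chrom_seq[chrom2] <- paste0(chrom_seq[chrom2], spacer2, dup)
      n_copies <- 2L
    }
    # realised identities, under the same definition the similarity filter
    # uses (optimal global alignment, matches / columns); for these
    # substitution-only copies they equal the counted identity except when
    # the optimal alignment squeezes out a few extra matches with gaps
    pids <- matrix(1, p$n_taxa, p$n_taxa)
    for (a in seq_len(p$n_taxa - 1)) {
      for (b in seq(a + 1, p$n_taxa)) {
        pids[a, b] <- pids[b, a] <-
          percent_identity(gene$copies[[a]], gene$copies[[b]])
      }
    }
    pid <- min(pids)
    # which cluster the discovery stage would form: connected components of
    # the >= min_identity identity graph; the component spanning >= 2 taxa
    # survives the similarity filter iff all its internal pairs pass
    adj <- pids >= cfg$min_identity
    diag(adj) <- FALSE
    gcomp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    cluster_pass <- FALSE
    for (cmp in seq_len(gcomp$no)) {
      idx <- which(gcomp$membership == cmp)
      if (length(idx) >= cfg$min_shared_transcriptomes &&
          min(pids[idx, idx]) >= cfg$min_identity) {
        cluster_pass <- TRUE
      }
    }
    coding_len <- sum(gene$exon_lens)
    truth_rows[[g]] <- tibble::tibble(
      gene_id = gene$id, class = if (gene$paralog) "paralog" else "single",
      n_copies_genome = n_copies, coding_len = coding_len,
      n_exons = length(gene$exon_lens),
      exon_lens = list(gene$exon_lens),
      intron_lens = list(gene$intron_lens),
      strand = strand, chrom = sprintf("chr%d", chrom),
      locus_start = locus_start, locus_end = locus_end,
      branch_divergence = gene$d,
      min_pairwise_identity = pid,
      expected_marker = !gene$paralog &&
        coding_len >= cfg$min_transcript_len &&
        cluster_pass
    )
  }
  # private genes: one transcriptome only, absent from the genome
  privates <- vector("list", n_private)
  for (q in seq_len(n_private)) {
    n_ex <- rint(p$exon_count_range)
    len <- sum(vapply(seq_len(n_ex), function(i) rint(p$exon_len_range), 1L))
    privates[[q]] <- list(id = sprintf("private%02d", q),
                          taxon = sample.int(p$n_taxa, 1),
                          seq = rand_seq(len))
    truth_rows[[p$n_genes + q]] <- tibble::tibble(
      gene_id = privates[[q]]$id, class = "private", n_copies_genome = 0L,
      coding_len = len, n_exons = n_ex, exon_lens = list(integer(0)),
      intron_lens = list(integer(0)), strand = NA_character_,
      chrom = NA_character_, locus_start = NA_integer_,
      locus_end = NA_integer_, branch_divergence = NA_real_,
      min_pairwise_identity = NA_real_, expected_marker = FALSE)
  }
  transcriptomes <- lapply(seq_len(p$n_taxa), function(t) {
    ids <- vapply(genes, `[[`, "", "id")
    seqs <- vapply(genes, function(gene) gene$copies[[t]], "")
    pv <- Filter(function(x) x$taxon == t, privates)
    if (length(pv) > 0) {
      ids <- c(ids, vapply(pv, `[[`, "", "id"))
      seqs <- c(seqs, vapply(pv, `[[`, "", "seq"))
    }
    seq_tbl(ids, seqs, source = sprintf("taxon%d", t), role = "transcript")
  })
  genome <- seq_tbl(sprintf("chr%d", seq_len(p$n_chromosomes)), chrom_seq,
                    source = "wgs", role = "genomic")
  list(genome = genome, transcriptomes = transcriptomes,
       truth = dplyr::bind_rows(truth_rows))
}

#' Simulate captured, fragmented contigs per sample
#'
#' Per sample and target: the sample haplotype is the target mutated at
#' `p$sample_divergence`; a subset of targets receives a second allele
#' differing at `k` positions (`k` drawn from `p$allele_diff_range`)
#' planted inside one `p$allele_window_len`-bp window clear of fragment
#' boundaries, so the merge rule's phenomenology is well defined:
#' both alleles are fragmented at the same breakpoints (successive
#' fragments overlapping by `p$contig_overlap` bp), terminal fragments may
#' carry random flanking sequence, and fragments are dropped with
#' probability `p$contig_coverage_gap_prob`.
#'
#' @param targets sequence tibble of target sequences.
#' @param p a [sim_params()].
#' @return List with `contigs` (one sequence tibble per sample, `source` =
#'   sample id) and `truth` (tibble: per target/sample allele count,
#'   planted difference positions, fragments kept).
#' @export
simulate_capture_contigs <- function(targets, p = sim_params()) {
  set.seed(p$seed + 1L)
  samples <- sprintf("sample%d", seq_len(p$n_samples))
  contig_rows <- list()
  truth_rows <- list()
  for (s in seq_along(samples)) {
    for (ti in seq_len(nrow(targets))) {
      tlen <- nchar(targets$seq[ti])
      hap <- mutate_seq(targets$seq[ti], p$sample_divergence)$seq
      k <- rint(p$allele_diff_range)
      # fragment breakpoints, shared between alleles; successive fragments
      # overlap by contig_overlap bp
      starts <- 0L
      ends <- integer(0)
      repeat {
        e <- min(tail(starts, 1) + rint(p$contig_len_range), tlen)
        ends <- c(ends, e)
        if (e >= tlen) break
        starts <- c(starts, e - p$contig_overlap)
      }
      # allele differences inside one window clear of all breakpoints
      diffs <- integer(0)
      hap2 <- NULL
      if (k > 0) {
        margin <- p$contig_overlap + 5L
        bounds <- setdiff(unique(c(starts, ends)), c(0L, tlen))
        ok_start <- function(w) {
          all(abs(bounds - w) > margin & abs(bounds - (w + p$allele_window_len)) > margin)
        }
        cand_w <- seq(margin, max(margin, tlen - p$allele_window_len - margin))
        cand_w <- cand_w[vapply(cand_w, ok_start, TRUE)]
        if (length(cand_w) == 0) cand_w <- (tlen - p$allele_window_len) %/% 2
        w <- cand_w[sample.int(length(cand_w), 1)]
        diffs <- sort(sample(seq(w, w + p$allele_window_len - 1L),
                             min(k, p$allele_window_len)))
        ch <- strsplit(hap, "")[[1]]
        for (d in diffs) ch[d + 1L] <- sample(setdiff(c("A", "C", "G", "T"), ch[d + 1L]), 1)
        hap2 <- paste(ch, collapse = "")
      }
      alleles <- c(list(hap), if (!is.null(hap2)) list(hap2))
      # flanking sequence is genomic context shared by both alleles
      flank_l <- rand_seq(rint(p$flank_len_range))
      flank_r <- rand_seq(rint(p$flank_len_range))
      frags <- list()
      for (al in seq_along(alleles)) {
        for (f in seq_along(starts)) {
          if (runif(1) < p$contig_coverage_gap_prob) next
          a0 <- starts[f]; a1 <- ends[f]
          seq <- substring(alleles[[al]], a0 + 1L, a1)
          placed <- a0
          if (f == 1 && nchar(flank_l) > 0) {
            seq <- paste0(flank_l, seq)
            placed <- a0 - nchar(flank_l)
          }
          if (f == length(starts) && nchar(flank_r) > 0) {
            seq <- paste0(seq, flank_r)
          }
          frags[[length(frags) + 1L]] <- tibble::tibble(
            sample = samples[s], target_id = targets$id[ti],
            allele = al, frag = f, start = a0, end = a1,
            placed_start = placed,
            contig_id = sprintf("%s|%s|a%d|f%d", samples[s], targets$id[ti], al, f),
            seq = seq)
        }
      }
      frags <- dplyr::bind_rows(frags)
      contig_rows[[length(contig_rows) + 1L]] <- frags
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        sample = samples[s], target_id = targets$id[ti],
        n_alleles = length(alleles), n_diffs = length(diffs),
        diff_positions = list(diffs),
        n_fragments = if (is.null(frags) || nrow(frags) == 0) 0L else nrow(frags),
        complete_both_alleles = length(alleles) * length(starts) ==
          (if (is.null(frags) || nrow(frags) == 0) 0L else nrow(frags)))
    }
  }
  all_frags <- dplyr::bind_rows(contig_rows)
  contigs <- lapply(samples, function(s) {
    fr <- all_frags[all_frags$sample == s, ]
    seq_tbl(fr$contig_id, fr$seq, source = s, role = "contig")
  })
  names(contigs) <- samples
  list(contigs = contigs, truth = dplyr::bind_rows(truth_rows),
       fragments = all_frags)
}
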