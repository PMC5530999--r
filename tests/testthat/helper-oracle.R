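# Independent pure-R oracles and fixture builders shared across tests.

# Exhaustive Gotoh local-alignment score (no traceback): the reference the
# C++ Smith-Waterman is checked against.  First gap base costs gap_open,
# further bases gap_ext; ambiguity codes never match.
r_local_score <- function(a, b, match = 1, mismatch = -1,
                          gap_open = -2, gap_ext = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  Hprev <- numeric(m + 1); Fprev <- rep(NEG, m + 1)
  best <- 0
  acgt <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    Hcur <- numeric(m + 1); Fcur <- rep(NEG, m + 1)
    E <- NEG
    for (j in seq_len(m)) {
      E <- max(Hcur[j] + gap_open, E + gap_ext)
      Fcur[j + 1] <- max(Hprev[j + 1] + gap_open, Fprev[j + 1] + gap_ext)
      s <- if (av[i] == bv[j] && av[i] %in% acgt) match else mismatch
      h <- max(0, Hprev[j] + s, E, Fcur[j + 1])
      Hcur[j + 1] <- h
      if (h > best) best <- h
    }
    Hprev <- Hcur; Fprev <- Fcur
  }
  best
}

# Global Gotoh score with penalised end gaps, for cross-checking the
# percent_identity alignment engine.
r_global_score <- function(a, b, match = 1, mismatch = -1,
                           gap_open = -2, gap_ext = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  Hprev <- c(0, gap_open + (seq_len(m) - 1) * gap_ext)
  Fprev <- rep(NEG, m + 1)
  acgt <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    Hcur <- c(gap_open + (i - 1) * gap_ext, numeric(m))
    Fcur <- c(Hcur[1], rep(NEG, m))
    E <- NEG
    for (j in seq_len(m)) {
      E <- max(Hcur[j] + gap_open, E + gap_ext)
      Fcur[j + 1] <- max(Hprev[j + 1] + gap_open, Fprev[j + 1] + gap_ext)
      s <- if (av[i] == bv[j] && av[i] %in% acgt) match else mismatch
      Hcur[j + 1] <- max(Hprev[j] + s, E, Fcur[j + 1])
    }
    Hprev <- Hcur; Fprev <- Fcur
  }
  Hprev[m + 1]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Substitute exactly k positions, each to a different base.
substitute_k <- function(seq, k, positions = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(length(ch), k)
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Plant a diverged copy of a query segment inside a random subject; returns
# the instance plus where it was planted.
plant_homologue <- function(qlen, slen, identity, minus = FALSE) {
  q <- rand_dna(qlen)
  k <- round((1 - identity) * qlen)
  hom <- substitute_k(q, k)
  if (minus) hom <- markerforge::revcomp(hom)
  pos <- sample(slen - qlen + 1, 1)
  s <- rand_dna(slen)
  s <- paste0(substr(s, 1, pos - 1), hom, substr(s, pos + qlen, slen))
  list(query = q, subject = s, s_start = pos - 1L, s_end = pos - 1L + qlen)
}

# Candidate tibble in the discover_markers() schema, built directly; exon
# structure is given per marker as a list of exon lengths plus intron
# lengths.
make_candidates <- function(exon_lens_list, intron_lens_list = NULL,
                            prefix = "m") {
  n <- length(exon_lens_list)
  if (is.null(intron_lens_list)) {
    intron_lens_list <- lapply(exon_lens_list, function(e) {
      if (length(e) > 1) rep(300L, length(e) - 1L) else integer(0)
    })
  }
  rows <- lapply(seq_len(n), function(i) {
    lens <- as.integer(exon_lens_list[[i]])
    ends <- cumsum(lens)
    starts <- c(0L, head(ends, -1))
    total <- sum(lens)
    tibble::tibble(
      marker_id = sprintf("%s%03d", prefix, i),
      source = "synthetic", id = sprintf("%s%03d", prefix, i),
      seq = rand_dna(total),
      n_members = 2L, n_sources = 2L,
      min_pairwise_identity = 0.9,
      copy_number = "single",
      has_model = length(lens) > 1,
      genome_id = NA_character_, strand = "+",
      exons = list(NULL),
      exons_q = list(cbind(q_start = starts, q_end = ends)),
      introns = list(NULL),
      intron_lens = list(as.integer(intron_lens_list[[i]])),
      exon_len_total = total,
      n_introns = length(intron_lens_list[[i]])
    )
  })
  dplyr::bind_rows(rows)
}
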