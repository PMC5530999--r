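# FASTA in/out and the sequence table ------------------------------------

#' Build a sequence table
#'
#' The package-wide container for sequences is an ordinary tibble with
#' columns `source` (dataset label), `id` (unique within its source), `role`
#' (one of `"transcript"`, `"genomic"`, `"contig"`, `"target"`) and `seq`
#' (upper-case IUPAC nucleotide string).  Coordinates reported against these
#' sequences are 0-based half-open internally; exported GFF/TSV reports are
#' 1-based inclusive.
#'
#' @param id,seq character vectors of equal length.
#' @param source single dataset label.
#' @param role sequence role.
#' @return Tibble with columns `source`, `id`, `role`, `seq`.
#' @export
seq_tbl <- function(id, seq, source = "seqs",
                    role = c("transcript", "genomic", "contig", "target")) {
  role <- match.arg(role)
  out <- tibble::tibble(source = source, id = as.character(id),
                        role = role, seq = toupper(as.character(seq)))
  validate_seq_tbl(out)
}

#' @noRd
validate_seq_tbl <- function(x) {
  stopifnot(all(c("source", "id", "role", "seq") %in% names(x)))
  if (any(!nzchar(x$id))) stop("sequence ids must be non-empty", call. = FALSE)
  if (any(!nzchar(x$seq))) stop("sequences must be non-empty", call. = FALSE)
  dup <- duplicated(paste(x$source, x$id, sep = "\r"))
  if (any(dup)) {
    stop("duplicate sequence id within source: ",
         paste(unique(x$id[dup]), collapse = ", "), call. = FALSE)
  }
  check_alphabet(x$seq)
  x
}

#' Read a FASTA file
#'
#' Sequences are upper-cased and validated against the IUPAC nucleotide
#' alphabet; entry order is preserved.  Malformed input (sequence text
#' before the first header, an entry with no sequence) raises a parse error
#' naming the offending line, and duplicated ids within one file are an
#' error.
#'
#' @param path FASTA file.
#' @param source dataset label stored in the `source` column (defaults to
#'   the file name without extension).
#' @param role sequence role, see [seq_tbl()].
#' @return A sequence tibble; the part of each header line after the first
#'   whitespace is kept in a `desc` column.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "NNTT"), f)
#' read_fasta(f, source = "demo")
#' @export
read_fasta <- function(path, source = NULL,
                       role = c("transcript", "genomic", "contig", "target")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0) stop("FASTA parse error: file is empty", call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop(sprintf("FASTA parse error at line %d: sequence text before first header",
                 lineno[1]), call. = FALSE)
  }
  entry <- cumsum(is_hdr)
  hdr_idx <- which(is_hdr)
  n_lines <- tabulate(entry, nbins = max(entry))
  if (any(n_lines == 1)) {
    bad <- hdr_idx[which(n_lines == 1)[1]]
    stop(sprintf("FASTA parse error at line %d: entry '%s' has an empty sequence",
                 lineno[bad], sub("^>", "", lines[bad])), call. = FALSE)
  }
  headers <- sub("^>", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!is_hdr], entry[!is_hdr]),
                 paste, "", collapse = "")
  seqs <- toupper(seqs[as.character(seq_along(ids))])
  if (anyDuplicated(ids)) {
    stop("duplicate id in ", basename(path), ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(source = source, id = ids, role = role,
                        seq = unname(seqs), desc = unname(desc))
  validate_seq_tbl(out)
}

#' Write a FASTA file
#'
#' Headers are the `id` column; sequences are wrapped at 60 columns.
#'
#' @param records sequence tibble (see [seq_tbl()]); must be non-empty.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0) stop("no records to write", call. = FALSE)
  validate_seq_tbl(records)
  chunks <- lapply(seq_len(nrow(records)), function(i) {
    s <- records$seq[i]
    starts <- seq(1, nchar(s), by = 60)
    c(paste0(">", records$id[i]),
      substring(s, starts, pmin(starts + 59, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

#' Read a single-copy gene catalogue
#'
#' A catalogue is a FASTA of reference coding sequences whose headers flag
#' each gene's copy-number class, e.g. `>geneX single` or
#' `>geneY copy_class=single`.  Descriptions containing the word `single`
#' (covering "single" and "mostly single") are flagged single copy;
#' everything else is treated as multi copy.
#'
#' @param path FASTA file.
#' @param source dataset label.
#' @return Sequence tibble with an additional logical `single_copy` column.
#' @export
read_catalogue <- function(path, source = "catalogue") {
  x <- read_fasta(path, source = source, role = "target")
  x$single_copy <- grepl("single", x$desc, ignore.case = TRUE)
  x
}

#' Write a tabular report as TSV
#'
#' All tabular reports share one format: a commented header line starting
#' with `#`, then tab-separated rows.  List columns are dropped.
#'
#' @param x data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  x <- x[, !vapply(x, is.list, TRUE), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(x), collapse = "\t")), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export homology hits as BLAST-style tabular text
#'
#' Mirrors the 12-column BLAST `outfmt 6` ordering (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, score, strand)
#' with 1-based inclusive coordinates; the E-value column is replaced by the
#' alignment score, and a strand column is appended.
#'
#' @param hits hit tibble from [find_homologues()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- tibble::tibble(
    qseqid = hits$query_id,
    sseqid = hits$subject_id,
    pident = round(hits$identity * 100, 2),
    length = hits$aln_len,
    mismatch = hits$aln_len - hits$matches - hits$gaps,
    gapopen = hits$gap_opens,
    qstart = hits$q_start + 1L,
    qend = hits$q_end,
    sstart = hits$s_start + 1L,
    send = hits$s_end,
    score = hits$score,
    strand = hits$strand
  )
  write_report_tsv(out, path)
}

#' Export gene models as GFF3
#'
#' One `gene` feature per marker with child `exon` features, 1-based
#' inclusive coordinates on the genome.
#'
#' @param candidates candidate tibble from [discover_markers()]; rows
#'   without a gene model are skipped.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(candidates, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(candidates))) {
    if (!isTRUE(candidates$has_model[i])) next
    ex <- candidates$exons[[i]]
    g0 <- min(ex[, 1]) + 1L
    g1 <- max(ex[, 2])
    mid <- candidates$marker_id[i]
    strand <- candidates$strand[i]
    chrom <- candidates$genome_id[i]
    lines <- c(lines, sprintf("%s\tmarkerforge\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              chrom, g0, g1, strand, mid))
    for (k in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tmarkerforge\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        chrom, ex[k, 1] + 1L, ex[k, 2], strand, mid, k, mid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
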