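# IUPAC nucleotide alphabet ----------------------------------------------

#' @noRd
IUPAC_SETS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' @noRd
IUPAC_FROM_SET <- setNames(names(IUPAC_SETS), IUPAC_SETS)

#' Expand an IUPAC code to its base set
#'
#' @param code single IUPAC nucleotide letter.
#' @return Character vector of the unambiguous bases the code stands for.
#' @examples
#' iupac_bases("R")
#' @export
iupac_bases <- function(code) {
  s <- IUPAC_SETS[[code]]
  if (is.null(s)) stop("not an IUPAC nucleotide code: ", code, call. = FALSE)
  strsplit(s, "")[[1]]
}

#' IUPAC code for a set of bases
#'
#' @param bases character vector of bases and/or IUPAC codes; the result
#'   encodes the union of their base sets.
#' @return Single IUPAC letter.
#' @examples
#' iupac_code(c("A", "G"))
#' iupac_code(c("R", "C"))
#' @export
iupac_code <- function(bases) {
  u <- sort(unique(unlist(lapply(bases, iupac_bases))))
  IUPAC_FROM_SET[[paste(u, collapse = "")]]
}

#' Reverse complement
#'
#' Complements the full IUPAC alphabet and reverses.
#'
#' @param x character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp("ACGTR")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' @noRd
check_alphabet <- function(seqs, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")), seqs)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the IUPAC nucleotide alphabet (first offender: entry %d)",
                 what, which(bad)[1]), call. = FALSE)
  }
  invisible(seqs)
}

# interval helpers (0-based, half-open) -----------------------------------

#' @noRd
interval_union_len <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > ce) {
      tot <- tot + (ce - cs); cs <- starts[i]; ce <- ends[i]
    } else {
      ce <- max(ce, ends[i])
    }
  }
  tot + (ce - cs)
}
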