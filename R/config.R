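#' Run configuration
#'
#' Bundles every tunable threshold of the pipeline.  The defaults reproduce
#' the parameterisation of the original bait-design study: a budget of 5,770
#' individual 120 bp baits tiled at 4x coverage (total bait length
#' 692,400 bp, capture footprint 173,100 bp), candidate transcripts of at
#' least 1,000 bp shared by at least two transcriptomes, a >= 75% identity
#' floor for probe hybridisation, coding regions >= 120 bp as bait targets,
#' a 100 bp minimum contig-to-target overlap and a 30 bp minimum overlap for
#' contig merging.
#'
#' @param min_transcript_len minimum transcript length kept by the length
#'   pre-filter, bp.  Sequences strictly shorter are removed.
#' @param min_shared_transcriptomes minimum number of distinct transcriptome
#'   sources a homologue cluster must span.
#' @param min_identity identity floor (fraction in (0, 1]) used for homologue
#'   clustering, the cluster similarity filter, copy-number locus calls and
#'   contig-to-target matching.
#' @param bait_len probe length, bp.
#' @param tiling_coverage tiling depth; adjacent baits are offset by
#'   `bait_len / tiling_coverage`, which must be a positive integer.
#' @param max_baits bait budget (count of individual baits).
#' @param min_exon_len minimum exon length targetable by baits, bp; shorter
#'   exons are skipped during tiling but do not disqualify their marker.
#' @param min_target_overlap minimum aligned target span for a captured
#'   contig to be retained, bp.
#' @param min_merge_overlap minimum overlap for merging two contigs, bp.
#' @param rank_mode ranking criterion for marker selection: `"exon_length"`,
#'   `"exon_plus_intron"`, `"variability"` or `"length_times_variability"`.
#' @param seed integer seed for all randomised components.
#' @param min_intron_len genomic gaps between chained exon hits shorter than
#'   this are absorbed into a single exon, bp.
#' @param max_unaligned_gap maximum transcript-side unaligned gap tolerated
#'   in a spliced mapping before the gene model is rejected, bp.
#' @param locus_merge_gap genomic hits of one transcript closer than this are
#'   counted as one locus, bp.
#' @param catalogue_min_identity relaxed identity floor for matching a
#'   representative against a single-copy gene catalogue.
#' @param intra_source_identity two cluster members from the same
#'   transcriptome below this global identity flag the cluster multi-copy.
#' @param paralog_split_identity merged contig sequences below this identity
#'   to each other are segregated into separate per-copy groups.
#' @param mean_intron_scope `"global"` (pooled mean over all candidates'
#'   introns) or `"per_marker"` (each marker's own mean intron length).
#' @param seed_len k-mer seed length of the homology search.
#' @param seed_band diagonal bandwidth for grouping seeds into one hit
#'   cluster, bp.
#' @param seed_max_gap maximum query-position gap between seeds of one
#'   cluster, bp.
#' @param seed_pad window padding around a seed cluster for exact
#'   realignment, bp (windows self-expand when an alignment presses
#'   against an edge).
#' @param rescue_seed_len,rescue_band,rescue_max_gap,rescue_min_ungapped
#'   sensitivity-rescue pass: query regions left uncovered by the primary
#'   seed pass are re-searched with this shorter seed, tighter diagonal
#'   band and query-gap limit, keeping only seed clusters whose ungapped
#'   x-drop extension reaches `rescue_min_ungapped` -- the ladder that
#'   lets the seeded search match the exact aligner down to the 75%
#'   identity floor.
#' @param min_hit_len minimum aligned query span for a reported homology
#'   hit, bp.
#' @param match,mismatch,gap_open,gap_ext alignment scores (first gap base
#'   costs `gap_open`, each further base `gap_ext`).
#'
#' @return A list with class `"marker_config"`.
#' @seealso [load_config()]
#' @examples
#' cfg <- run_config()
#' cfg$max_baits * cfg$bait_len  # total bait length of the default budget
#' @export
run_config <- function(min_transcript_len = 1000L,
                       min_shared_transcriptomes = 2L,
                       min_identity = 0.75,
                       bait_len = 120L,
                       tiling_coverage = 4L,
                       max_baits = 5770L,
                       min_exon_len = 120L,
                       min_target_overlap = 100L,
                       min_merge_overlap = 30L,
                       rank_mode = c("exon_length", "exon_plus_intron",
                                     "variability", "length_times_variability"),
                       seed = 1L,
                       min_intron_len = 20L,
                       max_unaligned_gap = 30L,
                       locus_merge_gap = 10000L,
                       catalogue_min_identity = 0.70,
                       intra_source_identity = 0.99,
                       paralog_split_identity = 0.90,
                       mean_intron_scope = c("global", "per_marker"),
                       seed_len = 11L,
                       seed_band = 16L,
                       seed_max_gap = 200L,
                       seed_pad = 200L,
                       rescue_seed_len = 6L,
                       rescue_band = 4L,
                       rescue_max_gap = 60L,
                       rescue_min_ungapped = 24L,
                       min_hit_len = 100L,
                       match = 1L,
                       mismatch = -1L,
                       gap_open = -2L,
                       gap_ext = -1L) {
  rank_mode <- match.arg(rank_mode)
  mean_intron_scope <- match.arg(mean_intron_scope)
  cfg <- list(
    min_transcript_len = as.integer(min_transcript_len),
    min_shared_transcriptomes = as.integer(min_shared_transcriptomes),
    min_identity = min_identity,
    bait_len = as.integer(bait_len),
    tiling_coverage = as.integer(tiling_coverage),
    max_baits = as.integer(max_baits),
    min_exon_len = as.integer(min_exon_len),
    min_target_overlap = as.integer(min_target_overlap),
    min_merge_overlap = as.integer(min_merge_overlap),
    rank_mode = rank_mode,
    seed = as.integer(seed),
    min_intron_len = as.integer(min_intron_len),
    max_unaligned_gap = as.integer(max_unaligned_gap),
    locus_merge_gap = as.integer(locus_merge_gap),
    catalogue_min_identity = catalogue_min_identity,
    intra_source_identity = intra_source_identity,
    paralog_split_identity = paralog_split_identity,
    mean_intron_scope = mean_intron_scope,
    seed_len = as.integer(seed_len),
    seed_band = as.integer(seed_band),
    seed_max_gap = as.integer(seed_max_gap),
    seed_pad = as.integer(seed_pad),
    rescue_seed_len = as.integer(rescue_seed_len),
    rescue_band = as.integer(rescue_band),
    rescue_max_gap = as.integer(rescue_max_gap),
    rescue_min_ungapped = as.integer(rescue_min_ungapped),
    min_hit_len = as.integer(min_hit_len),
    match = as.integer(match),
    mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open),
    gap_ext = as.integer(gap_ext)
  )
  class(cfg) <- "marker_config"
  validate_config(cfg)
}

#' @noRd
validate_config <- function(cfg) {
  fail <- function(key, why) {
    stop(sprintf("invalid configuration: `%s` %s", key, why), call. = FALSE)
  }
  if (!(cfg$min_identity > 0 && cfg$min_identity <= 1)) {
    fail("min_identity", "must be in (0, 1]")
  }
  if (cfg$bait_len <= 0) fail("bait_len", "must be positive")
  if (cfg$tiling_coverage < 1) fail("tiling_coverage", "must be >= 1")
  if (cfg$bait_len %% cfg$tiling_coverage != 0) {
    fail("tiling_coverage", sprintf(
      "must divide bait_len (tiling step %d / %d is not an integer)",
      cfg$bait_len, cfg$tiling_coverage))
  }
  if (cfg$max_baits < 0) fail("max_baits", "must be non-negative")
  if (cfg$min_shared_transcriptomes < 2) {
    fail("min_shared_transcriptomes", "must be >= 2")
  }
  for (key in c("catalogue_min_identity", "intra_source_identity",
                "paralog_split_identity")) {
    if (!(cfg[[key]] > 0 && cfg[[key]] <= 1)) fail(key, "must be in (0, 1]")
  }
  if (cfg$min_transcript_len < 0) fail("min_transcript_len", "must be >= 0")
  if (cfg$min_exon_len <= 0) fail("min_exon_len", "must be positive")
  if (cfg$min_merge_overlap <= 0) fail("min_merge_overlap", "must be positive")
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; unknown keys raise an
#' error, as do values violating the configuration invariants.
#'
#' @param path path to a YAML file of `key: value` pairs (see
#'   [run_config()] for the keys).
#' @return A `marker_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' @export
print.marker_config <- function(x, ...) {
  cat("<marker_config>\n")
  cat(sprintf("  bait budget : %d x %d bp baits at %dx tiling\n",
              x$max_baits, x$bait_len, x$tiling_coverage))
  cat(sprintf("  discovery   : length >= %d bp, shared by >= %d transcriptomes, identity >= %.2f\n",
              x$min_transcript_len, x$min_shared_transcriptomes, x$min_identity))
  cat(sprintf("  selection   : rank_mode = %s, targetable exons >= %d bp\n",
              x$rank_mode, x$min_exon_len))
  cat(sprintf("  postprocess : target overlap >= %d bp, merge overlap >= %d bp\n",
              x$min_target_overlap, x$min_merge_overlap))
  invisible(x)
}
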