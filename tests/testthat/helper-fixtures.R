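# The default synthetic study fixture and its discovery run are expensive,
# and several acceptance checks interrogate the same objects; compute them
# once per test session.

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function(seed = 101L) {
  key <- paste0("fix", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- markerforge::simulate_genome_and_transcriptomes(
      markerforge::sim_params(seed = seed))
    cand <- markerforge::discover_markers(sim$transcriptomes,
                                          genome = sim$genome)
    .fixture_cache[[key]] <- list(sim = sim, cand = cand)
  }
  .fixture_cache[[key]]
}

# Compare a candidate's recovered exon/intron structure with the planted
# truth (both reported in transcript orientation).
model_matches_truth <- function(cand_row, truth_row) {
  ex <- cand_row$exons[[1]]
  if (is.null(ex)) return(FALSE)
  fwd <- identical(cand_row$strand, "+")
  got_ex <- ex[, 2] - ex[, 1]
  got_in <- cand_row$intron_lens[[1]]
  if (!fwd) {
    got_ex <- rev(got_ex)
    got_in <- rev(got_in)
  }
  identical(as.integer(got_ex), as.integer(truth_row$exon_lens[[1]])) &&
    identical(as.integer(got_in), as.integer(truth_row$intron_lens[[1]]))
}
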