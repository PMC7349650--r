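# One default synthetic world + full pipeline run, cached per seed so the
# end-to-end checks across test files do not recompute it.

.world_cache <- new.env(parent = emptyenv())

default_world_run <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.world_cache[[key]])) {
    w <- make_world(sim_config(seed = seed))
    run <- suppressWarnings(
      pirna_analyze(w$reads, w$transcripts, w$genome, loci = w$loci))
    .world_cache[[key]] <- list(world = w, run = run)
  }
  .world_cache[[key]]
}
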