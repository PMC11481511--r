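# The default synthetic community (the study-scale desk fixture: ~40 species,
# ~120 prophages, 1% within-species divergence) with its full ANI matrix.
# Computed once and shared by the tests that need it.
default_fit <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$fit)) {
      comm <- generate_community(sim_config(seed = 1))
      mat <- compute_ani_matrix(comm$sequences)
      cache$fit <- list(comm = comm, mat = mat)
    }
    cache$fit
  }
})
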