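# Shared fixtures: the default synthetic dataset and its pipeline result
# are expensive (~40 s together), so they are built once per test run and
# reused across files.

# the cache lives in the global environment so that it survives helper
# re-sourcing between test files
.fixture_cache <- function() {
  if (!exists(".layerreg_fixture_cache", envir = globalenv())) {
    assign(".layerreg_fixture_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  }
  get(".layerreg_fixture_cache", envir = globalenv())
}

shared_dataset <- function() {
  cache <- .fixture_cache()
  if (is.null(cache$ds)) {
    cache$ds <- simulate_dataset(simulation_config(seed = 1))
  }
  cache$ds
}

shared_pipeline <- function() {
  cache <- .fixture_cache()
  if (is.null(cache$res)) {
    cache$res <- run_pipeline(shared_dataset())
  }
  cache$res
}

# truth labels ("null" for unplanted features) for a set of feature ids
truth_labels <- function(module_of, ids) {
  lab <- module_of[ids]
  ifelse(is.na(lab), "null", lab)
}

# small deterministic peak set builder
make_peaks <- function(starts, ends, chrom = "chr1", ids = NULL) {
  peaks_from_bed_coords(rep(chrom, length(starts)), starts, ends, ids)
}
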