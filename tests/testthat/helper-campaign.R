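# The full-scale simulation campaign is shared by several acceptance-level
# checks (detection rate, permutation null, size effect); it is computed at
# most once per test run, lazily.

acceptance_campaign <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_benchmark(n_datasets = 100L, n_perm = 20L, seed = 42L)
    cache
  }
})
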