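# The end-to-end study is expensive (three training regimes x three seeds),
# so it is computed once and shared by the tests that assert on different
# aspects of it.
.study_cache <- new.env(parent = emptyenv())

benchmark_study_cached <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- run_benchmark_study(seed = 1L)
  .study_cache$study
}
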