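# The end-to-end synthetic benchmark is expensive (several minutes), and two
# acceptance properties (classification and localization) share it; run it
# once per session and cache the result.

.bench_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function() {
  if (is.null(.bench_cache$bm)) {
    .bench_cache$bm <- synthetic_benchmark(seed = 1L)
  }
  .bench_cache$bm
}
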