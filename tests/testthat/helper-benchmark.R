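# the full four-class synthetic benchmark is expensive, so it is run once
# per test session and shared by the end-to-end checks

benchmark_report <- function() {
  fixture("benchmark_report", function() {
    cfg <- pipeline_config(seed = 1L)
    run_pipeline(cfg, verbose = FALSE)
  })
}
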