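# Trained models are expensive; build each once per test run and share.
.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.cache[[key]])) assign(key, build(), envir = .cache)
  .cache[[key]]
}

get_ff_model <- function() cached("ff", function() build_ff_model(seed = 42))

get_pc_model <- function() cached("pc", function() build_pc_model(seed = 42))

# A predictive-coding model sharing the cached trained cortex but with a
# freshly sampled subcortical network.
pc_model_with_rnn <- function(rnn_seed) {
  m <- get_pc_model()
  m$rnn <- sample_subcortex_rnn(rnn_seed)
  m$gains$out_cal <- calibrate_rnn_output(m$rnn, m$gains)
  m$gains$norm <- m$gains$norm_target / m$gains$out_cal$ref_do
  m
}

get_test_pairs <- function(n = 200, seed = 7) {
  cached(paste0("pairs", n, "_", seed), function() make_test_set(n, seed))
}
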