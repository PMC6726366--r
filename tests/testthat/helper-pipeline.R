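# The cross-validated synthetic training run is by far the most expensive
# computation in the suite, and several tests interrogate the trained
# model (accuracy recovery, attribution on real predictions). Train once
# per session and share the result.
.pipeline_cache <- new.env(parent = emptyenv())

trained_pipeline <- function() {
  if (is.null(.pipeline_cache$result)) {
    .pipeline_cache$result <- run_pipeline(
      sim = sim_config(seed = 1),
      train = train_config(epochs = 15, folds = 4, seed = 1),
      patch_px = 64, crop_px = 96, anchors_per_cell = 1)
  }
  .pipeline_cache$result
}
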