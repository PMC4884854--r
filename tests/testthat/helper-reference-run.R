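# The full reference experiment takes several minutes; it is run once
# and shared by the acceptance blocks that need it.
.reference_cache <- new.env(parent = emptyenv())

reference_run <- function() {
  if (is.null(.reference_cache$res))
    .reference_cache$res <- run_experiment(experiment_config("reference"))
  .reference_cache$res
}
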