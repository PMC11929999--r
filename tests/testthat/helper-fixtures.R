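# Shared fixtures, generated once per test run and memoised. The default
# synthetic cohort (36 samples, 9 breeds, 3 regions, default noise) feeds
# both the pipeline tests and the planted-structure recovery checks.

.fixture_env <- new.env(parent = emptyenv())

default_pipeline_run <- function() {
  if (is.null(.fixture_env$run)) {
    out_dir <- file.path(tempdir(), "cnvpool_default_run")
    cfg <- synthetic_config(seed = 20260929)
    manifest <- run_pipeline(pipeline_config(synthetic = cfg, seed = cfg$seed),
                             out_dir)
    .fixture_env$run <- list(cfg = cfg, out_dir = out_dir, manifest = manifest,
                             truth = jsonlite::read_json(
                               file.path(out_dir, "input", "truth.json"),
                               simplifyVector = TRUE))
  }
  .fixture_env$run
}

noiseless_dataset <- function() {
  if (is.null(.fixture_env$noiseless)) {
    cfg <- synthetic_config(
      seed = 11,
      tools = cnvpool:::.default_tool_profiles(detection_prob = 1,
                                               jitter_sd = 0, fp_per_mb = 0))
    dir <- file.path(tempdir(), "cnvpool_noiseless")
    .fixture_env$noiseless <- list(cfg = cfg,
                                   data = write_synthetic_dataset(cfg, dir))
  }
  .fixture_env$noiseless
}
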