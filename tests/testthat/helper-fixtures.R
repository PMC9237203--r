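# Shared fixtures, built once per test run and cached.

FEATURE_BLOCKS_FOR_TEST <- c("caudate", "putamen", "pallidum",
                             "CRputamen", "CRpallidum")

region_code_for_test <- function(atlas, region)
  atlas$regions$code[match(region, atlas$regions$name)]

.fixture_env <- new.env(parent = emptyenv())

fixture_atlas <- function() {
  if (is.null(.fixture_env$atlas)) .fixture_env$atlas <- build_atlas()
  .fixture_env$atlas
}

# A small default-parameter cohort run end to end through the pipeline:
# 14 NC + 14 PD on pseudo-scanner 1 (split 7:3), 7 + 7 on pseudo-scanner 2
# (entirely test set 2). Used by the directional and model-comparison
# tests so the cohort is simulated and featurised only once.
fixture_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    cfg <- pipeline_config(
      phantom = phantom_params(sizes = c(nc1 = 14, pd1 = 14, nc2 = 7,
                                         pd2 = 7), seed = 11),
      seed = 11)
    .fixture_env$pipeline <- run_pipeline(cfg)
  }
  .fixture_env$pipeline
}
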