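# Shared setup for the numbered analysis drivers. The full pipeline run
# on the default synthetic world is memoized under scratch/ so each
# driver can be re-run independently without recomputing upstream
# stages; delete scratch/pipeline.rds to force a fresh run.

library(paleorefugia)

MASTER_SEED <- 1

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

get_pipeline <- function(seed = MASTER_SEED) {
  cache <- file.path("scratch", sprintf("pipeline_seed%d.rds", seed))
  if (file.exists(cache)) return(readRDS(cache))
  message("running full pipeline on the default synthetic world ...")
  p <- suppressWarnings(run_pipeline(sim_config(seed = seed)))
  saveRDS(p, cache)
  p
}
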