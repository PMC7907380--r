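# Shared settings for the numbered analysis scripts. Each script is a thin
# driver over the sentinelews package: it states what it found and writes
# tables under results/; heavyweight intermediates are cached under scratch/
# (not part of the deliverable) so later scripts can reuse earlier stages.

library(sentinelews)
library(data.table)

RESULTS <- "results"
SCRATCH <- "scratch"
dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

MASTER_SEED <- 101
N_INTRUSIONS <- 10

study_config <- function(response = TRUE) {
  ews_config(seed = MASTER_SEED,
             n_per_species = c(zebra = 20, wildebeest = 20),
             response_enabled = response)
}

cache <- function(name, expr) {
  path <- file.path(SCRATCH, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- expr
  saveRDS(val, path)
  val
}

# reduced-scale classifier settings used throughout this analysis
# (documented in the methods vignette): smaller forest and cluster count
# matched to the 20-segment study
study_spec <- function() behavior_spec(rf_rows = 1500, rf_ntree = 120,
                                       n_clusters = 10)
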