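# Shared settings for the analysis scripts. The cohort reproduces the
# two-scanner design (dataset 1 split 7:3 into train/test1, dataset 2
# entirely test2) at a reduced size so the whole workflow runs in minutes;
# set `sizes <- c(nc1 = 81, pd1 = 239, nc2 = 20, pd2 = 73)` for the
# full-scale design.
library(striatomics)

sizes <- c(nc1 = 24, pd1 = 72, nc2 = 8, pd2 = 24)
root_seed <- 1L
results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

params <- phantom_params(sizes = sizes, seed = root_seed)
atlas_file <- file.path(results_dir, "atlas.nii.gz")
atlas_table <- file.path(results_dir, "atlas_regions.tsv")
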