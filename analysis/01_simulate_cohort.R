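#!/usr/bin/env Rscript
# Simulate the synthetic DAT-SPECT cohort on the standard MNI grid and
# persist the atlas and the cohort manifest. Volumes themselves are
# regenerated on demand from the per-subject seeds in the manifest, so
# nothing bulky is written.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_settings.R"))

atlas <- build_atlas()
write_atlas(atlas, atlas_file, atlas_table)
man <- cohort_manifest(params)
write.table(man, file.path(results_dir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d subjects (%d NC / %d PD), scanners: %s\n",
            nrow(man), sum(man$group == "NC"), sum(man$group == "PD"),
            paste(names(table(man$scanner)), table(man$scanner),
                  collapse = ", ", sep = "=")))
cat("atlas regions:\n")
print(atlas)
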