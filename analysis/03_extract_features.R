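#!/usr/bin/env Rscript
# Extract the 930-dimensional radiomics feature vector per subject:
# 186 IBSI-style features (intensity, histogram, IVH, local intensity,
# GLCM/GLRLM/GLSZM/GLDZM/NGTDM/NGLDM) for caudate, putamen and pallidum,
# bilaterally averaged, plus the two caudate-ratio blocks.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_settings.R"))

atlas <- read_atlas(atlas_file, atlas_table)
man <- read.delim(file.path(results_dir, "manifest.tsv"))
cfg <- radiomics_config()  # 64-bin FBN, 26-connectivity, alpha = 0

rows <- lapply(seq_len(nrow(man)), function(i) {
  set.seed(man$seed[i])
  s <- simulate_subject(params, man$group[i], man$scanner[i], atlas = atlas,
                        id = man$id[i])
  feature_vector(s, atlas, cfg)
})
ft <- cbind(man[, c("id", "group", "scanner")],
            as.data.frame(do.call(rbind, rows), check.names = FALSE))
write.table(ft, file.path(results_dir, "features.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

n_undef <- sum(!complete.cases(t(ft[, -(1:3)])))
cat(sprintf("feature table: %d subjects x %d features (%d undefined ratio features dropped downstream)\n",
            nrow(ft), ncol(ft) - 3, n_undef))
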