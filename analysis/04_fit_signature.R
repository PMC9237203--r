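#!/usr/bin/env Rscript
# Split dataset 1 into 7:3 train/test (stratified by group), z-score the
# training features, select by LASSO with ten-fold cross-validation, and
# build the radiomics signature. Dataset 2 is never touched in training.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_settings.R"))

ft <- read.delim(file.path(results_dir, "features.tsv"),
                 check.names = FALSE)
d1 <- ft$scanner == "dataset1"
sp <- stratified_split(ft$id[d1], ft$group[d1], 0.7,
                       seed = root_seed + 1L)
set <- ifelse(!d1, "test2", ifelse(ft$id %in% sp$train, "train", "test1"))
write.table(data.frame(id = ft$id, set = set),
            file.path(results_dir, "split.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tr <- set == "train"
X <- as.matrix(ft[, -(1:3)])
sig <- fit_signature(X[tr, ], as.numeric(ft$group[tr] == "PD"),
                     lambda = "cv", seed = root_seed + 2L)
write_signature(sig, file.path(results_dir, "signature.json"))

scores <- data.frame(id = ft$id, group = ft$group, scanner = ft$scanner,
                     set = set,
                     signature_score = score_signature(sig, X))
write.table(scores, file.path(results_dir, "signature_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("selected %d features at lambda = %.4g (CV min rule):\n",
            length(sig$features), sig$lambda))
print(sig)
blocks <- table(feature_block(sig$features))
cat("selected features per block:\n")
print(blocks)
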