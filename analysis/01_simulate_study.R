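#!/usr/bin/env Rscript
# Generate the default synthetic paired brain/spleen study (2 strains x
# EAE/control x 3 mice, 5000 genes with planted disease, strain and
# surrogate classes) and write its matrices, annotation and ground truth.

library(crossorgan)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(seed = 1)
study <- generate_study(spec)

write_expression_table(study$brain, file.path(out, "brain_log2.tsv"))
write_expression_table(study$spleen, file.path(out, "spleen_log2.tsv"))
write_result_table(study$annotation, file.path(out, "annotation.tsv"))
write_truth_table(study$truth, file.path(out, "truth.tsv"))

cat("study:", nrow(study$brain), "genes x", ncol(study$brain),
    "brain +", ncol(study$spleen), "spleen samples\n")
print(table(study$truth$classes))
cat("written to", out, "\n")
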