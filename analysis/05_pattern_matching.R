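#!/usr/bin/env Rscript
# Pattern matching: correlate every spleen gene with the brain PC1 scores
# across the 12 mouse-paired samples, filter by |r| > 0.8 plus a >2-fold
# (or <0.5-fold) spleen change in at least one strain, and check the
# candidates against planted ground truth.

library(crossorgan)

src <- "results/synthetic"
out <- "results/pattern_match"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

brain <- read_expression_table(file.path(src, "brain_log2.tsv"), "log2")
spleen <- read_expression_table(file.path(src, "spleen_log2.tsv"), "log2")
ann <- read_sample_annotation(file.path(src, "annotation.tsv"))
truth_tbl <- read.delim(file.path(src, "truth.tsv"))
truth <- list(classes = setNames(truth_tbl$class, truth_tbl$gene_id))

p <- run_pca(brain)
p <- orient_components(p, ann, "case_scores_positive", components = 1L)
pairing <- pair_scores(p$scores[, 1], ann)
r_table <- pearson_with_scores(spleen, pairing$brain_score,
                               pairing$spleen_sample_id)
folds <- list(strainA = fold_change_table(spleen, ann, "spleen", "strainA"),
              strainB = fold_change_table(spleen, ann, "spleen", "strainB"))
candidates <- select_surrogates(r_table, folds,
                                r_threshold = 0.8, fc_threshold = 2)

write_result_table(r_table, file.path(out, "pc1_correlation.tsv"))
write_result_table(candidates, file.path(out, "candidates.tsv"))

cat(sprintf("%d surrogate candidates: %d positive, %d negative\n",
            nrow(candidates), sum(candidates$direction == "positive"),
            sum(candidates$direction == "negative")))
cf <- truth_confusion(candidates, truth)
cat(sprintf("against planted surrogates: TP %d, FP %d, FN %d (sens %.2f)\n",
            cf$TP, cf$FP, cf$FN, cf$sensitivity))
cat("note: spleen disease-response blocks track the latent axis by design\n",
    "and legitimately appear among the candidates alongside the planted\n",
    "surrogate classes.\n")
cat("tables written to", out, "\n")
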