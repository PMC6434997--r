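#!/usr/bin/env Rscript
# PCA of the brain and spleen matrices: sample scores, proportion of
# variance per component, and factor-loading rankings for PC1. PC1 is
# oriented so EAE samples score positive; higher components so the
# largest-magnitude loading is positive.

library(crossorgan)

src <- "results/synthetic"
out <- "results/pca"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_sample_annotation(file.path(src, "annotation.tsv"))

for (organ in c("brain", "spleen")) {
  mat <- read_expression_table(file.path(src, paste0(organ, "_log2.tsv")),
                               "log2")
  p <- run_pca(mat)
  p <- orient_components(p, ann, "case_scores_positive", components = 1L)
  p <- orient_components(p, rule = "max_loading_positive",
                         components = seq_along(p$component_sd)[-1])
  cat(sprintf("%s: PC1 %.0f%%, PC2 %.0f%% of variance\n", organ,
              100 * proportion_of_variance(p, 1),
              100 * proportion_of_variance(p, 2)))
  write_result_table(data.frame(sample_id = rownames(p$scores), p$scores),
                     file.path(out, paste0("scores_", organ, ".tsv")))
  write_result_table(data.frame(component = names(p$component_sd),
                                sd = unname(p$component_sd),
                                proportion = unname(p$proportion_of_variance)),
                     file.path(out, paste0("variance_", organ, ".tsv")))
  rk <- rank_factor_loadings(p, 1, top_n = 100)
  write_result_table(rbind(cbind(side = "positive", rk$positive),
                           cbind(side = "negative", rk$negative)),
                     file.path(out, paste0("pc1_loading_rank_", organ, ".tsv")))
}
cat("tables written to", out, "\n")
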