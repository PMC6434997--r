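#!/usr/bin/env Rscript
# Cluster per-gene condition log-ratio profiles (AB, SB, AS, SS) with
# k-means, select k by the Davies-Bouldin index, and summarise the clusters
# with substantial centroid changes and their representative genes.

library(crossorgan)

src <- "results/synthetic"
out <- "results/clusters"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

brain <- read_expression_table(file.path(src, "brain_log2.tsv"), "log2")
spleen <- read_expression_table(file.path(src, "spleen_log2.tsv"), "log2")
ann <- read_sample_annotation(file.path(src, "annotation.tsv"))

fts <- list(AB = fold_change_table(brain, ann, "brain", "strainA"),
            SB = fold_change_table(brain, ann, "brain", "strainB"),
            AS = fold_change_table(spleen, ann, "spleen", "strainA"),
            SS = fold_change_table(spleen, ann, "spleen", "strainB"))
profiles <- condition_profiles(fts)

sweep <- select_cluster_number(profiles, 2:20, seed = 1)
write_result_table(sweep$table, file.path(out, "k_sweep.tsv"))
cat(sprintf("best k = %d (Davies-Bouldin %.3f)\n", sweep$best_k,
            min(sweep$table$davies_bouldin)))

model <- sweep$best_model
subst <- substantial_clusters(model, threshold = 1.0)
cat(length(subst), "of", model$k,
    "clusters have a centroid beyond +/-1 log2 in some condition\n")
write_result_table(data.frame(gene_id = names(model$assignment),
                              cluster = unname(model$assignment)),
                   file.path(out, "assignment.tsv"))
write_result_table(data.frame(cluster = seq_len(model$k), model$centroids,
                              size = model$sizes,
                              substantial = seq_len(model$k) %in% subst),
                   file.path(out, "centroids.tsv"))
reps <- do.call(rbind, lapply(subst, function(cid) {
  g <- cluster_representatives(model, profiles, cid, band_size = 80)
  data.frame(cluster = cid, rank = seq_along(g), gene_id = g)
}))
write_result_table(reps, file.path(out, "representatives.tsv"))
cat("tables written to", out, "\n")
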