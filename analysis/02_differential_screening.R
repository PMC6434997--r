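#!/usr/bin/env Rscript
# Per-organ, per-strain case/control screening: fold changes, Student t,
# volcano classification, and the top-20 up/down gene lists per contrast.
# Reads the study written by 01_simulate_study.R.

library(crossorgan)

src <- "results/synthetic"
out <- "results/differential"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

brain <- read_expression_table(file.path(src, "brain_log2.tsv"), "log2")
spleen <- read_expression_table(file.path(src, "spleen_log2.tsv"), "log2")
ann <- read_sample_annotation(file.path(src, "annotation.tsv"))

contrasts <- list(AB = c("brain", "strainA"), SB = c("brain", "strainB"),
                  AS = c("spleen", "strainA"), SS = c("spleen", "strainB"))
for (nm in names(contrasts)) {
  cc <- contrasts[[nm]]
  mat <- if (cc[1] == "brain") brain else spleen
  ft <- fold_change_table(mat, ann, cc[1], cc[2])
  vc <- volcano_classify(ft)
  write_result_table(vc$table, file.path(out, paste0("volcano_", nm, ".tsv")))
  cat(sprintf("%s (%s %s): %d up, %d down of %d genes\n", nm, cc[2], cc[1],
              vc$counts["up"], vc$counts["down"], nrow(ft)))
  for (d in c("up", "down")) {
    top <- top_ranked_genes(ft, d, n = 20)
    write_result_table(data.frame(rank = seq_along(top), gene_id = top),
                       file.path(out, paste0("top20_", d, "_", nm, ".tsv")))
  }
}
cat("tables written to", out, "\n")
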