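# Small synthetic studies shared across test files.

tiny_study <- function(seed = 1, n_genes = 300,
                       class_sizes = round(n_genes / 300 *
                                             c(brain_up_shared = 40,
                                               brain_up_strainB_only = 10,
                                               spleen_down_shared = 20,
                                               spleen_up_shared = 10,
                                               strain_marker = 10,
                                               surrogate_pos = 10,
                                               surrogate_neg = 20)), ...) {
  generate_study(synthetic_spec(seed = seed, n_genes = n_genes,
                                class_sizes = class_sizes, ...))
}

null_study <- function(seed = 1, n_genes = 500) {
  generate_study(synthetic_spec(seed = seed, n_genes = n_genes,
                                class_sizes = c(), effect_log2 = 0))
}

# the four condition fold tables of a study, in AB, SB, AS, SS order
study_fold_tables <- function(study) {
  ann <- study$annotation
  list(AB = fold_change_table(study$brain, ann, "brain", "strainA"),
       SB = fold_change_table(study$brain, ann, "brain", "strainB"),
       AS = fold_change_table(study$spleen, ann, "spleen", "strainA"),
       SS = fold_change_table(study$spleen, ann, "spleen", "strainB"))
}

# an expression matrix with given log2 values and generated ids
make_mat <- function(values) {
  values <- as.matrix(values)
  rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values)
}

# minimal two-strain paired annotation for hand-built matrices:
# samples s01..s(4n) are brain, s(4n+1)..s(8n) the matching spleens
make_annotation <- function(n_per_group = 3) {
  n_mice <- 4 * n_per_group
  mice <- sprintf("m%02d", seq_len(n_mice))
  strain <- rep(c("strainA", "strainB"), each = 2 * n_per_group)
  group <- rep(rep(c("EAE", "control"), each = n_per_group), 2)
  sample_annotation(data.frame(
    sample_id = sprintf("s%02d", seq_len(2 * n_mice)),
    mouse_id = rep(mice, 2),
    strain = rep(strain, 2),
    organ = rep(c("brain", "spleen"), each = n_mice),
    group = rep(group, 2)))
}

# run the pattern-matching arm of the pipeline on a generated study
match_pipeline <- function(study, r_threshold = 0.8, fc_threshold = 2) {
  p <- run_pca(study$brain)
  p <- orient_components(p, study$annotation, "case_scores_positive",
                         components = 1L)
  pr <- pair_scores(p$scores[, 1], study$annotation)
  rt <- pearson_with_scores(study$spleen, pr$brain_score, pr$spleen_sample_id)
  ann <- study$annotation
  fts <- list(strainA = fold_change_table(study$spleen, ann, "spleen", "strainA"),
              strainB = fold_change_table(study$spleen, ann, "spleen", "strainB"))
  select_surrogates(rt, fts, r_threshold = r_threshold,
                    fc_threshold = fc_threshold)
}
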