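#' Specification of a synthetic paired two-organ expression study
#'
#' Defines the study design the generator emulates: two mouse strains, two
#' organs (brain, spleen), EAE vs age-matched control, `n_per_group` mice per
#' strain per group, each mouse contributing one brain and one spleen sample.
#' Planted gene classes carry known ground truth:
#'
#' * `brain_up_shared` — up in EAE brains of both strains;
#' * `brain_up_strainB_only` — up in EAE brains of strain B only (CNS
#'   T-cell-infiltration-like genes);
#' * `spleen_down_shared` / `spleen_up_shared` — erythrocyte-like down- and
#'   stefin-like up-blocks in EAE spleens of both strains;
#' * `strain_marker` — constitutive strain difference, no disease effect;
#' * `surrogate_pos` / `surrogate_neg` — spleen genes tracking the latent
#'   brain disease axis at Pearson correlation `target_r` (positively or
#'   negatively), with the disease-group mean shift `effect_log2`;
#' * everything else is null.
#'
#' Disease-responsive classes are driven by a per-mouse latent disease axis
#' (one scalar, shared by both organs of that mouse) so that cross-organ
#' correlation is meaningful: gene = baseline + (effect_log2 / latent_shift)
#' * latent + noise. The expected EAE-minus-control shift is then exactly
#' `effect_log2`.
#'
#' @param n_per_group Mice per strain per group (default 3; the study design
#'   gives 2 strains x 2 groups x 3 = 12 mice, 12 paired brain/spleen pairs).
#' @param n_genes Total genes (default 5000; set 28853 to emulate the full
#'   array platform).
#' @param class_sizes Named integer vector of planted class sizes; missing
#'   classes default as documented, unnamed classes are an error. The
#'   remainder up to `n_genes` is null.
#' @param effect_log2 Planted mean EAE shift per disease class in log2 units
#'   (default 2.0, i.e. 4-fold).
#' @param noise_sd_log2 Per-gene residual SD in log2 units (default 0.4).
#' @param target_r Intended population Pearson correlation of surrogate genes
#'   with the latent disease axis (default 0.95), 0 < target_r < 1.
#' @param baseline_mean_log2,baseline_sd_log2 Gene baseline distribution
#'   (defaults 7.0, 1.5).
#' @param latent_shift Mean latent-axis difference, EAE minus control
#'   (default 3; latent ~ Normal(group mean, 1)).
#' @param strain_sd_log2 SD of the per-gene constitutive strain-B baseline
#'   offset (default 0.3), the source of PC2-like strain separation.
#' @param seed Random seed.
#' @return A validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_per_group = 3,
                           n_genes = 5000,
                           class_sizes = c(brain_up_shared = 400,
                                           brain_up_strainB_only = 100,
                                           spleen_down_shared = 200,
                                           spleen_up_shared = 50,
                                           strain_marker = 50,
                                           surrogate_pos = 30,
                                           surrogate_neg = 300),
                           effect_log2 = 2.0,
                           noise_sd_log2 = 0.4,
                           target_r = 0.95,
                           baseline_mean_log2 = 7.0,
                           baseline_sd_log2 = 1.5,
                           latent_shift = 3,
                           strain_sd_log2 = 0.3,
                           seed = 1L) {
  known <- c("brain_up_shared", "brain_up_strainB_only", "spleen_down_shared",
             "spleen_up_shared", "strain_marker", "surrogate_pos",
             "surrogate_neg")
  sizes <- stats::setNames(rep(0L, length(known)), known)
  if (length(class_sizes)) {
    bad <- setdiff(names(class_sizes), known)
    if (length(bad)) stop("unknown planted class(es): ", paste(bad, collapse = ", "))
    sizes[names(class_sizes)] <- as.integer(class_sizes)
  }
  if (any(sizes < 0)) stop("class sizes must be non-negative")
  if (sum(sizes) > n_genes) stop("class sizes exceed n_genes")
  if (n_per_group < 2) stop("n_per_group must be >= 2 (correlation undefined below)")
  if (!(target_r > 0 && target_r < 1)) stop("target_r must lie in (0, 1)")
  if (noise_sd_log2 <= 0) stop("noise_sd_log2 must be positive")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_genes = as.integer(n_genes),
                 class_sizes = sizes,
                 effect_log2 = effect_log2,
                 noise_sd_log2 = noise_sd_log2,
                 target_r = target_r,
                 baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 latent_shift = latent_shift,
                 strain_sd_log2 = strain_sd_log2,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic paired brain/spleen expression study
#'
#' Draws a study under a [synthetic_spec()]: a per-mouse latent disease axis
#' latent ~ Normal(0, 1) for controls and Normal(`latent_shift`, 1) for EAE
#' mice; gene baselines; a per-gene strain-B offset ~ Normal(0,
#' `strain_sd_log2`); then one log2 matrix per organ. Disease classes add
#' (effect_log2 / latent_shift) * latent to their target organ/strain
#' samples. Surrogate genes are built as baseline + b * latent + eps with
#' b = effect_log2 / latent_shift (sign per class) and
#' Var(eps) = b^2 * Var(latent) * (1 / target_r^2 - 1), which makes the
#' population correlation with the latent axis exactly `target_r` (Var(latent)
#' is the equal-weight group mixture variance 1 + (latent_shift / 2)^2).
#' Identical spec (including seed) gives bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `brain` and `spleen` ([expression_matrix()]),
#'   `annotation` ([sample_annotation()]), and `truth` (list with `classes`,
#'   a gene -> class vector, and `latent`, the per-mouse latent scores).
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_group
  strains <- c("strainA", "strainB")
  groups <- c("EAE", "control")
  mice <- expand.grid(rep = seq_len(n), group = groups, strain = strains,
                      stringsAsFactors = FALSE)
  mice$mouse_id <- sprintf("m%02d", seq_len(nrow(mice)))
  n_mice <- nrow(mice)

  latent <- stats::rnorm(n_mice,
                         mean = ifelse(mice$group == "EAE", spec$latent_shift, 0),
                         sd = 1)
  names(latent) <- mice$mouse_id

  g_ids <- sprintf("g%05d", seq_len(spec$n_genes))
  classes <- rep("null", spec$n_genes)
  idx <- 0L
  for (cl in names(spec$class_sizes)) {
    sz <- spec$class_sizes[[cl]]
    if (sz > 0) {
      classes[(idx + 1):(idx + sz)] <- cl
      idx <- idx + sz
    }
  }
  names(classes) <- g_ids

  baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean_log2,
                           spec$baseline_sd_log2)
  strain_off <- stats::rnorm(spec$n_genes, 0, spec$strain_sd_log2)

  slope <- spec$effect_log2 / spec$latent_shift
  var_latent <- 1 + (spec$latent_shift / 2)^2
  eps_sd <- sqrt(slope^2 * var_latent * (1 / spec$target_r^2 - 1))

  is_B <- mice$strain == "strainB"
  one <- rep(1, n_mice)

  build_organ <- function(organ) {
    # systematic part: baseline + strain offset (+ strain_marker shift)
    m <- outer(baseline, one)
    m <- m + outer(strain_off, as.numeric(is_B))
    m <- m + outer(as.numeric(classes == "strain_marker") * spec$effect_log2,
                   as.numeric(is_B))
    add_latent <- function(class, sign, mouse_mask) {
      outer(as.numeric(classes == class) * sign * slope,
            latent * as.numeric(mouse_mask))
    }
    if (organ == "brain") {
      m <- m + add_latent("brain_up_shared", +1, one > 0)
      m <- m + add_latent("brain_up_strainB_only", +1, is_B)
    } else {
      m <- m + add_latent("spleen_down_shared", -1, one > 0)
      m <- m + add_latent("spleen_up_shared", +1, one > 0)
      m <- m + add_latent("surrogate_pos", +1, one > 0)
      m <- m + add_latent("surrogate_neg", -1, one > 0)
    }
    sd_row <- rep(spec$noise_sd_log2, spec$n_genes)
    if (organ == "spleen") {
      sd_row[classes %in% c("surrogate_pos", "surrogate_neg")] <- eps_sd
    }
    m <- m + matrix(stats::rnorm(length(m), 0, rep(sd_row, n_mice)),
                    nrow = spec$n_genes)
    dimnames(m) <- list(g_ids, paste(mice$mouse_id, organ, sep = "_"))
    expression_matrix(m, scale = "log2")
  }

  brain <- build_organ("brain")
  spleen <- build_organ("spleen")

  ann <- do.call(rbind, lapply(c("brain", "spleen"), function(org) {
    data.frame(sample_id = paste(mice$mouse_id, org, sep = "_"),
               mouse_id = mice$mouse_id, strain = mice$strain,
               organ = org, group = mice$group, stringsAsFactors = FALSE)
  }))
  ann <- sample_annotation(ann)

  list(brain = brain, spleen = spleen, annotation = ann,
       truth = list(classes = classes, latent = latent))
}

#' Confusion counts of surrogate candidates against planted truth
#'
#' Partitions the spleen gene universe by planted positives (classes
#' `surrogate_pos` and `surrogate_neg`) versus everything else, and by
#' membership in the candidate list.
#'
#' @param candidates Character vector of candidate gene ids, or a data frame
#'   with a `gene_id` column (e.g. output of [select_surrogates()]).
#' @param truth The `truth` element of [generate_study()] output.
#' @return Named integer vector `c(TP, FP, FN, TN)` plus `sensitivity` and
#'   `fdr` as attributes-free list entries.
#' @export
truth_confusion <- function(candidates, truth) {
  if (is.data.frame(candidates)) candidates <- candidates$gene_id
  candidates <- as.character(candidates)
  universe <- names(truth$classes)
  unknown <- setdiff(candidates, universe)
  if (length(unknown)) {
    stop("candidate gene id(s) not in truth universe: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  planted <- truth$classes %in% c("surrogate_pos", "surrogate_neg")
  called <- universe %in% candidates
  tp <- sum(planted & called)
  fp <- sum(!planted & called)
  fn <- sum(planted & !called)
  tn <- sum(!planted & !called)
  list(TP = tp, FP = fp, FN = fn, TN = tn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_)
}

#' Write a ground-truth table
#'
#' @param truth The `truth` element of [generate_study()] output.
#' @param path Output TSV path (columns `gene_id`, `class`).
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write_result_table(data.frame(gene_id = names(truth$classes),
                                class = unname(truth$classes)), path)
}
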