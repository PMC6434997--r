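#' Build and validate a pipeline configuration
#'
#' Exactly one of `inputs` (paths to real data) or `synthetic` (a
#' [synthetic_spec()] or argument list for one) must be supplied. Thresholds
#' default to the analysis' standard screen: 2-fold, p < 0.05, |r| > 0.8,
#' centroid log-ratio 1.0, 20 heat-map genes, 100 loading-ranked genes.
#'
#' @param inputs Optional list with `brain`, `spleen`, `annotation` paths and
#'   optionally `human_de` (TSV: symbol, direction, p_value) and `probe_map`
#'   (TSV: probe_id, symbol).
#' @param synthetic Optional [synthetic_spec()] or list of its arguments.
#' @param thresholds Optional overrides: `fc`, `p`, `r`, `centroid`,
#'   `top_n_heatmap`, `loading_top_n`.
#' @param k_range Candidate cluster numbers (default 2:50).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param out_dir Output directory for tables and the run manifest.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(inputs = NULL, synthetic = NULL,
                            thresholds = list(), k_range = 2:50,
                            seed = 1L, out_dir = "results") {
  if (is.null(inputs) == is.null(synthetic)) {
    stop("exactly one of `inputs` and `synthetic` must be given")
  }
  thr <- list(fc = 2, p = 0.05, r = 0.8, centroid = 1.0,
              top_n_heatmap = 20, loading_top_n = 100)
  bad <- setdiff(names(thresholds), names(thr))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  thr[names(thresholds)] <- thresholds
  if (!(thr$fc > 1)) stop("fc threshold must exceed 1")
  if (!(thr$p > 0 && thr$p < 1)) stop("p threshold must be in (0, 1)")
  if (!(thr$r > 0 && thr$r < 1)) stop("r threshold must be in (0, 1)")
  if (thr$centroid <= 0) stop("centroid threshold must be positive")
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_spec")) {
    synthetic <- do.call(synthetic_spec, as.list(synthetic))
  }
  if (!is.null(inputs)) {
    need <- c("brain", "spleen", "annotation")
    missing <- setdiff(need, names(inputs))
    if (length(missing)) {
      stop("inputs missing: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(inputs = inputs, synthetic = synthetic, thresholds = thr,
                 k_range = as.integer(k_range), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys: `inputs` or `synthetic`, `thresholds`, `k_range` (either a
#' vector or `{from, to}`), `seed`, `out_dir`. Unknown top-level keys are an
#' error.
#'
#' @param path YAML file path.
#' @return A validated [pipeline_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("inputs", "synthetic", "thresholds", "k_range", "seed", "out_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  k_range <- raw$k_range
  if (is.list(k_range) && all(c("from", "to") %in% names(k_range))) {
    k_range <- seq.int(k_range$from, k_range$to)
  }
  pipeline_config(inputs = raw$inputs, synthetic = raw$synthetic,
                  thresholds = if (is.null(raw$thresholds)) list() else raw$thresholds,
                  k_range = if (is.null(k_range)) 2:50 else k_range,
                  seed = if (is.null(raw$seed)) 1L else raw$seed,
                  out_dir = if (is.null(raw$out_dir)) "results" else raw$out_dir)
}

#' Dump a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$synthetic)) {
    x$synthetic <- lapply(unclass(x$synthetic), function(v) {
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
    })
  }
  x$k_range <- list(from = min(config$k_range), to = max(config$k_range))
  yaml::write_yaml(x, path)
  invisible(path)
}

# deterministic per-stage seed derived from the global seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

#' Run the full cross-organ surrogate-marker analysis
#'
#' Executes, in order: input loading (or synthetic generation); per-organ,
#' per-strain differential tables with volcano counts and top-N up/down
#' lists; condition log-ratio profiles, the Davies-Bouldin k sweep,
#' substantial clusters and their representatives; brain and spleen PCA with
#' variance proportions and factor-loading rankings; pattern matching of
#' spleen genes against brain PC1 and candidate selection; optionally the
#' human concordance intersection. All stage outputs are written as flat
#' TSVs under `config$out_dir`, plus `manifest.json` recording the config,
#' seed, package and R versions, and an MD5 checksum of every output.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines? Default `FALSE`.
#' @return Invisibly, a list with every intermediate result (`study`,
#'   `fold_tables`, `volcano`, `top_genes`, `profiles`, `sweep`,
#'   `substantial`, `representatives`, `pca`, `pairing`, `r_table`,
#'   `candidates`, `concordant`, `manifest`).
#' @export
run_full <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- config$thresholds
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, ...) {
    if (!quiet) {
      message(sprintf("[%s] %s (%.1fs)", stage, paste0(...),
                      proc.time()[["elapsed"]] - t0))
    }
  }
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_result_table(df, path)
    written <<- c(written, path)
    path
  }

  # --- load or simulate -----------------------------------------------------
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    spec$seed <- stage_seed(config$seed, "simulate")
    study <- generate_study(spec)
    write_truth_table(study$truth, file.path(config$out_dir, "truth.tsv"))
    written <- c(written, file.path(config$out_dir, "truth.tsv"))
  } else {
    brain <- read_expression_table(config$inputs$brain)
    spleen <- read_expression_table(config$inputs$spleen)
    ann <- read_sample_annotation(config$inputs$annotation)
    if (!is.null(config$inputs$probe_map)) {
      pm <- utils::read.delim(config$inputs$probe_map, colClasses = "character")
      map <- stats::setNames(pm[[2]], pm[[1]])
      brain <- collapse_probes_to_symbols(brain, map)
      spleen <- collapse_probes_to_symbols(spleen, map)
    }
    study <- list(brain = brain, spleen = spleen, annotation = ann,
                  truth = NULL)
  }
  ann <- study$annotation
  strains <- sort(unique(ann$strain))
  if (length(strains) != 2) stop("expected exactly 2 strains, got ",
                                 length(strains))
  log_stage("load", sprintf("%d genes x %d brain / %d spleen samples",
                            nrow(study$brain), ncol(study$brain),
                            ncol(study$spleen)))

  # --- differential screening ----------------------------------------------
  contrasts <- list(AB = list(organ = "brain", strain = strains[1]),
                    SB = list(organ = "brain", strain = strains[2]),
                    AS = list(organ = "spleen", strain = strains[1]),
                    SS = list(organ = "spleen", strain = strains[2]))
  fold_tables <- lapply(contrasts, function(cc) {
    m <- if (cc$organ == "brain") study$brain else study$spleen
    fold_change_table(m, ann, cc$organ, cc$strain)
  })
  volcano <- lapply(fold_tables, volcano_classify,
                    fc_threshold = thr$fc, p_threshold = thr$p)
  top_genes <- lapply(names(fold_tables), function(nm) {
    list(up = top_ranked_genes(fold_tables[[nm]], "up", thr$top_n_heatmap,
                               thr$fc, thr$p),
         down = top_ranked_genes(fold_tables[[nm]], "down", thr$top_n_heatmap,
                                 thr$fc, thr$p))
  })
  names(top_genes) <- names(fold_tables)
  for (nm in names(fold_tables)) {
    emit(volcano[[nm]]$table, paste0("differential_", nm, ".tsv"))
  }
  emit(data.frame(contrast = rep(names(volcano), each = 3),
                  label = unlist(lapply(volcano, function(v) names(v$counts))),
                  count = unlist(lapply(volcano, function(v) unname(v$counts)))),
       "volcano_counts.tsv")
  emit(do.call(rbind, lapply(names(top_genes), function(nm) {
    do.call(rbind, lapply(c("up", "down"), function(d) {
      g <- top_genes[[nm]][[d]]
      if (length(g) == 0) return(NULL)
      data.frame(contrast = nm, direction = d, rank = seq_along(g), gene_id = g)
    }))
  })), "top_genes.tsv")
  log_stage("differential", "4 contrasts screened")

  # --- clustering -----------------------------------------------------------
  profiles <- condition_profiles(fold_tables)
  sweep <- select_cluster_number(profiles, config$k_range,
                                 seed = stage_seed(config$seed, "cluster"))
  model <- sweep$best_model
  subst <- substantial_clusters(model, thr$centroid)
  reps <- lapply(subst, function(cid) {
    cluster_representatives(model, profiles, cid)
  })
  names(reps) <- as.character(subst)
  emit(sweep$table, "k_sweep.tsv")
  emit(data.frame(gene_id = names(model$assignment),
                  cluster = unname(model$assignment)), "cluster_assignment.tsv")
  emit(data.frame(cluster = seq_len(model$k), model$centroids,
                  size = model$sizes,
                  substantial = seq_len(model$k) %in% subst),
       "cluster_centroids.tsv")
  emit(do.call(rbind, lapply(names(reps), function(cid) {
    data.frame(cluster = cid, rank = seq_along(reps[[cid]]),
               gene_id = reps[[cid]])
  })), "cluster_representatives.tsv")
  log_stage("cluster", sprintf("best k = %d (DB %.3f), %d substantial",
                               sweep$best_k,
                               min(sweep$table$davies_bouldin), length(subst)))

  # --- PCA ------------------------------------------------------------------
  pca <- lapply(list(brain = study$brain, spleen = study$spleen), function(m) {
    p <- run_pca(m)
    p <- orient_components(p, ann, "case_scores_positive", components = 1L)
    if (length(p$component_sd) > 1) {
      p <- orient_components(p, rule = "max_loading_positive",
                             components = seq_along(p$component_sd)[-1])
    }
    p
  })
  for (org in names(pca)) {
    p <- pca[[org]]
    emit(data.frame(sample_id = rownames(p$scores), p$scores),
         paste0("pca_scores_", org, ".tsv"))
    emit(data.frame(component = names(p$component_sd),
                    sd = unname(p$component_sd),
                    proportion = unname(p$proportion_of_variance)),
         paste0("pca_variance_", org, ".tsv"))
    rk <- rank_factor_loadings(p, 1, thr$loading_top_n)
    emit(rbind(data.frame(side = "positive", rank = seq_len(nrow(rk$positive)),
                          rk$positive),
               data.frame(side = "negative", rank = seq_len(nrow(rk$negative)),
                          rk$negative)),
         paste0("pca_loading_rank_", org, ".tsv"))
  }
  log_stage("pca", sprintf("brain PC1 %.0f%%, spleen PC1 %.0f%%",
                           100 * pca$brain$proportion_of_variance[1],
                           100 * pca$spleen$proportion_of_variance[1]))

  # --- pattern matching -----------------------------------------------------
  pairing <- pair_scores(pca$brain$scores[, 1], ann)
  r_table <- pearson_with_scores(study$spleen, pairing$brain_score,
                                 pairing$spleen_sample_id)
  spleen_folds <- fold_tables[c("AS", "SS")]
  names(spleen_folds) <- strains
  candidates <- select_surrogates(r_table, spleen_folds,
                                  r_threshold = thr$r, fc_threshold = thr$fc)
  emit(r_table, "pattern_match_r.tsv")
  emit(candidates, "surrogate_candidates.tsv")
  log_stage("match", sprintf("%d candidates (%d positive, %d negative)",
                             nrow(candidates),
                             sum(candidates$direction == "positive"),
                             sum(candidates$direction == "negative")))

  # --- optional human concordance ------------------------------------------
  concordant <- NULL
  if (!is.null(config$inputs$human_de)) {
    human <- utils::read.delim(config$inputs$human_de)
    concordant <- intersect_external_de(candidates, human, p_threshold = thr$p)
    emit(concordant, "human_concordant.tsv")
    log_stage("human", sprintf("%d concordant gene(s)", nrow(concordant)))
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    config = list(thresholds = thr, k_range = range(config$k_range),
                  seed = config$seed,
                  mode = if (is.null(config$synthetic)) "real" else "synthetic"),
    versions = list(package = as.character(utils::packageVersion("crossorgan")),
                    r = R.version.string),
    outputs = as.list(stats::setNames(unname(tools::md5sum(written)),
                                      basename(written))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_stage("done", length(written), " tables + manifest written")

  invisible(list(study = study, fold_tables = fold_tables, volcano = volcano,
                 top_genes = top_genes, profiles = profiles, sweep = sweep,
                 substantial = subst, representatives = reps, pca = pca,
                 pairing = pairing, r_table = r_table,
                 candidates = candidates, concordant = concordant,
                 manifest = manifest))
}
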