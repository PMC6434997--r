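#' Align brain PC1 scores with spleen samples by mouse
#'
#' Every mouse must contribute exactly one brain and one spleen sample. The
#' canonical ordering is by mouse id (lexicographic), so shuffled annotation
#' rows give identical output.
#'
#' @param brain_scores Named numeric vector of PC1 scores, names = brain
#'   sample ids.
#' @param annotation A [sample_annotation()] covering both organs.
#' @return List with `mouse_id`, `brain_score` and `spleen_sample_id`, all
#'   aligned to the canonical mouse order.
#' @export
pair_scores <- function(brain_scores, annotation) {
  br <- annotation[annotation$organ == "brain", ]
  sp <- annotation[annotation$organ == "spleen", ]
  mice <- sort(unique(annotation$mouse_id))
  missing_br <- setdiff(mice, br$mouse_id)
  missing_sp <- setdiff(mice, sp$mouse_id)
  if (length(missing_br) || length(missing_sp)) {
    stop("unpaired mouse (one organ only): ",
         paste(unique(c(missing_br, missing_sp)), collapse = ", "))
  }
  br_sample <- br$sample_id[match(mice, br$mouse_id)]
  if (!all(br_sample %in% names(brain_scores))) {
    stop("brain scores missing for sample(s): ",
         paste(setdiff(br_sample, names(brain_scores)), collapse = ", "))
  }
  list(mouse_id = mice,
       brain_score = unname(brain_scores[br_sample]),
       spleen_sample_id = sp$sample_id[match(mice, sp$mouse_id)])
}

#' Pearson correlation of every spleen gene with a score vector
#'
#' Correlates each gene's log2 values, over the paired samples in the given
#' order, with the brain PC1 score vector. Genes with zero variance across
#' the pairs have undefined correlation; they are returned as `NA` and never
#' become candidates.
#'
#' @param spleen_mat An [expression_matrix()] for the spleen.
#' @param score_vector Numeric scores, one per pair (e.g. brain PC1).
#' @param sample_order Spleen sample ids aligned with `score_vector`.
#' @return Data frame `gene_id`, `r`, `n_pairs`.
#' @export
pearson_with_scores <- function(spleen_mat, score_vector, sample_order) {
  if (length(score_vector) < 3) stop("need >= 3 paired samples")
  if (length(score_vector) != length(sample_order)) {
    stop("score_vector and sample_order lengths differ")
  }
  if (!all(sample_order %in% colnames(spleen_mat))) {
    stop("sample(s) absent from the spleen matrix: ",
         paste(setdiff(sample_order, colnames(spleen_mat)), collapse = ", "))
  }
  vals <- unclass(spleen_mat)[, sample_order, drop = FALSE]
  sds <- apply(vals, 1L, stats::sd)
  r <- rep(NA_real_, nrow(vals))
  ok <- sds > 0
  if (any(ok)) {
    r[ok] <- as.vector(stats::cor(t(vals[ok, , drop = FALSE]), score_vector))
  }
  data.frame(gene_id = rownames(vals), r = r,
             n_pairs = length(score_vector), row.names = NULL)
}

#' Select spleen surrogate-marker candidates
#'
#' The pattern-matching filter: a positive candidate correlates with the
#' brain PC1 scores at r strictly above `r_threshold` and is up-regulated
#' more than `fc_threshold`-fold in at least one strain's spleen; a negative
#' candidate has r strictly below `-r_threshold` and is down-regulated below
#' 1/`fc_threshold` in at least one strain. Direction of fold change must
#' agree with the sign of r. Output is sorted by |r| descending.
#'
#' @param r_table Output of [pearson_with_scores()].
#' @param fold_tables Named list of spleen [fold_change_table()] outputs, one
#'   per strain.
#' @param r_threshold Correlation cutoff (default 0.8).
#' @param fc_threshold Fold-change cutoff (default 2).
#' @return Data frame of passing candidates: `gene_id`, `r`, one `fc_` column
#'   per strain, `direction` (`positive`/`negative`), `passes`, `n_pairs`.
#' @export
select_surrogates <- function(r_table, fold_tables, r_threshold = 0.8,
                              fc_threshold = 2) {
  if (!(r_threshold > 0 && r_threshold < 1)) stop("r_threshold must be in (0, 1)")
  if (!(fc_threshold > 1)) stop("fc_threshold must exceed 1")
  ids <- r_table$gene_id
  fc <- vapply(fold_tables, function(t) {
    if (!identical(sort(t$gene_id), sort(ids))) {
      stop("fold table gene universe differs from the correlation table")
    }
    t$fold_change[match(ids, t$gene_id)]
  }, numeric(length(ids)))
  fc_max <- apply(fc, 1L, max)
  fc_min <- apply(fc, 1L, min)
  r <- r_table$r
  pos <- !is.na(r) & r > r_threshold & fc_max > fc_threshold
  neg <- !is.na(r) & r < -r_threshold & fc_min < 1 / fc_threshold
  out <- data.frame(gene_id = ids, r = r, fc,
                    direction = ifelse(pos, "positive",
                                       ifelse(neg, "negative", "none")),
                    passes = pos | neg,
                    n_pairs = r_table$n_pairs,
                    row.names = NULL, check.names = FALSE)
  names(out)[2 + seq_len(ncol(fc))] <-
    paste0("fc_", if (is.null(colnames(fc))) seq_len(ncol(fc)) else colnames(fc))
  out <- out[out$passes, , drop = FALSE]
  out[order(-abs(out$r), out$gene_id, method = "radix"), , drop = FALSE]
}

#' Intersect candidates with an external human differential table
#'
#' Keeps candidates for which a human record exists with p below
#' `p_threshold` and a direction concordant with the candidate
#' (positive candidate and human `up`, or negative and `down`). Matching is
#' by uppercase gene symbol unless an explicit mouse-to-human map is given;
#' unmatched candidates are dropped, with a message giving the count.
#'
#' @param candidates Output of [select_surrogates()].
#' @param human_table Data frame with columns `symbol` (uppercase human
#'   symbol), `direction` (`up`/`down`), `p_value`.
#' @param symbol_map Optional named character vector, mouse gene id -> human
#'   symbol; default is `toupper` of the mouse id.
#' @param p_threshold Human significance cutoff (default 0.05).
#' @return Data frame `gene_id`, `human_symbol`, `direction`,
#'   `human_direction`, `human_p`.
#' @export
intersect_external_de <- function(candidates, human_table, symbol_map = NULL,
                                  p_threshold = 0.05) {
  need <- c("symbol", "direction", "p_value")
  if (nrow(candidates) == 0 || nrow(human_table) == 0) {
    return(data.frame(gene_id = character(0), human_symbol = character(0),
                      direction = character(0),
                      human_direction = character(0),
                      human_p = numeric(0)))
  }
  missing <- setdiff(need, names(human_table))
  if (length(missing)) {
    stop("human table missing column(s): ", paste(missing, collapse = ", "))
  }
  sym <- if (is.null(symbol_map)) {
    toupper(candidates$gene_id)
  } else {
    unname(symbol_map[candidates$gene_id])
  }
  hit <- match(sym, toupper(human_table$symbol))
  unmatched <- sum(is.na(hit))
  if (unmatched > 0) {
    message(unmatched, " candidate(s) had no human record and were dropped")
  }
  keep <- !is.na(hit)
  hd <- tolower(human_table$direction[hit[keep]])
  hp <- human_table$p_value[hit[keep]]
  concordant <- hp < p_threshold &
    ((candidates$direction[keep] == "positive" & hd == "up") |
     (candidates$direction[keep] == "negative" & hd == "down"))
  data.frame(gene_id = candidates$gene_id[keep][concordant],
             human_symbol = sym[keep][concordant],
             direction = candidates$direction[keep][concordant],
             human_direction = hd[concordant],
             human_p = hp[concordant],
             row.names = NULL)
}
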