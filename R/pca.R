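#' Principal component analysis of an expression matrix
#'
#' Unsupervised PCA of samples in gene space: each gene is centred across
#' samples (no unit-variance scaling), and the centred samples x genes
#' matrix is decomposed by SVD — the behaviour of `prcomp` with its default
#' settings, which is used internally. Components are ordered by decreasing
#' variance (divisor n - 1) and truncated to min(samples - 1, genes).
#'
#' @param mat An [expression_matrix()] (genes x samples).
#' @return List of class `"pca_result"`: `scores` (samples x components),
#'   `loadings` (genes x components, unit-norm columns), `component_sd`,
#'   `proportion_of_variance`, `orientation` (per-component sign applied so
#'   far, all +1 initially).
#' @export
run_pca <- function(mat) {
  x <- t(unclass(mat))            # samples x genes
  if (nrow(x) < 2) stop("PCA needs >= 2 samples")
  if (ncol(x) < 1) stop("PCA needs >= 1 gene")
  if (all(apply(x, 2L, stats::var) == 0)) {
    stop("all genes constant: total variance is zero")
  }
  n_comp <- min(nrow(x) - 1L, ncol(x))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_comp)
  sdev <- p$sdev[seq_len(n_comp)]
  total_var <- sum(p$sdev^2)
  comp <- paste0("PC", seq_len(n_comp))
  scores <- p$x[, seq_len(n_comp), drop = FALSE]
  loadings <- p$rotation[, seq_len(n_comp), drop = FALSE]
  dimnames(scores) <- list(rownames(x), comp)
  dimnames(loadings) <- list(colnames(x), comp)
  structure(list(scores = scores, loadings = loadings,
                 component_sd = stats::setNames(sdev, comp),
                 proportion_of_variance =
                   stats::setNames(sdev^2 / total_var, comp),
                 orientation = stats::setNames(rep(1, n_comp), comp)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$component_sd))
  cat(sprintf("pca_result: %d samples, %d genes, %d components\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  cat("proportion of variance:",
      paste(sprintf("%s %.1f%%", names(x$proportion_of_variance)[1:k],
                    100 * x$proportion_of_variance[1:k]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Proportion of variance explained by one component
#'
#' @param result A [run_pca()] result.
#' @param component Component index (1-based) or name (`"PC1"`).
#' @return The fraction of total sample variance, in \[0, 1\].
#' @export
proportion_of_variance <- function(result, component) {
  p <- result$proportion_of_variance
  if (is.character(component)) component <- match(component, names(p))
  if (is.na(component) || component < 1 || component > length(p)) {
    stop("component out of range")
  }
  unname(p[component])
}

#' Rank genes by factor loading on one component
#'
#' Genes sorted by their loading, descending; the `top_n` head (largest
#' positive loadings) and `top_n` tail (most negative first) are returned.
#' Ties broken lexicographically by gene id.
#'
#' @param result A [run_pca()] result.
#' @param component Component index or name.
#' @param top_n List length (default 100); truncated to the gene count.
#' @return List with `positive` and `negative` data frames (`gene_id`,
#'   `loading`), each ordered by contribution strength.
#' @export
rank_factor_loadings <- function(result, component = 1, top_n = 100) {
  if (is.character(component)) {
    component <- match(component, colnames(result$loadings))
  }
  if (is.na(component) || component < 1 || component > ncol(result$loadings)) {
    stop("component out of range")
  }
  if (top_n < 1) stop("top_n must be >= 1")
  l <- result$loadings[, component]
  ids <- names(l)
  ord <- order(-l, ids, method = "radix")
  n <- min(top_n, length(l))
  pos <- ord[seq_len(n)]
  neg <- rev(ord)[seq_len(n)]       # most negative loading first
  list(positive = data.frame(gene_id = ids[pos], loading = unname(l[pos])),
       negative = data.frame(gene_id = ids[neg], loading = unname(l[neg])))
}

#' Fix the sign of principal components
#'
#' SVD leaves each component's sign arbitrary; this flips scores and
#' loadings together so a stated convention holds, leaving the
#' scores %*% t(loadings) reconstruction unchanged. Rules:
#' `"max_loading_positive"` — the largest-magnitude loading is positive;
#' `"case_scores_positive"` — the mean score of case (EAE) samples exceeds
#' the control mean, so "up with disease" is the positive direction.
#' Idempotent.
#'
#' @param result A [run_pca()] result.
#' @param annotation A [sample_annotation()]; required for
#'   `"case_scores_positive"`.
#' @param rule Orientation rule.
#' @param components Which components to orient (default: all).
#' @return The result with flips applied and recorded in `orientation`.
#' @export
orient_components <- function(result, annotation = NULL,
                              rule = c("max_loading_positive",
                                       "case_scores_positive"),
                              components = seq_along(result$component_sd)) {
  rule <- match.arg(rule)
  for (j in components) {
    flip <- FALSE
    if (rule == "max_loading_positive") {
      l <- result$loadings[, j]
      flip <- l[which.max(abs(l))] < 0
    } else {
      if (is.null(annotation)) stop("case_scores_positive needs an annotation")
      ann <- annotation[annotation$sample_id %in% rownames(result$scores), ]
      case_ids <- ann$sample_id[ann$group == "EAE"]
      ctrl_ids <- ann$sample_id[ann$group == "control"]
      if (length(case_ids) == 0) stop("no case (EAE) samples in annotation")
      ref <- if (length(ctrl_ids)) mean(result$scores[ctrl_ids, j]) else 0
      flip <- mean(result$scores[case_ids, j]) < ref
    }
    if (flip) {
      result$scores[, j] <- -result$scores[, j]
      result$loadings[, j] <- -result$loadings[, j]
      result$orientation[j] <- -result$orientation[j]
    }
  }
  result
}
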