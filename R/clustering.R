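#' Condition log-ratio profiles
#'
#' Builds, per gene, the 4-vector of log2(EAE/control) ratios over the fixed
#' condition order AB, SB, AS, SS (strain A brain, strain B brain, strain A
#' spleen, strain B spleen) — the feature space in which cluster patterns and
#' radar charts are expressed.
#'
#' @param fold_tables List of four [fold_change_table()] outputs, in AB, SB,
#'   AS, SS order (names, if present, are kept for documentation only).
#' @return Numeric matrix, genes x 4, columns `AB`, `SB`, `AS`, `SS`.
#' @export
condition_profiles <- function(fold_tables) {
  if (length(fold_tables) != 4) stop("need exactly four fold tables (AB, SB, AS, SS)")
  ids <- fold_tables[[1]]$gene_id
  for (t in fold_tables[-1]) {
    if (!identical(sort(t$gene_id), sort(ids))) {
      stop("fold tables do not share a common gene universe")
    }
  }
  prof <- vapply(fold_tables, function(t) {
    t$log2_ratio[match(ids, t$gene_id)]
  }, numeric(length(ids)))
  if (!is.matrix(prof)) prof <- matrix(prof, nrow = 1)
  dimnames(prof) <- list(ids, c("AB", "SB", "AS", "SS"))
  if (!all(is.finite(prof))) stop("non-finite log2 ratios in condition profiles")
  prof
}

# squared Euclidean distances between rows of x and rows of centers
.sqdist <- function(x, centers) {
  d <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  d[d < 0] <- 0
  d
}

# k-means++ initialisation (Arthur & Vassilvitskii): first centre uniform,
# then each next centre with probability proportional to squared distance to
# the nearest chosen centre.
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- .sqdist(x, centers[1, , drop = FALSE])[, 1]
  for (i in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[i + 1, ] <- x[sample.int(n, 1), ]
    } else {
      centers[i + 1, ] <- x[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, .sqdist(x, centers[i + 1, , drop = FALSE])[, 1])
  }
  centers
}

.lloyd <- function(x, centers, max_iter = 100) {
  k <- nrow(centers)
  assign_old <- rep(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- .sqdist(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    # empty clusters: re-seed from the point farthest from its centre
    for (j in which(tabulate(assign_new, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), assign_new)])
      assign_new[far] <- j
      d2[far, ] <- Inf; d2[far, j] <- 0
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
    }
  }
  d2 <- .sqdist(x, centers)
  sse <- sum(d2[cbind(seq_len(nrow(x)), assign_old)])
  list(assignment = assign_old, centers = centers, sse = sse)
}

#' k-means clustering of condition profiles
#'
#' Lloyd's algorithm with Euclidean distance and k-means++ seeding; the best
#' total within-cluster sum of squares over `restarts` seeded starts is kept.
#' Empty clusters arising during iteration are repaired by re-seeding from
#' the point farthest from its current centre. Deterministic given `seed`.
#'
#' @param profiles Numeric matrix (genes x conditions), e.g. from
#'   [condition_profiles()].
#' @param k Number of clusters, between 1 and the number of distinct rows.
#' @param seed Random seed for the restarts.
#' @param restarts Number of seeded starts (default 10).
#' @return List of class `"cluster_model"`: `k`, `assignment` (named integer
#'   vector), `centroids` (k x conditions), `within_scatter` (mean member
#'   distance to centroid, per cluster), `sizes`, `tot_withinss`.
#' @export
kmeans_cluster <- function(profiles, k, seed = 1L, restarts = 10) {
  x <- as.matrix(profiles)
  n_distinct <- nrow(unique(x))
  if (k < 1) stop("k must be >= 1")
  if (k > n_distinct) {
    stop("k = ", k, " exceeds the number of distinct profiles (", n_distinct, ")")
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .lloyd(x, .kmeanspp_init(x, k))
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  assignment <- stats::setNames(best$assignment, rownames(x))
  sizes <- tabulate(best$assignment, k)
  d <- sqrt(.sqdist(x, best$centers))
  within <- vapply(seq_len(k), function(j) {
    mean(d[best$assignment == j, j])
  }, numeric(1))
  structure(list(k = k, assignment = assignment, centroids = best$centers,
                 within_scatter = within, sizes = sizes,
                 tot_withinss = best$sse),
            class = "cluster_model")
}

#' Davies-Bouldin index of a cluster model
#'
#' The original centroid-based formulation:
#' DB = (1/k) * sum_i max_{j != i} (S_i + S_j) / d(c_i, c_j), with S_i the
#' mean Euclidean distance of cluster i's members to its centroid and d the
#' Euclidean distance between centroids. Lower is better. Coincident
#' centroids contribute +Inf, with a warning.
#'
#' @param model A `"cluster_model"` from [kmeans_cluster()] with k >= 2 and
#'   no empty cluster.
#' @return The index (a non-negative scalar).
#' @export
davies_bouldin_index <- function(model) {
  k <- model$k
  if (k < 2) stop("Davies-Bouldin index needs k >= 2")
  if (any(model$sizes == 0)) stop("empty cluster in model")
  S <- model$within_scatter
  cd <- as.matrix(stats::dist(model$centroids))
  ratio <- outer(S, S, "+") / cd
  diag(ratio) <- -Inf
  if (any(cd[upper.tri(cd)] == 0)) {
    warning("coincident centroids: infinite Davies-Bouldin contribution")
  }
  mean(apply(ratio, 1L, max))
}

#' Sweep k and select the cluster number by Davies-Bouldin index
#'
#' Fits one model per k (same seed and restart policy for every k) and picks
#' `best_k` as the argmin of the index (smallest k on ties). A decrease in
#' within-cluster SSE with growing k is expected of the best-of-restarts
#' model; an increase is reported as a restart-budget warning.
#'
#' @param profiles Numeric matrix of profiles.
#' @param k_range Integer vector of candidate k, all >= 2.
#' @param seed Random seed (shared across k).
#' @param restarts Restarts per k (default 10).
#' @return List of class `"k_sweep"`: `table` (data frame k,
#'   davies_bouldin, tot_withinss), `models` (one per k), `best_k`,
#'   `best_model`.
#' @export
select_cluster_number <- function(profiles, k_range = 2:50, seed = 1L,
                                  restarts = 10) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("empty k_range")
  if (any(k_range < 2)) stop("k_range must be >= 2 for the Davies-Bouldin index")
  n_distinct <- nrow(unique(as.matrix(profiles)))
  k_range <- k_range[k_range <= n_distinct]
  if (length(k_range) == 0) stop("no k in range is <= the distinct-profile count")
  models <- lapply(k_range, function(k) {
    kmeans_cluster(profiles, k, seed = seed, restarts = restarts)
  })
  db <- vapply(models, davies_bouldin_index, numeric(1))
  sse <- vapply(models, function(m) m$tot_withinss, numeric(1))
  if (any(diff(sse) > 1e-8)) {
    warning("within-cluster SSE increased along the k sweep; ",
            "consider more restarts")
  }
  best <- which.min(db)
  structure(list(table = data.frame(k = k_range, davies_bouldin = db,
                                    tot_withinss = sse),
                 models = stats::setNames(models, paste0("k", k_range)),
                 best_k = k_range[best], best_model = models[[best]]),
            class = "k_sweep")
}

#' Clusters with a substantial centroid change
#'
#' A cluster is substantial when its centroid has any condition log-ratio
#' strictly above `threshold` or below `-threshold` — i.e. more than 2-fold
#' up or down in at least one organ or strain at the default threshold 1.
#'
#' @param model A `"cluster_model"`.
#' @param threshold Log2-ratio cutoff (default 1.0).
#' @return Integer vector of cluster ids.
#' @export
substantial_clusters <- function(model, threshold = 1.0) {
  which(apply(abs(model$centroids) > threshold, 1L, any))
}

#' Representative genes of a cluster
#'
#' Members ranked by Euclidean distance to the centroid, ascending (ties by
#' gene id); the first `band_size` (top), a centred middle `band_size`, and
#' the last `band_size` (bottom) are returned, de-duplicated, or the whole
#' cluster when it has at most 3 * `band_size` members.
#'
#' @param model A `"cluster_model"`.
#' @param profiles The profile matrix the model was fitted on.
#' @param cluster_id Cluster to summarise.
#' @param band_size Band width (default 80, i.e. up to 240 genes).
#' @return Character vector of gene ids in band order.
#' @export
cluster_representatives <- function(model, profiles, cluster_id, band_size = 80) {
  if (!(cluster_id %in% seq_len(model$k))) stop("unknown cluster id: ", cluster_id)
  if (band_size <= 0) return(character(0))
  members <- names(model$assignment)[model$assignment == cluster_id]
  if (length(members) == 0) stop("cluster ", cluster_id, " is empty")
  x <- as.matrix(profiles)[members, , drop = FALSE]
  d <- sqrt(.sqdist(x, model$centroids[cluster_id, , drop = FALSE]))[, 1]
  ord <- members[order(d, members, method = "radix")]
  m <- length(ord)
  if (m <= 3 * band_size) return(ord)
  mid_start <- floor((m - band_size) / 2) + 1
  unique(c(ord[seq_len(band_size)],
           ord[mid_start:(mid_start + band_size - 1)],
           ord[(m - band_size + 1):m]))
}
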