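# brute-force optimal k-partition SSE by exhaustive assignment enumeration
brute_force_sse <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (i in seq_len(nrow(grid))) {
    a <- as.integer(grid[i, ])
    if (length(unique(a)) < k) next
    sse <- sum(vapply(seq_len(k), function(j) {
      xi <- x[a == j, , drop = FALSE]
      sum(sweep(xi, 2, colMeans(xi))^2)
    }, numeric(1)))
    best <- min(best, sse)
  }
  best
}

test_that("condition profiles stack the four contrasts in fixed order", {
  st <- tiny_study(seed = 2, n_genes = 60)
  ft <- study_fold_tables(st)
  prof <- condition_profiles(ft)
  expect_identical(colnames(prof), c("AB", "SB", "AS", "SS"))
  expect_equal(prof[, "SB"],
               setNames(ft$SB$log2_ratio, ft$SB$gene_id)[rownames(prof)])
  # a gene 2-fold up in both brains and flat in spleens maps to (1,1,0,0)
  fake <- lapply(c(AB = 1, SB = 1, AS = 0, SS = 0), function(lr) {
    data.frame(gene_id = "gX", log2_ratio = lr)
  })
  expect_equal(as.vector(condition_profiles(fake)),
               c(1, 1, 0, 0))
  broken <- ft
  broken$SS <- broken$SS[-1, ]
  expect_error(condition_profiles(broken), "gene universe")
})

test_that("k-means handles degenerate and trivial geometries", {
  x <- matrix(c(0, 10), ncol = 1, dimnames = list(c("a", "b"), "d"))
  m <- kmeans_cluster(x, 2, seed = 1)
  expect_equal(sort(as.vector(m$centroids)), c(0, 10))
  expect_equal(m$tot_withinss, 0)

  x2 <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], NULL))
  m1 <- kmeans_cluster(x2, 1, seed = 1)
  expect_equal(as.vector(m1$centroids), colMeans(x2), tolerance = 1e-12)

  expect_error(kmeans_cluster(x, 3, seed = 1), "distinct")
  expect_identical(kmeans_cluster(x2, 3, seed = 9)$assignment,
                   kmeans_cluster(x2, 3, seed = 9)$assignment)
})

test_that("centroids equal the member means", {
  set.seed(11)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(sprintf("g%02d", 1:20), NULL))
  m <- kmeans_cluster(x, 4, seed = 2)
  for (j in seq_len(m$k)) {
    expect_equal(m$centroids[j, ],
                 colMeans(x[m$assignment == j, , drop = FALSE]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("k-means attains the exhaustive optimum on small instances", {
  set.seed(4)
  hits <- 0L
  runs <- 0L
  for (rep in 1:7) {
    n <- sample(6:9, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(2 * n), n, 2, dimnames = list(paste0("p", 1:n), NULL))
    opt <- brute_force_sse(x, k)
    for (s in 1:3) {
      runs <- runs + 1L
      got <- kmeans_cluster(x, k, seed = s)$tot_withinss
      expect_gte(got, opt - 1e-8)
      if (got <= opt + 1e-8) hits <- hits + 1L
    }
  }
  expect_gte(hits / runs, 0.95)
})

test_that("k-means++ matches stats::kmeans quality on larger instances", {
  set.seed(21)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 6), 50, 2))
  rownames(x) <- sprintf("p%03d", 1:100)
  ours <- kmeans_cluster(x, 2, seed = 1)$tot_withinss
  ref <- stats::kmeans(x, 2, nstart = 10)$tot.withinss
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("the Davies-Bouldin index matches hand-computed values", {
  # two singleton clusters: zero scatter
  x <- matrix(c(0, 5), 2, 1, dimnames = list(c("a", "b"), NULL))
  m <- kmeans_cluster(x, 2, seed = 1)
  expect_equal(davies_bouldin_index(m), 0)

  # {(0,0),(0,1)} vs {(10,0),(10,1)}: S = 0.5 each, centroid distance 10
  x2 <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  rownames(x2) <- letters[1:4]
  m2 <- kmeans_cluster(x2, 2, seed = 1)
  expect_equal(davies_bouldin_index(m2), 0.1, tolerance = 1e-12)

  expect_error(davies_bouldin_index(kmeans_cluster(x2, 1, seed = 1)), "k >= 2")
})

test_that("the Davies-Bouldin index is translation- and scale-invariant", {
  set.seed(31)
  x <- matrix(rnorm(120), 30, 4, dimnames = list(sprintf("g%02d", 1:30), NULL))
  m <- kmeans_cluster(x, 3, seed = 5)
  db <- davies_bouldin_index(m)
  for (f in list(function(z) z + 7, function(z) z * 3.5)) {
    m2 <- kmeans_cluster(f(x), 3, seed = 5)
    # same seed, affine map: identical partition, hence identical index
    expect_identical(m2$assignment, m$assignment)
    expect_equal(davies_bouldin_index(m2), db, tolerance = 1e-9)
  }
})

blob_profiles <- function(seed, n_per = 50, sd = 0.3) {
  set.seed(seed)
  centers <- rbind(c(3, 0, 0, 0), c(0, -3, 0, 0), c(0, 0, 0, 3))
  prof <- centers[rep(1:3, each = n_per), ] +
    matrix(rnorm(3 * n_per * 4, 0, sd), 3 * n_per, 4)
  dimnames(prof) <- list(sprintf("g%03d", seq_len(3 * n_per)),
                         c("AB", "SB", "AS", "SS"))
  prof
}

test_that("the k sweep selects the planted number of blobs", {
  sw <- select_cluster_number(blob_profiles(1), 2:6, seed = 1)
  expect_equal(sw$best_k, 3)
  expect_equal(sw$table$k, 2:6)
  expect_true(all(sw$table$davies_bouldin > 0))
  expect_equal(sw$table$davies_bouldin[sw$table$k == 3],
               min(sw$table$davies_bouldin))
  # length-1 range returns that k
  expect_equal(select_cluster_number(blob_profiles(2), 4, seed = 1)$best_k, 4)
  expect_error(select_cluster_number(blob_profiles(2), integer(0)), "empty")
})

test_that("substantial clusters are flagged by centroid magnitude", {
  model <- structure(list(k = 3,
                          centroids = rbind(c(0.2, -0.3, 0, 0),
                                            c(1.4, 0, 0, 0),
                                            c(0, 0, 0, -1.2)),
                          sizes = c(1L, 1L, 1L)),
                     class = "cluster_model")
  expect_equal(substantial_clusters(model), c(2L, 3L))
  expect_equal(substantial_clusters(model, threshold = 1.5), integer(0))
})

test_that("cluster representatives band by distance to the centroid", {
  prof <- blob_profiles(3, n_per = 300)           # 900 genes, 3 clusters
  m <- kmeans_cluster(prof, 3, seed = 1)
  cid <- unname(m$assignment[["g001"]])
  reps <- cluster_representatives(m, prof, cid, band_size = 80)
  expect_equal(length(reps), 240)
  members <- names(m$assignment)[m$assignment == cid]
  d <- sqrt(colSums((t(prof[members, ]) - m$centroids[cid, ])^2))
  ord <- members[order(d, members)]
  expect_identical(reps[1:80], ord[1:80])                      # top band
  expect_identical(reps[161:240], ord[(length(ord) - 79):length(ord)])
  expect_true(all(reps[81:160] %in% ord[81:(length(ord) - 80)]))

  small <- cluster_representatives(m, prof, cid, band_size = 200)
  expect_setequal(small, members)                 # whole cluster when small
  expect_identical(cluster_representatives(m, prof, cid, band_size = 0),
                   character(0))
  expect_error(cluster_representatives(m, prof, 99), "unknown cluster")
})

test_that("within-cluster SSE does not increase along the sweep", {
  sw <- select_cluster_number(blob_profiles(5), 2:8, seed = 3)
  expect_true(all(diff(sw$table$tot_withinss) <= 1e-8))
})
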