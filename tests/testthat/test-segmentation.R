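# embedding, SNN graph construction, Louvain clustering, markers, regions

test_that("preprocessing standardizes retained features and drops constants", {
  withr::local_seed(2)
  m <- cbind(matrix(rexp(300), ncol = 3), 5)  # last column constant
  fm <- toy_feature_matrix(m)
  expect_warning(emb <- preprocess_for_clustering(fm, pca_dims = 3),
                 "zero-variance")
  expect_equal(ncol(emb), 2)  # min(3, retained features - 1)

  # the standardized matrix has mean 0, variance 1 pre-clipping
  x <- scale(log1p(m[, 1:3]))
  expect_equal(unname(colMeans(x)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(x, 2, var)), rep(1, 3), tolerance = 1e-12)

  # all-zero pixels sit at the origin pre-standardization
  expect_equal(log1p(0), 0)
  expect_error(
    suppressWarnings(
      preprocess_for_clustering(toy_feature_matrix(matrix(1, 5, 2)))),
    "informative")
})

test_that("SNN graph matches a brute-force neighbor-set oracle", {
  # symmetric configurations give symmetric graphs: 3 equidistant points
  # form a complete triangle; on a square with k = 3 every pair (adjacent or
  # diagonal) shares exactly two neighbors, so all six weights are equal
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  g <- build_snn_graph(pts, k = 2, prune = 0)
  expect_equal(igraph::ecount(g), 3)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  gf <- build_snn_graph(sq, k = 3, prune = 0)
  expect_equal(igraph::ecount(gf), 6)
  expect_equal(unique(igraph::E(gf)$weight), 0.5)

  # two well-separated triads, k = 2: no inter-triad edges after pruning
  far <- rbind(pts, pts + 100)
  g2 <- build_snn_graph(far, k = 2, prune = 1 / 15)
  cross <- igraph::crossing(igraph::make_clusters(
    g2, membership = rep(1:2, each = 3)), g2)
  expect_false(any(cross))

  # brute-force Jaccard check on random points
  withr::local_seed(4)
  emb <- matrix(rnorm(40), ncol = 2)
  k <- 5
  g3 <- build_snn_graph(emb, k = k, prune = 0)
  d <- as.matrix(dist(emb))
  nbr <- lapply(seq_len(nrow(emb)), function(i) order(d[i, ])[seq_len(k)])
  w <- igraph::as_adjacency_matrix(g3, attr = "weight", sparse = FALSE)
  for (i in 1:10) for (j in (i + 1):11) {
    inter <- length(intersect(nbr[[i]], nbr[[j]]))
    expect_equal(w[i, j], inter / (2 * k - inter), tolerance = 1e-12)
  }

  # degenerate prune threshold empties the edge set
  g4 <- build_snn_graph(emb, k = 5, prune = 1.01)
  expect_equal(igraph::ecount(g4), 0)

  expect_error(build_snn_graph(emb, k = 0), "positive")
  expect_error(build_snn_graph(emb, k = 100), "smaller")
})

test_that("two well-separated blobs give two clusters at ARI 1, deterministically", {
  withr::local_seed(10)
  emb <- rbind(matrix(rnorm(200), ncol = 2),
               matrix(rnorm(200, mean = 30), ncol = 2))
  truth <- rep(1:2, each = 100)
  g <- build_snn_graph(emb, k = 40, prune = 1 / 15)
  seg1 <- cluster_pixels(g, resolution = 0.9, seed = 5)
  expect_equal(length(seg1$cluster_sizes), 2)
  expect_equal(adjusted_rand_index(seg1$labels, truth), 1)
  # labels are contiguous from 1, by decreasing size; pixels conserved
  expect_setequal(unique(seg1$labels), seq_along(seg1$cluster_sizes))
  expect_true(all(diff(seg1$cluster_sizes) <= 0))
  expect_equal(sum(seg1$cluster_sizes), nrow(emb))

  seg2 <- cluster_pixels(g, resolution = 0.9, seed = 5)
  expect_identical(seg1$labels, seg2$labels)
})

test_that("cluster count grows with resolution (statistical monotonicity)", {
  withr::local_seed(31)
  emb <- matrix(rnorm(600, sd = 2), ncol = 2) +
    cbind(rep(c(0, 8, 16), each = 100), rep(c(0, 8, 0), each = 100))
  g <- build_snn_graph(emb, k = 15, prune = 1 / 15)
  n_low <- n_high <- numeric(10)
  for (i in 1:10) {
    n_low[i] <- length(cluster_pixels(g, resolution = 0.5,
                                      seed = i)$cluster_sizes)
    n_high[i] <- length(cluster_pixels(g, resolution = 1.5,
                                       seed = i)$cluster_sizes)
  }
  expect_gte(mean(n_high), mean(n_low))
})

test_that("top_cluster_lipids ranks by median-scaled cluster means", {
  withr::local_seed(6)
  m <- matrix(rexp(300, rate = 1 / 10), ncol = 6)
  labels <- rep(1:2, each = 25)
  m[labels == 1, 3] <- m[labels == 1, 3] * 10  # dominance in cluster 1
  fm <- toy_feature_matrix(m)
  top <- top_cluster_lipids(fm, labels, n = 5)
  expect_equal(top$mz[top$cluster == 1 & top$rank == 1], fm$mz[3])

  # brute-force oracle for the full ranking
  med <- apply(m, 2, function(v) median(v[v > 0]))
  scaled <- sweep(m, 2, med, "/")
  for (cl in 1:2) {
    want <- order(colMeans(scaled[labels == cl, ]),
                  decreasing = TRUE)[1:5]
    got <- top$mz[top$cluster == cl]
    expect_equal(got, fm$mz[want])
  }

  # single cluster: ranking equals the global ranking
  top1 <- top_cluster_lipids(fm, rep(1L, 50), n = 6)
  expect_equal(top1$mz, fm$mz[order(colMeans(scaled), decreasing = TRUE)])

  # n beyond the feature count truncates with a warning
  expect_warning(top_cluster_lipids(fm, labels, n = 10), "truncated")
})

test_that("assign_regions propagates cluster regions and defaults to unassigned", {
  pixels <- tibble::tibble(x = seq_len(100), y = 1L,
                           acquisition_index = seq_len(100))
  seg <- structure(list(
    sample_id = "s", labels = rep(1:2, each = 50),
    cluster_sizes = c(50L, 50L), parameters = list(), pixels = pixels),
    class = "msi_segmentation")

  out <- assign_regions(seg, c(`1` = "airway_epithelium"))
  expect_true(all(out$region[out$cluster == 1] == "airway_epithelium"))
  expect_true(all(out$region[out$cluster != 1] == "unassigned"))

  expect_error(assign_regions(seg, c(`99` = "airway_lumen")), "non-existent")
  expect_error(assign_regions(seg, c(`1` = "not_a_region")), "unknown region")

  # retaining only the two epithelial regions leaves exactly those in play
  map2 <- tibble::tibble(cluster = 1:2,
                         region = c("airway_epithelium",
                                    "alveolar_epithelium"))
  out2 <- assign_regions(seg, map2)
  expect_setequal(unique(out2$region),
                  c("airway_epithelium", "alveolar_epithelium"))
})

test_that("planted regions are recovered on a small synthetic section", {
  gen <- small_dataset()
  bins <- align_features(gen$samples)
  mats <- build_feature_matrix(gen$samples, bins)
  ann <- match_features(bins, gen$truth$library, 0.010, mode = "negative")
  fm <- select_features(mats[[1]], unique(ann$feature_mz))
  fm$annotation <- ann
  lo <- suppressMessages(sparse_loess_normalize(list(fm), 0.10))
  seg <- segment_sample(lo$matrices[[1]], seed = 42)
  ev <- evaluate_segmentation(seg, gen$truth$regions)
  expect_gte(ev$ari, 0.9)

  # determinism of the full chain
  seg2 <- segment_sample(lo$matrices[[1]], seed = 42)
  expect_identical(seg$labels, seg2$labels)
})
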