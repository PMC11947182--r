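# Unsupervised pixel segmentation: log/scale/PCA embedding, shared-nearest-
# neighbor graph with Jaccard weights, and Louvain community detection with a
# resolution parameter -- the graph-clustering recipe popularised by
# single-cell toolkits, applied per tissue section.

#' Region vocabulary for cluster-to-region maps
#' @export
msi_region_levels <- c("airway_epithelium", "airway_lumen",
                       "basement_membrane", "distal_airway_epithelium",
                       "alveolar_epithelium", "off_tissue", "unassigned")

#' Embed pixels for clustering
#'
#' `log(1 + x)` transform, per-feature standardization to mean 0 / variance 1
#' (zero-variance features dropped with a warning, standardized values clipped
#' at `+-clip`), then projection onto the first
#' `min(pca_dims, features - 1)` principal components.
#'
#' @param fm A normalized [feature_matrix()].
#' @param pca_dims Number of principal components, default 10.
#' @param clip Clipping bound for standardized values, default 10.
#' @return Numeric matrix (pixels x components) with the pixel table in the
#'   `"pixels"` attribute.
#' @export
preprocess_for_clustering <- function(fm, pca_dims = 10, clip = 10) {
  x <- log1p(fm$values)
  vars <- apply(x, 2, stats::var)
  keep <- which(vars > 0)
  if (length(keep) < ncol(x)) {
    rlang::warn(sprintf("dropping %d zero-variance feature(s) before PCA",
                        ncol(x) - length(keep)))
  }
  if (length(keep) < 2L) {
    rlang::abort("need at least 2 informative (non-constant) features")
  }
  x <- scale(x[, keep, drop = FALSE])
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  d <- min(pca_dims, ncol(x) - 1L)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = d)
  emb <- pc$x[, seq_len(d), drop = FALSE]
  attr(emb, "pixels") <- fm$pixels
  emb
}

#' Build a shared-nearest-neighbor graph over pixels
#'
#' Finds each pixel's `k` Euclidean nearest neighbors (self included), weights
#' the edge between two pixels by the Jaccard overlap of their neighbor sets,
#' and removes edges below `prune`.
#'
#' @param embedding Numeric matrix (pixels x dimensions).
#' @param k Neighborhood size, default 20.
#' @param prune Jaccard pruning threshold, default 1/15.
#' @return An undirected weighted [igraph::graph] with one vertex per pixel.
#' @export
build_snn_graph <- function(embedding, k = 20, prune = 1 / 15) {
  n <- nrow(embedding)
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    rlang::abort("`k` must be a positive integer")
  }
  if (k >= n) rlang::abort("`k` must be smaller than the number of pixels")
  nn <- RANN::nn2(embedding, k = k)$nn.idx
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), times = k),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  counts <- Matrix::tcrossprod(adj)
  counts <- as(counts, "generalMatrix")
  counts <- as(counts, "CsparseMatrix")
  # Jaccard: |A intersect B| / |A union B| with |A| = |B| = k
  counts@x <- counts@x / (2 * k - counts@x)
  counts@x[counts@x < prune] <- 0
  counts <- Matrix::drop0(counts)
  Matrix::diag(counts) <- 0
  counts <- Matrix::drop0(counts)
  igraph::graph_from_adjacency_matrix(counts, mode = "undirected",
                                      weighted = TRUE)
}

#' Cluster pixels by Louvain community detection
#'
#' Runs modularity-based community detection with a resolution parameter on
#' the SNN graph and relabels communities as contiguous integers from 1 in
#' decreasing size order. Isolated pixels form singleton clusters and are
#' flagged in the `"singletons"` attribute for review.
#'
#' @param graph Weighted SNN graph from [build_snn_graph()].
#' @param resolution Modularity resolution, default 0.9.
#' @param seed RNG seed making the partition reproducible.
#' @param pixels Optional pixel table carried into the result.
#' @param sample_id Optional sample identifier.
#' @param parameters Optional list of upstream parameters recorded verbatim.
#' @return An object of class `msi_segmentation` with fields `sample_id`,
#'   `labels`, `cluster_sizes`, `parameters`, `pixels`.
#' @export
cluster_pixels <- function(graph, resolution = 0.9, seed = 42L,
                           pixels = NULL, sample_id = NA_character_,
                           parameters = list()) {
  if (igraph::vcount(graph) == 0L) rlang::abort("graph has no vertices")
  assert_scalar_number(resolution, "resolution", lower = 0,
                       strict_lower = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  # contiguous ids from 1, largest community first (ties by original id)
  new_id <- rank(-as.integer(sizes), ties.method = "first")
  names(new_id) <- names(sizes)
  labels <- as.integer(new_id[as.character(memb)])
  cluster_sizes <- as.integer(table(labels))
  params <- utils::modifyList(parameters,
                              list(resolution = resolution, seed = seed))
  if (is.null(pixels)) {
    pixels <- tibble::tibble(x = NA_integer_, y = NA_integer_,
                             acquisition_index = seq_along(labels))
  }
  out <- structure(
    list(sample_id = sample_id, labels = labels,
         cluster_sizes = cluster_sizes, parameters = params,
         pixels = tibble::as_tibble(pixels)),
    class = "msi_segmentation")
  attr(out, "singletons") <- which(labels %in% which(cluster_sizes == 1L))
  out
}

#' Segment one sample end to end
#'
#' Convenience chain: [preprocess_for_clustering()] ->
#' [build_snn_graph()] -> [cluster_pixels()].
#'
#' @inheritParams preprocess_for_clustering
#' @inheritParams build_snn_graph
#' @inheritParams cluster_pixels
#' @return An `msi_segmentation`.
#' @export
segment_sample <- function(fm, k = 20, prune = 1 / 15, pca_dims = 10,
                           resolution = 0.9, seed = 42L, clip = 10) {
  emb <- preprocess_for_clustering(fm, pca_dims = pca_dims, clip = clip)
  graph <- build_snn_graph(emb, k = k, prune = prune)
  cluster_pixels(graph, resolution = resolution, seed = seed,
                 pixels = fm$pixels, sample_id = fm$sample_id,
                 parameters = list(k = k, prune = prune,
                                   pca_dims = pca_dims, clip = clip))
}

#' @export
print.msi_segmentation <- function(x, ...) {
  cat(sprintf("<msi_segmentation> %s | %d pixels -> %d clusters (res %.2g)\n",
              x$sample_id, length(x$labels), length(x$cluster_sizes),
              x$parameters$resolution %||% NA))
  invisible(x)
}

#' @method tidy msi_segmentation
#' @export
tidy.msi_segmentation <- function(x, ...) {
  out <- x$pixels
  out$cluster <- x$labels
  out$sample_id <- x$sample_id
  out[, c("sample_id", "x", "y", "acquisition_index", "cluster")]
}

#' @method glance msi_segmentation
#' @export
glance.msi_segmentation <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id, n_pixels = length(x$labels),
                 n_clusters = length(x$cluster_sizes),
                 n_singletons = sum(x$cluster_sizes == 1L),
                 resolution = x$parameters$resolution %||% NA_real_,
                 seed = x$parameters$seed %||% NA_integer_)
}

#' Rank the lipids that define each cluster
#'
#' Intensities are scaled by each lipid's global median over its non-zero
#' pixels (all-zero lipids are excluded); within each cluster, lipids are
#' ranked by their mean scaled intensity and the top `n` reported. The
#' `"combined"` attribute lists the union of top lipids with duplicates across
#' clusters included once, in first-appearance order, for heatmap export; the
#' global mean per-pixel `log2(1 + x)` intensity accompanies every lipid.
#'
#' @param fm A normalized [feature_matrix()].
#' @param labels An `msi_segmentation` or an integer vector of cluster labels.
#' @param n Number of top lipids per cluster, default 5 (truncated with a
#'   warning if it exceeds the feature count).
#' @return Tibble: `cluster`, `rank`, `mz`, `lipid`, `mean_scaled_intensity`,
#'   `mean_log2_intensity`.
#' @export
top_cluster_lipids <- function(fm, labels, n = 5) {
  if (inherits(labels, "msi_segmentation")) labels <- labels$labels
  if (length(labels) != nrow(fm$values)) {
    rlang::abort("labels must cover every pixel of the matrix")
  }
  med <- apply(fm$values, 2, function(v) {
    nz <- v[v > 0]
    if (length(nz) == 0L) NA_real_ else stats::median(nz)
  })
  keep <- which(!is.na(med))
  if (length(keep) == 0L) rlang::abort("all features are all-zero")
  if (n > length(keep)) {
    rlang::warn(sprintf("n truncated from %d to the %d usable feature(s)",
                        n, length(keep)))
    n <- length(keep)
  }
  scaled <- sweep(fm$values[, keep, drop = FALSE], 2, med[keep], "/")
  cluster_means <- rowsum(scaled, group = labels) /
    as.vector(table(labels))
  mean_log2 <- colMeans(log2(1 + fm$values[, keep, drop = FALSE]))

  lipid_names <- lipid_labels_for(fm)[keep]
  rows <- purrr::map(seq_len(nrow(cluster_means)), function(ci) {
    ord <- order(cluster_means[ci, ], decreasing = TRUE)[seq_len(n)]
    tibble::tibble(
      cluster = as.integer(rownames(cluster_means)[ci]),
      rank = seq_len(n),
      mz = fm$mz[keep][ord],
      lipid = lipid_names[ord],
      mean_scaled_intensity = unname(cluster_means[ci, ord]),
      mean_log2_intensity = unname(mean_log2[ord])
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "combined") <- unique(out$lipid)
  out
}

# display labels: annotation name when available, else the formatted m/z
lipid_labels_for <- function(fm) {
  labels <- format_mz(fm$mz)
  ann <- fm$annotation
  if (!is.null(ann) && nrow(ann) > 0L) {
    first <- ann[!duplicated(ann$feature_mz), ]
    idx <- match(fm$mz, first$feature_mz)
    labels[!is.na(idx)] <- first$lipid_name[idx[!is.na(idx)]]
  }
  labels
}

#' Assign segmentation clusters to morphological regions
#'
#' Pixels inherit the region of their cluster per the supplied map (the
#' analogue of matching clusters to H&E-validated serial sections). Unmapped
#' clusters become `"unassigned"`; `"unassigned"` and `"off_tissue"` are
#' excluded from group statistics downstream.
#'
#' @param seg An `msi_segmentation`.
#' @param region_map Data frame with columns `cluster`, `region`, or a named
#'   character vector (names = cluster ids). Regions must come from
#'   [msi_region_levels].
#' @return Tibble: `sample_id`, `x`, `y`, `acquisition_index`, `cluster`,
#'   `region`.
#' @export
assign_regions <- function(seg, region_map) {
  if (is.character(region_map)) {
    region_map <- tibble::tibble(cluster = as.integer(names(region_map)),
                                 region = unname(region_map))
  }
  region_map <- tibble::as_tibble(region_map)
  if (!all(c("cluster", "region") %in% names(region_map))) {
    rlang::abort("region_map needs columns 'cluster' and 'region'")
  }
  known <- sort(unique(seg$labels))
  bad <- setdiff(region_map$cluster, known)
  if (length(bad)) {
    rlang::abort(sprintf("region_map names non-existent cluster(s): %s",
                         paste(bad, collapse = ", ")))
  }
  bad_region <- setdiff(region_map$region, msi_region_levels)
  if (length(bad_region)) {
    rlang::abort(sprintf(
      "unknown region label(s): %s (see msi_region_levels)",
      paste(bad_region, collapse = ", ")))
  }
  lookup <- setNames(region_map$region, region_map$cluster)
  region <- unname(lookup[as.character(seg$labels)])
  region[is.na(region)] <- "unassigned"
  out <- tidy.msi_segmentation(seg)
  out$region <- region
  out
}
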