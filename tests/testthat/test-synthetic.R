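# generator determinism, configured statistics, ARI utility

test_that("the generator is reproducible from its seed", {
  cfg <- synthetic_config(width = 20, height = 20, n_features = 30,
                          groups = "control", sexes = "F", n_per_cell = 2,
                          seed = 55)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$truth$region_means, g2$truth$region_means)
  expect_identical(g1$samples[[1]]$spectra, g2$samples[[1]]$spectra)
  expect_identical(g1$samples[[2]]$spectra, g2$samples[[2]]$spectra)

  # pixel count is conserved: width x height per sample
  expect_equal(nrow(g1$samples[[1]]$spectra), 400)
  expect_equal(sort(unique(g1$truth$regions$region)),
               sort(c("off_tissue", "airway_lumen", "airway_epithelium",
                      "alveolar_epithelium")))
})

test_that("noiseless linear drift reproduces the configured TIC slope", {
  cfg <- synthetic_config(width = 30, height = 30, n_features = 20,
                          groups = "control", sexes = "F", n_per_cell = 1,
                          sigma = 0, dropout = 0, region_profile_sdlog = 0,
                          n_alveolar_patches = 1,
                          drift = list(type = "linear", amplitude = 0.5,
                                       feature_jitter = 0),
                          seed = 9)
  gen <- generate_dataset(cfg)
  s <- gen$samples[[1]]
  # TIC over alveolar pixels only: one region, so the trend is pure drift
  alv <- gen$truth$regions$acquisition_index[
    gen$truth$regions$region == "alveolar_epithelium"]
  tic <- vapply(s$spectra$intensity, sum, numeric(1))
  idx <- s$spectra$acquisition_index
  keep <- idx %in% alv
  fit <- lm(tic[keep] ~ idx[keep])
  base <- sum(gen$truth$region_means$true_mean[
    gen$truth$region_means$region == "alveolar_epithelium"])
  slope_expected <- base * 0.5 / 900  # d/di of base * (1 + 0.5 i / n)
  expect_equal(unname(coef(fit)[2]), slope_expected, tolerance = 0.01)
})

test_that("empirical dropout rate sits inside the binomial 99% CI", {
  cfg <- synthetic_config(width = 24, height = 24, n_features = 30,
                          groups = "control", sexes = "F", n_per_cell = 1,
                          dropout = 0.25, off_tissue_scale = 0, seed = 77)
  gen <- generate_dataset(cfg)
  truth <- gen$truth$regions
  tissue_idx <- truth$acquisition_index[truth$region != "off_tissue"]
  sp <- gen$samples[[1]]$spectra
  # count zeros among lipid features on tissue pixels (always non-zero
  # pre-dropout there)
  lib_mz <- gen$truth$library$expected_mz
  n_present <- sum(vapply(which(sp$acquisition_index %in% tissue_idx),
                          function(i) sum(sp$mz[[i]] %in% lib_mz),
                          numeric(1)))
  n_total <- length(tissue_idx) * length(lib_mz)
  p_hat <- 1 - n_present / n_total
  half <- qnorm(0.995) * sqrt(0.25 * 0.75 / n_total)
  expect_gt(p_hat, 0.25 - half)
  expect_lt(p_hat, 0.25 + half)
})

test_that("planted region means are matched by the empirical means", {
  cfg <- synthetic_config(width = 30, height = 30, n_features = 20,
                          groups = "control", sexes = "F", n_per_cell = 1,
                          sigma = 0.2, dropout = 0, n_alveolar_patches = 1,
                          drift = list(type = "linear", amplitude = 0),
                          seed = 12)
  gen <- generate_dataset(cfg)
  truth <- gen$truth
  sp <- gen$samples[[1]]$spectra
  feats <- sort(unique(unlist(sp$mz)))
  vals <- matrix(0, nrow(sp), length(feats))
  for (i in seq_len(nrow(sp))) {
    vals[i, match(sp$mz[[i]], feats)] <- sp$intensity[[i]]
  }
  region_of <- truth$regions$region[match(sp$acquisition_index,
                                          truth$regions$acquisition_index)]
  alv <- region_of == "alveolar_epithelium"
  tm <- truth$region_means[truth$region_means$region == "alveolar_epithelium", ]
  j <- match(feats, truth$library$expected_mz)
  ok <- !is.na(j)
  expected <- tm$true_mean[match(truth$library$lipid_name[j[ok]],
                                 tm$lipid_name)]
  observed <- colMeans(vals[alv, ok]) / exp(0.2^2 / 2)  # lognormal mean bias
  expect_equal(observed, expected, tolerance = 0.1)
})

test_that("adjusted Rand index: identity, label permutation, chance level", {
  a <- rep(1:3, times = c(30, 40, 30))
  expect_equal(adjusted_rand_index(a, a), 1)
  relabeled <- c(7, 2, 5)[a]
  expect_equal(adjusted_rand_index(a, relabeled), 1)

  withr::local_seed(14)
  big <- sample(1:5, 1e4, replace = TRUE)
  rand <- sample(1:5, 1e4, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(big, rand)), 0.02)

  # cross-check against an independent implementation
  expect_equal(adjusted_rand_index(a, c(rep(1, 35), rep(2, 65))),
               mclust::adjustedRandIndex(a, c(rep(1, 35), rep(2, 65))),
               tolerance = 1e-12)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("evaluate_segmentation validates the pixel set and maps majorities", {
  truth <- tibble::tibble(x = rep(1:10, 2), y = rep(1:2, each = 10),
                          acquisition_index = 1:20,
                          region = rep(c("airway_epithelium",
                                         "alveolar_epithelium"), each = 10))
  seg <- structure(list(
    sample_id = "s", labels = rep(c(1L, 2L, 3L), c(10, 5, 5)),
    cluster_sizes = c(10L, 5L, 5L), parameters = list(),
    pixels = truth[, c("x", "y", "acquisition_index")]),
    class = "msi_segmentation")
  ev <- evaluate_segmentation(seg, truth)
  # clusters 2 and 3 both map onto alveolar: mapped ARI is exact
  expect_equal(ev$ari, 1)
  expect_lt(ev$ari_raw, 1)
  expect_equal(ev$recall$recall, c(1, 1))

  bad <- truth[1:15, ]
  expect_error(evaluate_segmentation(seg, bad), "pixel set")
})

test_that("geometry validation rejects overlapping regions", {
  expect_error(synthetic_config(r_lumen = 20, r_epithelium = 15),
               "overlapping")
  expect_error(synthetic_config(width = 40, height = 40, r_epithelium = 19),
               "overlapping")
  expect_error(synthetic_config(dropout = 1.2), "\\[0, 1\\]")
})
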