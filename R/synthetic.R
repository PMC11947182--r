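# Ground-truthed synthetic MSI lipidomics datasets.
#
# The generator emulates the structure of a multi-replicate lung imaging
# study: a raster grid with an off-tissue margin, an airway (lumen plus
# epithelial ring, optionally a basement-membrane ring) embedded in an
# alveolar field; per-region lipid profiles with region-marker lipids;
# multiplicative intensity drift along the acquisition order; per-sample
# global scale differences; lognormal pixel noise; per-feature zero
# inflation; and planted group effects on chosen lipids. Every sample comes
# with truth tables so each pipeline stage can be scored.

#' Configuration for the synthetic MSI generator
#'
#' Defaults describe the benchmark section: a 120 x 120 raster, 100 lipid
#' features, three tissue regions (airway lumen, airway epithelium, alveolar
#' field) plus an off-tissue margin, linear multiplicative drift of amplitude
#' 0.5, a 2x inter-sample scale spread, lognormal noise (sigma 0.3), 20%
#' zero inflation, and a planted decrease of 1 log2 unit on 10 unsaturated
#' PE/PG lipids in the alveolar region of the exposed group.
#'
#' @param width,height Raster size in pixels.
#' @param n_features Number of lipid features.
#' @param margin Off-tissue border width in pixels; default 10% of the
#'   smaller grid side.
#' @param r_lumen,r_epithelium,r_basement Airway radii (pixels); defaults
#'   scale with the grid. `r_basement` only applies when `include_basement`.
#' @param include_basement Add a basement-membrane ring?
#' @param n_markers_per_region Dedicated marker lipids per tissue region.
#' @param marker_fold Fold elevation of a marker in its region.
#' @param off_tissue_scale Intensity of sporadic background off tissue, as a
#'   fraction of the base mean. Most lipid channels are clean zeros off
#'   tissue (sub-threshold signal never survives peak picking); a subset of
#'   channels carries mass-specific chemical interference.
#' @param off_tissue_presence Probability that an interference-prone lipid
#'   channel registers in an off-tissue pixel; replaces the ordinary dropout
#'   there.
#' @param off_tissue_noise_frac Fraction of lipid features subject to
#'   off-tissue chemical interference.
#' @param n_matrix_peaks Matrix-derived background features: strong off
#'   tissue, present everywhere, and absent from the annotation library.
#' @param matrix_tissue_scale On-tissue level of matrix features relative to
#'   their base mean.
#' @param matrix_scale_spread Ratio of the largest to smallest per-sample
#'   matrix deposition factor (log-spaced across samples in the reverse of
#'   the tissue-scale order, so the two factors are decorrelated) -- matrix
#'   deposition varies independently of tissue lipid yield, which is why
#'   whole-spectrum TIC normalization cannot equalize annotated signal
#'   across samples.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of per-feature
#'   base means.
#' @param region_profile_sdlog Spread (log scale) of the per-region, per-lipid
#'   profile factors that differentiate tissue regions beyond their dedicated
#'   markers; regional lipidomes differ broadly, not only in a handful of
#'   marker species. Drawn once per dataset, shared by all samples.
#' @param n_alveolar_patches,alveolar_texture_sdlog Within-alveolar texture:
#'   each sample's alveolar field is divided into Voronoi patches whose lipid
#'   profiles vary with the given log spread, emulating parenchymal
#'   heterogeneity (airspaces, septa, vessels). Real sections segment into
#'   more clusters than regions; mapping clusters to regions is many-to-one.
#'   Set `n_alveolar_patches = 1` for a homogeneous field.
#' @param sigma Lognormal pixel noise sigma (0 = noiseless).
#' @param dropout Zero-inflation probability, scalar or per feature.
#' @param drift List: `type` (`"linear"` or `"sinusoidal"`), `amplitude`, and
#'   `feature_jitter`. Linear drift multiplies a feature's intensities by
#'   `1 + a_f * i / n` at acquisition index `i` of `n`, where the per-feature
#'   amplitude `a_f` is `amplitude` scaled by a factor drawn uniformly in
#'   `[1 - feature_jitter, 1 + feature_jitter]` -- detector drift is
#'   mass-dependent, which is why pixel-sum (TIC) normalization corrects
#'   drift only partially. `matrix_factor` (default -0.5) scales the drift of
#'   matrix-derived background ions, which decay rather than grow with
#'   acquisition time.
#' @param sample_scale_spread Ratio of the largest to smallest per-sample
#'   global scale factor. Factors are log-spaced over the replicates and the
#'   same set recurs in every group x sex cell, so overall sensitivity is
#'   orthogonal to treatment (the counterpart of randomized acquisition
#'   order).
#' @param groups,sexes,n_per_cell Study design; one sample per
#'   group x sex x replicate.
#' @param effects Tibble (`lipid`, `region`, `group`, `log2_effect`, optional
#'   `sex`) of planted effects; `NULL` installs the default template of -1.0
#'   on 10 unsaturated PE/PG lipids in the alveolar region of the second
#'   group. `NA` sex applies to both sexes.
#' @param ionization_mode,scan_range Acquisition descriptors.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(width = 120, height = 120, n_features = 100,
                             margin = NULL, r_lumen = NULL,
                             r_epithelium = NULL, r_basement = NULL,
                             include_basement = FALSE,
                             n_markers_per_region = 12, marker_fold = 6,
                             off_tissue_scale = 0.02, off_tissue_presence = 0.3,
                             off_tissue_noise_frac = 0.15,
                             n_matrix_peaks = 8,
                             matrix_tissue_scale = 12, matrix_scale_spread = 2,
                             baseline_meanlog = log(50), baseline_sdlog = 0.6,
                             region_profile_sdlog = 0.8,
                             n_alveolar_patches = 4,
                             alveolar_texture_sdlog = 0.3,
                             sigma = 0.3, dropout = 0.1,
                             drift = list(type = "linear", amplitude = 0.5,
                                          feature_jitter = 0.5),
                             sample_scale_spread = 2,
                             groups = c("control", "HDM_O3"),
                             sexes = c("F", "M"), n_per_cell = 3,
                             effects = NULL,
                             ionization_mode = "negative",
                             scan_range = c(300, 900), seed = 1L) {
  m <- min(width, height)
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    n_features = as.integer(n_features),
    margin = as.integer(margin %||% round(0.10 * m)),
    r_lumen = r_lumen %||% (0.08 * m),
    r_epithelium = r_epithelium %||% (0.14 * m),
    r_basement = r_basement %||% (0.17 * m),
    include_basement = isTRUE(include_basement),
    n_markers_per_region = as.integer(n_markers_per_region),
    marker_fold = marker_fold, off_tissue_scale = off_tissue_scale,
    off_tissue_presence = off_tissue_presence,
    off_tissue_noise_frac = off_tissue_noise_frac,
    n_matrix_peaks = as.integer(n_matrix_peaks),
    matrix_tissue_scale = matrix_tissue_scale,
    matrix_scale_spread = matrix_scale_spread,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    region_profile_sdlog = region_profile_sdlog,
    n_alveolar_patches = as.integer(n_alveolar_patches),
    alveolar_texture_sdlog = alveolar_texture_sdlog,
    sigma = sigma, dropout = dropout,
    drift = utils::modifyList(list(feature_jitter = 0.5,
                                   matrix_factor = -0.5), drift),
    sample_scale_spread = sample_scale_spread,
    groups = groups, sexes = sexes, n_per_cell = as.integer(n_per_cell),
    effects = effects, ionization_mode = normalize_mode(ionization_mode),
    scan_range = scan_range, seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$width < 10 || cfg$height < 10) {
    rlang::abort("grid must be at least 10 x 10 pixels")
  }
  dropout <- cfg$dropout
  if (!is.null(cfg$off_tissue_presence) &&
      (cfg$off_tissue_presence < 0 || cfg$off_tissue_presence > 1)) {
    rlang::abort("off_tissue_presence must be in [0, 1]")
  }
  if (any(dropout < 0 | dropout > 1)) {
    rlang::abort("dropout probabilities must be in [0, 1]")
  }
  if (cfg$sigma < 0) rlang::abort("sigma must be >= 0")
  if (!cfg$drift$type %in% c("linear", "sinusoidal")) {
    rlang::abort("drift$type must be 'linear' or 'sinusoidal'")
  }
  r_outer <- if (cfg$include_basement) cfg$r_basement else cfg$r_epithelium
  if (cfg$r_lumen >= cfg$r_epithelium ||
      (cfg$include_basement && cfg$r_epithelium >= cfg$r_basement)) {
    rlang::abort("airway radii must be strictly increasing (overlapping region geometry)")
  }
  tissue_w <- cfg$width - 2 * cfg$margin
  if (2 * r_outer >= tissue_w) {
    rlang::abort("airway does not fit inside the tissue area (overlapping region geometry)")
  }
  invisible(cfg)
}

# region label per pixel; the airway sits at the centre of the tissue field,
# so spatial structure is symmetric along the acquisition order and the
# TIC-vs-index drift diagnostic is not tilted by anatomy
synthetic_geometry <- function(cfg) {
  grid <- expand.grid(x = seq_len(cfg$width), y = seq_len(cfg$height))
  cx <- cfg$margin + 0.5 * (cfg$width - 2 * cfg$margin)
  cy <- cfg$margin + 0.5 * (cfg$height - 2 * cfg$margin)
  r <- sqrt((grid$x - cx)^2 + (grid$y - cy)^2)
  off <- grid$x <= cfg$margin | grid$x > cfg$width - cfg$margin |
    grid$y <= cfg$margin | grid$y > cfg$height - cfg$margin
  region <- rep("alveolar_epithelium", nrow(grid))
  region[r <= cfg$r_basement & cfg$include_basement] <- "basement_membrane"
  region[r <= cfg$r_epithelium] <- "airway_epithelium"
  region[r <= cfg$r_lumen] <- "airway_lumen"
  region[off] <- "off_tissue"
  tibble::tibble(x = grid$x, y = grid$y,
                 acquisition_index = (grid$y - 1L) * cfg$width + grid$x,
                 region = region)
}

# deterministic synthetic lipid panel: enough unsaturated PE/PG species to
# carry the default effect template, saturated PC and SM blocks mirroring
# airway/alveolar marker chemistry, and a remainder drawn across classes
synthetic_features <- function(cfg) {
  n <- cfg$n_features
  plan <- c(rep("PE", 15), rep("PG", 15), rep("SM", 10), rep("PC", 15),
            rep("FA", 10))
  extra_classes <- c("PI", "PS", "PA", "LPC", "LPE", "Cer", "TG", "CE")
  if (n > length(plan)) {
    plan <- c(plan, rep(extra_classes, length.out = n - length(plan)))
  } else {
    plan <- plan[seq_len(n)]
  }
  carbons <- integer(n); dbs <- integer(n)
  for (i in seq_len(n)) {
    cls <- plan[i]
    carbons[i] <- switch(cls, FA = sample(16:22, 1), LPC = , LPE = sample(16:22, 1),
                         SM = sample(34:44, 1), Cer = sample(34:42, 1),
                         TG = sample(48:56, 1), sample(30:44, 1))
    dbs[i] <- switch(cls,
                     PE = sample(2:6, 1), PG = sample(1:6, 1),
                     SM = sample(0:2, 1), PC = sample(0:1, 1),
                     FA = sample(3:6, 1), sample(0:4, 1))
  }
  name <- paste0(plan, " ", carbons, ":", dbs)
  # uniqueness of (name, mz): nudge duplicates to unused carbon counts
  while (any(duplicated(name))) {
    d <- which(duplicated(name))
    carbons[d] <- carbons[d] + 2L
    name <- paste0(plan, " ", carbons, ":", dbs)
  }
  mz <- sort(cfg$scan_range[1] + 300 +
               cumsum(stats::runif(n, 0.4, 1.6)))
  tibble::tibble(feature = seq_len(n), lipid_name = name, lipid_class = plan,
                 total_carbons = carbons, total_double_bonds = dbs,
                 expected_mz = mz,
                 ionization_mode = cfg$ionization_mode,
                 source = "slide_scrape", parsed = TRUE)
}

default_effect_template <- function(features) {
  unsat <- features[features$lipid_class %in% c("PE", "PG") &
                      features$total_double_bonds >= 2, ]
  pick <- utils::head(unsat$feature, 10L)
  tibble::tibble(lipid = pick, region = "alveolar_epithelium",
                 group = "HDM_O3", sex = NA_character_, log2_effect = -1.0)
}

#' Generate a ground-truthed synthetic MSI dataset
#'
#' Pixel intensity is
#' `region_mean[region, lipid] * group_effect * sample_scale * drift(i) *
#' lognormal(0, sigma)`, then zeroed with the dropout probability; pixels are
#' acquired in row-major raster order. Identical seeds give byte-identical
#' output.
#'
#' @param config A [synthetic_config()].
#' @return List with `samples` (list of centroided [msi_sample()]s), `truth`
#'   (list: `regions`, `drift`, `region_means`, `effects`, `library`,
#'   `sample_info`) and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  cfg <- validate_synthetic_config(config)
  set.seed(cfg$seed)

  geom <- synthetic_geometry(cfg)
  features <- synthetic_features(cfg)
  n_feat <- nrow(features)
  regions <- unique(geom$region)
  tissue_regions <- setdiff(regions, "off_tissue")

  base_mean <- stats::rlnorm(n_feat, cfg$baseline_meanlog, cfg$baseline_sdlog)

  # marker assignment: airway epithelium gets polyunsaturated PE + SM,
  # alveolar field gets PG + saturated PC, the lumen a mixed panel,
  # off-tissue its matrix-derived peaks
  taken <- integer(0)
  pick_markers <- function(pref, n_needed) {
    pool <- setdiff(pref, taken)
    got <- utils::head(pool, n_needed)
    if (length(got) < n_needed) {
      rest <- setdiff(features$feature, c(taken, got))
      got <- c(got, utils::head(rest, n_needed - length(got)))
    }
    taken <<- c(taken, got)
    got
  }
  nm <- cfg$n_markers_per_region
  markers <- list(
    airway_epithelium = pick_markers(
      features$feature[(features$lipid_class == "PE" &
                          features$total_double_bonds >= 3) |
                         features$lipid_class == "SM"], nm),
    alveolar_epithelium = pick_markers(
      features$feature[features$lipid_class == "PG" |
                         (features$lipid_class == "PC" &
                            features$total_double_bonds <= 1)], nm),
    airway_lumen = pick_markers(
      features$feature[features$lipid_class %in% c("LPC", "LPE", "FA")], nm),
    # matrix-derived background ions: the tail of the panel, never lipids
    # carrying markers or planted effects
    off_tissue = utils::tail(setdiff(features$feature, taken),
                             cfg$n_matrix_peaks)
  )
  taken <- c(taken, markers$off_tissue)
  if (cfg$include_basement) {
    markers$basement_membrane <- pick_markers(
      features$feature[features$lipid_class == "PC" &
                         features$total_double_bonds >= 4], nm)
  }

  matrix_feats <- markers$off_tissue
  lipid_feats <- setdiff(features$feature, matrix_feats)
  # channels subject to off-tissue chemical interference
  noise_feats <- sort(sample(lipid_feats,
                             round(cfg$off_tissue_noise_frac *
                                     length(lipid_feats))))
  region_mean <- matrix(rep(base_mean, each = length(regions)),
                        nrow = length(regions),
                        dimnames = list(regions, features$lipid_name))
  for (r in regions) {
    if (r == "off_tissue") {
      region_mean[r, lipid_feats] <- base_mean[lipid_feats] *
        cfg$off_tissue_scale
    } else if (r == "airway_lumen") {
      region_mean[r, lipid_feats] <- base_mean[lipid_feats] * 0.25
    }
    mk <- markers[[r]]
    if (!is.null(mk) && r != "off_tissue") {
      region_mean[r, mk] <- base_mean[mk] * cfg$marker_fold
    }
  }
  # broad regional profile differences on top of the dedicated markers
  if (cfg$region_profile_sdlog > 0) {
    for (r in tissue_regions) {
      region_mean[r, lipid_feats] <- region_mean[r, lipid_feats] *
        stats::rlnorm(length(lipid_feats), 0, cfg$region_profile_sdlog)
    }
  }
  # matrix-derived background ions: strong on the bare matrix margin,
  # attenuated but present over tissue
  region_mean["off_tissue", matrix_feats] <-
    base_mean[matrix_feats] * cfg$marker_fold
  for (r in tissue_regions) {
    region_mean[r, matrix_feats] <- base_mean[matrix_feats] *
      cfg$matrix_tissue_scale
  }

  effects <- config$effects %||% default_effect_template(features)
  if (!all(effects$lipid %in% features$feature)) {
    rlang::abort("effect lipids must be a subset of the feature set")
  }
  if (!"sex" %in% names(effects)) effects$sex <- NA_character_

  sample_info <- tidyr::expand_grid(group = cfg$groups, sex = cfg$sexes,
                                    replicate = seq_len(cfg$n_per_cell))
  n_samples <- nrow(sample_info)
  sample_info$sample_id <- sprintf("S%02d_%s_%s_r%d", seq_len(n_samples),
                                   sample_info$group, sample_info$sex,
                                   sample_info$replicate)
  sample_info$run_order <- seq_len(n_samples)
  nrep <- cfg$n_per_cell
  rep_frac <- if (nrep == 1L) rep(0.5, 1) else (seq_len(nrep) - 1) / (nrep - 1)
  sample_info$scale <- if (n_samples == 1L) 1 else {
    cfg$sample_scale_spread^rep_frac[sample_info$replicate]
  }
  sample_info$matrix_scale <- if (n_samples == 1L) 1 else {
    cfg$matrix_scale_spread^rev(rep_frac)[sample_info$replicate]
  }

  npx <- nrow(geom)
  jit <- cfg$drift$feature_jitter
  a_f <- cfg$drift$amplitude * stats::runif(n_feat, 1 - jit, 1 + jit)
  a_f[matrix_feats] <- a_f[matrix_feats] * cfg$drift$matrix_factor
  drift_base <- switch(cfg$drift$type,
                       linear = geom$acquisition_index / npx,
                       sinusoidal = sin(2 * pi * geom$acquisition_index / npx))
  drift_mat <- 1 + outer(drift_base, a_f)
  drift_vals <- 1 + drift_base * cfg$drift$amplitude
  dropout <- rep(cfg$dropout, length.out = n_feat)
  region_idx <- match(geom$region, regions)

  samples <- vector("list", n_samples)
  truth_regions <- vector("list", n_samples)
  truth_drift <- vector("list", n_samples)
  truth_means <- vector("list", n_samples)

  for (s in seq_len(n_samples)) {
    info <- sample_info[s, ]
    effect_factor <- matrix(1, nrow = length(regions), ncol = n_feat,
                            dimnames = dimnames(region_mean))
    eff <- effects[effects$group == info$group &
                     (is.na(effects$sex) | effects$sex == info$sex), ]
    if (nrow(eff) > 0L) {
      for (e in seq_len(nrow(eff))) {
        effect_factor[eff$region[e], eff$lipid[e]] <-
          effect_factor[eff$region[e], eff$lipid[e]] * 2^eff$log2_effect[e]
      }
    }
    mean_se <- region_mean * effect_factor * info$scale
    mean_se[, matrix_feats] <- mean_se[, matrix_feats] * info$matrix_scale

    expected <- mean_se[region_idx, , drop = FALSE]
    # per-sample parenchymal texture: Voronoi patches of the alveolar field
    if (cfg$n_alveolar_patches > 1L && cfg$alveolar_texture_sdlog > 0) {
      alv <- which(geom$region == "alveolar_epithelium")
      if (length(alv) > cfg$n_alveolar_patches) {
        seeds_idx <- sample(alv, cfg$n_alveolar_patches)
        d <- outer(geom$x[alv], geom$x[seeds_idx], "-")^2 +
          outer(geom$y[alv], geom$y[seeds_idx], "-")^2
        patch <- max.col(-d, ties.method = "first")
        patch_factor <- matrix(
          stats::rlnorm(cfg$n_alveolar_patches * length(lipid_feats),
                        0, cfg$alveolar_texture_sdlog),
          nrow = cfg$n_alveolar_patches)
        expected[alv, lipid_feats] <- expected[alv, lipid_feats] *
          patch_factor[patch, ]
      }
    }
    values <- expected * drift_mat
    if (cfg$sigma > 0) {
      values <- values * matrix(stats::rlnorm(npx * n_feat, 0, cfg$sigma),
                                nrow = npx)
    }
    keep_prob <- matrix(1 - dropout, nrow = npx, ncol = n_feat, byrow = TRUE)
    keep_prob[geom$region == "off_tissue", lipid_feats] <- 0
    keep_prob[geom$region == "off_tissue", noise_feats] <-
      cfg$off_tissue_presence
    keep <- matrix(stats::runif(npx * n_feat), nrow = npx) < keep_prob
    values <- values * keep

    ord <- order(geom$acquisition_index)
    spectra <- tibble::tibble(
      x = geom$x[ord], y = geom$y[ord],
      acquisition_index = geom$acquisition_index[ord],
      mz = purrr::map(ord, function(p) {
        features$expected_mz[values[p, ] > 0]
      }),
      intensity = purrr::map(ord, function(p) {
        v <- values[p, ]
        unname(v[v > 0])
      })
    )
    samples[[s]] <- msi_sample(
      spectra, sample_id = info$sample_id,
      ionization_mode = cfg$ionization_mode, group = info$group,
      sex = info$sex, run_order = info$run_order,
      scan_range = cfg$scan_range, centroided = TRUE)

    truth_regions[[s]] <- dplyr::mutate(geom, sample_id = info$sample_id,
                                        .before = 1)
    truth_drift[[s]] <- tibble::tibble(
      sample_id = info$sample_id,
      acquisition_index = geom$acquisition_index[ord],
      drift = drift_vals[ord])
    tm <- as.data.frame.table(mean_se, responseName = "true_mean")
    names(tm)[1:2] <- c("region", "lipid_name")
    tm$sample_id <- info$sample_id
    truth_means[[s]] <- tibble::as_tibble(tm)
  }

  library <- as_annotation_library(features[lipid_feats, c(
    "lipid_name", "lipid_class", "total_carbons", "total_double_bonds",
    "expected_mz", "ionization_mode", "source", "parsed")])

  list(
    samples = samples,
    truth = list(
      regions = dplyr::bind_rows(truth_regions),
      drift = dplyr::bind_rows(truth_drift),
      region_means = dplyr::bind_rows(truth_means),
      effects = dplyr::left_join(effects,
                                 features[, c("feature", "lipid_name")],
                                 by = c(lipid = "feature")),
      library = library,
      feature_drift = tibble::tibble(
        lipid_name = features$lipid_name, drift_amplitude = a_f),
      markers = markers,
      sample_info = sample_info
    ),
    config = cfg
  )
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' permutation), about 0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return A number in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("labelings differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Score a segmentation against the generator's truth
#'
#' Maps each cluster to its majority truth region (region assignment is
#' many-to-one: a tissue region may span several clusters) and computes the
#' adjusted Rand index between the mapped labels and the truth, plus
#' per-region recall under the mapping. The unmapped (cluster-level) ARI is
#' reported alongside.
#'
#' @param seg An `msi_segmentation`.
#' @param truth Truth regions for the same sample: tibble with `x`, `y`
#'   (or `acquisition_index`) and `region`.
#' @return List of class `segmentation_evaluation`: `ari` (after majority
#'   mapping), `ari_raw` (cluster labels vs truth), `mapping`
#'   (cluster -> region), `recall` (per-region tibble).
#' @export
evaluate_segmentation <- function(seg, truth) {
  truth <- tibble::as_tibble(truth)
  if ("sample_id" %in% names(truth) && !is.na(seg$sample_id)) {
    truth <- truth[truth$sample_id == seg$sample_id, ]
  }
  key <- if (all(c("x", "y") %in% names(truth)) &&
             !anyNA(seg$pixels$x)) c("x", "y") else "acquisition_index"
  idx <- match(
    do.call(paste, seg$pixels[key]),
    do.call(paste, truth[key]))
  if (anyNA(idx) || nrow(truth) != length(seg$labels)) {
    rlang::abort("segmentation and truth cover different pixel sets")
  }
  truth_region <- truth$region[idx]
  ari_raw <- adjusted_rand_index(seg$labels, truth_region)

  mapping <- tibble::as_tibble(as.data.frame(table(
    cluster = seg$labels, region = truth_region),
    stringsAsFactors = FALSE))
  mapping <- dplyr::slice_max(
    dplyr::group_by(mapping, .data$cluster), .data$Freq,
    n = 1, with_ties = FALSE)
  mapping <- dplyr::ungroup(mapping)[, c("cluster", "region")]
  mapping$cluster <- as.integer(mapping$cluster)

  mapped <- mapping$region[match(seg$labels, mapping$cluster)]
  ari <- adjusted_rand_index(mapped, truth_region)
  recall <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(truth = truth_region, mapped = mapped),
                    region = .data$truth),
    n_pixels = dplyr::n(),
    recall = mean(.data$mapped == .data$region),
    .groups = "drop")

  structure(list(ari = ari, ari_raw = ari_raw, mapping = mapping,
                 recall = recall),
            class = "segmentation_evaluation")
}

#' @export
print.segmentation_evaluation <- function(x, ...) {
  cat(sprintf(
    "<segmentation_evaluation> mapped ARI %.3f (raw %.3f) over %d regions\n",
    x$ari, x$ari_raw, nrow(x$recall)))
  invisible(x)
}

#' @method glance segmentation_evaluation
#' @export
glance.segmentation_evaluation <- function(x, ...) {
  tibble::tibble(ari = x$ari, ari_raw = x$ari_raw,
                 n_regions = nrow(x$recall),
                 min_recall = min(x$recall$recall))
}
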