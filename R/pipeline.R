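# End-to-end orchestration: import/simulate -> peaks -> annotate ->
# normalize -> segment -> stats, from one validated config, with derived
# per-stage seeds and a provenance manifest.

pipeline_required_keys <- c("seed", "out_dir", "ppm", "snr", "tol_mda",
                            "span", "k", "prune", "pca_dims", "resolution",
                            "p_cut", "lfc_cut", "saturated_max_db")

#' Build and validate a pipeline configuration
#'
#' @param config A named list or the path to a YAML file. Required keys:
#'   `seed`, `out_dir`, and the stage parameters `ppm`, `snr`, `tol_mda`,
#'   `span`, `k`, `prune`, `pca_dims`, `resolution`, `p_cut`, `lfc_cut`,
#'   `saturated_max_db`. Input is either `simulate: true` (optionally with a
#'   `synthetic` block of [synthetic_config()] overrides) or an `inputs` block
#'   with `imzml` file/metadata entries, a `library` path, and optional
#'   `exclusions` path and `region_map` (sample -> cluster -> region).
#' @return The validated config list, class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) rlang::abort("config must be a list or a YAML path")
  for (key in pipeline_required_keys) {
    if (is.null(config[[key]])) {
      rlang::abort(sprintf("pipeline config is missing required key '%s'", key))
    }
  }
  assert_scalar_number(config$ppm, "ppm", lower = 0, strict_lower = TRUE)
  assert_scalar_number(config$snr, "snr", lower = 0, strict_lower = TRUE)
  assert_scalar_number(config$tol_mda, "tol_mda", lower = 0)
  assert_scalar_number(config$span, "span", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(config$k, "k", lower = 1)
  assert_scalar_number(config$prune, "prune", lower = 0, upper = 1)
  assert_scalar_number(config$pca_dims, "pca_dims", lower = 1)
  assert_scalar_number(config$resolution, "resolution", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(config$p_cut, "p_cut", lower = 0, upper = 1)
  assert_scalar_number(config$lfc_cut, "lfc_cut", lower = 0)
  assert_scalar_number(config$saturated_max_db, "saturated_max_db", lower = 0)
  assert_scalar_number(config$seed, "seed", lower = 0, upper = 2^31 - 1)
  if (!isTRUE(config$simulate) && is.null(config$inputs)) {
    rlang::abort("config needs either simulate: true or an inputs block")
  }
  structure(config, class = c("pipeline_config", "list"))
}

#' Default pipeline configuration
#'
#' A complete, explicit parameter set -- 5 ppm binning, SNR 3, 10 mDa
#' annotation tolerance, LOESS span fraction 0.10, k = 20 neighbors with
#' Jaccard pruning 1/15 on 10 principal components, Louvain resolution 0.9,
#' volcano cuts p < 0.05 and |log2 FC| > 0.5, saturation cutoff at 1 double
#' bond -- running on simulated input.
#'
#' @param out_dir Output directory.
#' @param seed Global seed fanned out to the stages.
#' @param synthetic Optional list of [synthetic_config()] overrides.
#' @return A `pipeline_config`.
#' @export
default_pipeline_config <- function(out_dir, seed = 1L, synthetic = list()) {
  pipeline_config(list(
    seed = seed, out_dir = out_dir, simulate = TRUE, synthetic = synthetic,
    ppm = 5, snr = 3, tol_mda = 10, span = 0.10, k = 20, prune = 1 / 15,
    pca_dims = 10, resolution = 0.9, p_cut = 0.05, lfc_cut = 0.5,
    saturated_max_db = 1
  ))
}

# global seed -> per-stage seeds, so stages are individually reproducible
stage_seeds <- function(seed) {
  base <- as.integer(seed) %% (2^31 - 1000L)
  list(simulate = base, segment = base + 1L)
}

#' Run the full pipeline from one config
#'
#' Executes import/simulate, peak alignment, annotation, normalization,
#' per-sample segmentation with region assignment, and regional statistics;
#' writes every stage output plus a JSON run manifest (file hashes, seed,
#' parameters, package version) into `out_dir`. A failure in any stage halts
#' the run with a stage-tagged error. Rerunning with the same config and seed
#' reproduces identical output hashes.
#'
#' @param config A [pipeline_config()] (or list/YAML path coercible to one).
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  seeds <- stage_seeds(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  # --- import / simulate ---------------------------------------------------
  truth <- NULL
  if (isTRUE(config$simulate)) {
    gen <- stage("simulate", {
      overrides <- config$synthetic %||% list()
      overrides$seed <- seeds$simulate
      cfg <- do.call(synthetic_config, overrides)
      generate_dataset(cfg)
    })
    samples <- gen$samples
    truth <- gen$truth
    library <- gen$truth$library
    exclusions <- tibble::tibble(mz = double())
  } else {
    samples <- stage("import", {
      manifest <- tibble::as_tibble(config$inputs$imzml)
      purrr::pmap(manifest, function(path, sample_id, mode, group, sex,
                                     run_order, ...) {
        read_imzml(path, sample_id = sample_id, ionization_mode = mode,
                   group = group, sex = sex, run_order = run_order)
      })
    })
    library <- stage("import", load_annotation_library(config$inputs$library))
    exclusions <- if (!is.null(config$inputs$exclusions)) {
      stage("import", load_exclusion_list(config$inputs$exclusions))
    } else tibble::tibble(mz = double())
  }

  # --- peaks ---------------------------------------------------------------
  bins <- stage("peaks", align_features(samples, tolerance_ppm = config$ppm,
                                        snr = config$snr))
  matrices <- stage("peaks", build_feature_matrix(samples, bins,
                                                  snr = config$snr))

  # --- annotate ------------------------------------------------------------
  mode <- samples[[1]]$ionization_mode
  annotations <- stage("annotate", {
    ann <- match_features(bins, library, tolerance_da = config$tol_mda / 1000,
                          mode = mode,
                          saturated_max_db = config$saturated_max_db)
    ann <- filter_incompatible_classes(ann, mode)
    apply_exclusion_list(ann, exclusions)
  })
  if (nrow(annotations) == 0L) {
    rlang::abort("stage 'annotate' failed: no features were annotated")
  }
  restrict <- function(fm) {
    fm <- select_features(fm, unique(annotations$feature_mz))
    fm$annotation <- annotations[annotations$feature_mz %in% fm$mz, ]
    fm
  }
  matrices_full <- matrices
  matrices <- purrr::map(matrices_full, restrict)

  # --- normalize -----------------------------------------------------------
  # TIC divides by the whole-spectrum pixel sum (annotated + background),
  # as acquired; drift is always reported on the annotated-compound sums
  norm <- stage("normalize", {
    tic <- purrr::map(purrr::map(matrices_full, tic_normalize), restrict)
    lo <- sparse_loess_normalize(matrices, span_fraction = config$span)
    report <- drift_report(raw = matrices, tic = tic, loess = lo$matrices)
    list(tic = tic, loess = lo, report = report)
  })
  normalized <- norm$loess$matrices

  # --- segment -------------------------------------------------------------
  segments <- stage("segment", purrr::imap(normalized, function(fm, sid) {
    segment_sample(fm, k = config$k, prune = config$prune,
                   pca_dims = config$pca_dims,
                   resolution = config$resolution, seed = seeds$segment)
  }))
  region_assignments <- stage("segment", purrr::map(segments, function(seg) {
    map <- if (!is.null(truth)) {
      evaluate_segmentation(seg, truth$regions)$mapping
    } else {
      rm_cfg <- config$inputs$region_map[[seg$sample_id]]
      if (is.null(rm_cfg)) {
        rlang::abort(sprintf("no region map for sample '%s'", seg$sample_id))
      }
      tibble::tibble(cluster = as.integer(names(rm_cfg)),
                     region = unlist(rm_cfg, use.names = FALSE))
    }
    assign_regions(seg, map)
  }))
  markers <- stage("segment", purrr::map2(normalized, segments,
                                          top_cluster_lipids))

  # --- stats ---------------------------------------------------------------
  stats_out <- stage("stats", {
    summaries <- summarize_regions(normalized, region_assignments)
    diff <- differential_anova(summaries)
    diff <- classify_volcano(diff, p_cut = config$p_cut,
                             lfc_cut = config$lfc_cut)
    enr <- ks_class_enrichment(diff,
                               saturated_max_db = config$saturated_max_db)
    list(summaries = summaries, differential = diff, enrichment = enr)
  })

  # --- write outputs -------------------------------------------------------
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
    files <<- c(files, path)
  }
  emit(bins, "feature_bins.csv")
  emit(annotations, "annotations.csv")
  emit(tibble::as_tibble(norm$report), "drift_report.csv")
  emit(norm$loess$skipped, "loess_skipped.csv")
  seg_tables <- purrr::map(region_assignments, tibble::as_tibble)
  seg_all <- dplyr::bind_rows(seg_tables)
  path <- file.path(out_dir, "segmentation.tsv")
  readr::write_tsv(seg_all, path, progress = FALSE)
  files <- c(files, path)
  emit(dplyr::bind_rows(markers, .id = "sample_id"), "cluster_markers.csv")
  emit(stats_out$summaries, "region_summary.csv")
  emit(stats_out$differential, "differential.csv")
  emit(stats_out$enrichment, "enrichment.csv")

  manifest <- list(
    package = "msiregion",
    version = as.character(utils::packageVersion("msiregion")),
    seed = config$seed,
    stage_seeds = seeds,
    parameters = config[intersect(names(config), pipeline_required_keys)],
    n_samples = length(samples),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(structure(
    list(manifest = manifest, manifest_path = manifest_path,
         bins = bins, annotations = annotations, matrices = matrices,
         normalized = normalized, drift = norm$report, segments = segments,
         regions = region_assignments, markers = markers,
         summaries = stats_out$summaries,
         differential = stats_out$differential,
         enrichment = stats_out$enrichment,
         truth = truth),
    class = "msi_pipeline_result"))
}

#' @export
print.msi_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<msi_pipeline_result> %d sample(s), %d feature bin(s), %d annotation(s)\n",
    x$manifest$n_samples, nrow(x$bins), nrow(x$annotations)))
  cat(sprintf("  outputs: %s\n", dirname(x$manifest_path)))
  invisible(x)
}
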