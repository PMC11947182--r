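# shared fixtures, all built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny hand-made sample: n pixels on one row, centroided by default
tiny_sample <- function(n = 3, sample_id = "tiny", mode = "negative",
                        centroided = TRUE, mz_axes = NULL,
                        intensities = NULL) {
  mz_axes <- mz_axes %||% purrr::map(seq_len(n), ~ c(700.1, 750.2, 800.3))
  intensities <- intensities %||% purrr::map(seq_len(n), ~ c(10, 20, 30) * .x)
  spectra <- tibble::tibble(
    x = seq_len(n), y = rep(1L, n), acquisition_index = seq_len(n),
    mz = mz_axes, intensity = intensities
  )
  msi_sample(spectra, sample_id = sample_id, ionization_mode = mode,
             centroided = centroided)
}

# toy annotation library as a tibble (and optionally on disk)
toy_library_tbl <- function() {
  tibble::tibble(
    name = c("PE 18:0/22:6", "SM 44:1", "PC 32:0", "PI 36:4", "PS 40:6",
             "FA 22:6", "PG 34:1"),
    class = c("PE", "SM", "PC", "PI", "PS", "FA", "PG"),
    mz = c(790.539, 841.679, 734.569, 857.519, 834.529, 327.233, 747.518),
    mode = c("negative", "positive", "positive", "negative", "negative",
             "negative", "negative")
  )
}

write_toy_library <- function(path = tempfile(fileext = ".csv")) {
  readr::write_csv(toy_library_tbl(), path, progress = FALSE)
  path
}

toy_library <- function() {
  load_annotation_library(write_toy_library())
}

# small feature matrix with known structure
toy_feature_matrix <- function(values, sample_id = "fm", mz = NULL,
                               group = NA, sex = NA, run_order = 1L) {
  values <- as.matrix(values)
  mz <- mz %||% (700 + seq_len(ncol(values)))
  n <- nrow(values)
  pixels <- tibble::tibble(x = seq_len(n), y = rep(1L, n),
                           acquisition_index = seq_len(n))
  feature_matrix(values, pixels, mz, sample_id,
                 meta = list(ionization_mode = "negative", group = group,
                             sex = sex, run_order = run_order,
                             centroided = TRUE))
}

# small synthetic dataset used by several test files (cached per session)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(width = 36, height = 36, n_features = 40,
                              groups = c("control", "HDM_O3"), sexes = "F",
                              n_per_cell = 1, seed = 303)
      cache <<- generate_dataset(cfg)
    }
    cache
  }
})
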