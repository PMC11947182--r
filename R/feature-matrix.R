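#' Construct a pixel-by-feature matrix
#'
#' A `feature_matrix` holds one sample's pixels (rows, ordered by acquisition
#' index) against the shared, aligned feature list (columns, m/z bin centers).
#' Zero encodes absent signal.
#'
#' @param values Numeric matrix, pixels x features, non-negative.
#' @param pixels Tibble with `x`, `y`, `acquisition_index` (one row per matrix
#'   row, in matrix row order).
#' @param mz Numeric vector of bin-center m/z values (one per column).
#' @param sample_id Sample identifier.
#' @param meta List of sample metadata (`ionization_mode`, `group`, `sex`,
#'   `run_order`, `centroided`).
#' @param annotation Optional `lipid_annotations` tibble for the columns.
#'
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, pixels, mz, sample_id, meta = list(),
                           annotation = NULL) {
  values <- as.matrix(values)
  pixels <- tibble::as_tibble(pixels)
  if (nrow(values) != nrow(pixels)) {
    rlang::abort("values and pixels disagree on the number of pixels")
  }
  if (ncol(values) != length(mz)) {
    rlang::abort("values and mz disagree on the number of features")
  }
  if (any(values < 0)) rlang::abort("feature matrix values must be >= 0")
  if (is.unsorted(mz, strictly = TRUE)) {
    rlang::abort("feature m/z centers must be strictly increasing")
  }
  colnames(values) <- format_mz(mz)
  structure(
    list(sample_id = as.character(sample_id), values = values,
         pixels = pixels, mz = as.numeric(mz), meta = meta,
         annotation = annotation),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s | %d pixels x %d features | %s mode\n",
              x$sample_id, nrow(x$values), ncol(x$values),
              x$meta$ionization_mode %||% "?"))
  invisible(x)
}

#' Long-format view of a feature matrix
#'
#' @param x A `feature_matrix`.
#' @param keep_zeros Keep zero cells? Default drops them (sparse contract).
#' @param ... Unused.
#' @return Tibble with `sample_id`, `x`, `y`, `acquisition_index`, `mz`,
#'   `intensity`.
#' @method as_tibble feature_matrix
#' @export
as_tibble.feature_matrix <- function(x, keep_zeros = FALSE, ...) {
  long <- tibble::tibble(
    sample_id = x$sample_id,
    x = rep(x$pixels$x, times = ncol(x$values)),
    y = rep(x$pixels$y, times = ncol(x$values)),
    acquisition_index = rep(x$pixels$acquisition_index, times = ncol(x$values)),
    mz = rep(x$mz, each = nrow(x$values)),
    intensity = as.vector(x$values)
  )
  if (!keep_zeros) long <- long[long$intensity > 0, ]
  long
}

#' Restrict a feature matrix to a subset of features
#'
#' @param fm A `feature_matrix`.
#' @param mz_keep Numeric vector of bin centers to keep (matched exactly).
#' @return A `feature_matrix` with the selected columns.
#' @export
select_features <- function(fm, mz_keep) {
  idx <- which(fm$mz %in% mz_keep)
  if (length(idx) == 0L) rlang::abort("no matching features to keep")
  ann <- fm$annotation
  if (!is.null(ann)) ann <- ann[ann$feature_mz %in% fm$mz[idx], ]
  feature_matrix(fm$values[, idx, drop = FALSE], fm$pixels, fm$mz[idx],
                 fm$sample_id, fm$meta, ann)
}

#' Per-pixel total ion current of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @return Tibble with `sample_id`, `acquisition_index`, `tic`.
#' @export
tic_series <- function(fm) {
  tibble::tibble(
    sample_id = fm$sample_id,
    acquisition_index = fm$pixels$acquisition_index,
    tic = unname(rowSums(fm$values))
  )
}

#' Export a feature matrix as sparse-triplet tables
#'
#' Writes three plain-text files: `<stem>_triplets.csv` (pixel, feature,
#' value for non-zero cells), `<stem>_pixels.csv` and `<stem>_features.csv`.
#'
#' @param fm A `feature_matrix`.
#' @param stem Output path stem.
#' @return Character vector of the files written, invisibly.
#' @export
write_feature_matrix <- function(fm, stem) {
  nz <- which(fm$values > 0, arr.ind = TRUE)
  triplets <- tibble::tibble(
    pixel = nz[, 1], feature = nz[, 2],
    value = fm$values[nz]
  )
  files <- paste0(stem, c("_triplets.csv", "_pixels.csv", "_features.csv"))
  readr::write_csv(triplets, files[1], progress = FALSE)
  readr::write_csv(fm$pixels, files[2], progress = FALSE)
  readr::write_csv(tibble::tibble(feature = seq_along(fm$mz), mz = fm$mz),
                   files[3], progress = FALSE)
  invisible(files)
}
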