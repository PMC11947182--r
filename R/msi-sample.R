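#' Construct an MSI sample
#'
#' An `msi_sample` holds the pixel spectra of one tissue section together with
#' its acquisition metadata. Pixel coordinates follow the imzML convention
#' (1-based integers); `acquisition_index` records the order in which pixels
#' were acquired and is the axis along which signal drift is modelled.
#'
#' @param spectra A data frame with columns `x`, `y`, `acquisition_index`,
#'   `mz` (list of numeric vectors, each sorted ascending) and `intensity`
#'   (list of non-negative numeric vectors, same lengths as `mz`).
#' @param sample_id Sample identifier.
#' @param ionization_mode `"positive"` or `"negative"`.
#' @param group Treatment group label (e.g. `"control"`, `"HDM_O3"`).
#' @param sex `"F"` or `"M"` (or `NA`).
#' @param run_order Integer position of this section in the acquisition batch.
#' @param scan_range Length-2 numeric, the instrument m/z scan window.
#' @param centroided Logical; `TRUE` when spectra are already centroided so
#'   peak detection reduces to thresholding.
#'
#' @return An object of class `msi_sample`.
#' @export
msi_sample <- function(spectra, sample_id, ionization_mode,
                       group = NA_character_, sex = NA_character_,
                       run_order = 1L, scan_range = NULL, centroided = FALSE) {
  spectra <- tibble::as_tibble(spectra)
  out <- structure(
    list(
      sample_id = as.character(sample_id),
      ionization_mode = normalize_mode(ionization_mode),
      group = as.character(group),
      sex = as.character(sex),
      run_order = as.integer(run_order),
      scan_range = scan_range,
      centroided = isTRUE(centroided),
      spectra = spectra
    ),
    class = "msi_sample"
  )
  validate_msi_sample(out)
}

#' Validate an MSI sample against its invariants
#'
#' Checks coordinate uniqueness, that acquisition indices are a permutation of
#' `1..n_pixels`, non-negative intensities, per-pixel array length agreement
#' and strictly increasing m/z axes.
#'
#' @param sample An `msi_sample`.
#' @return `sample`, invisibly usable, after validation.
#' @export
validate_msi_sample <- function(sample) {
  sp <- sample$spectra
  need <- c("x", "y", "acquisition_index", "mz", "intensity")
  missing <- setdiff(need, names(sp))
  if (length(missing)) {
    rlang::abort(sprintf("spectra is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (nrow(sp) == 0L) rlang::abort("sample has no pixels")
  if (any(sp$x < 1L) || any(sp$y < 1L)) {
    rlang::abort("pixel coordinates must be >= 1 (imzML convention)")
  }
  if (anyDuplicated(sp[c("x", "y")])) {
    rlang::abort(sprintf("duplicate pixel coordinates in sample '%s'",
                         sample$sample_id))
  }
  if (!setequal(sp$acquisition_index, seq_len(nrow(sp)))) {
    rlang::abort("acquisition_index must be a permutation of 1..n_pixels")
  }
  lens_ok <- purrr::map2_lgl(sp$mz, sp$intensity,
                             ~ length(.x) == length(.y))
  if (!all(lens_ok)) rlang::abort("mz and intensity lengths differ for a pixel")
  mz_ok <- purrr::map_lgl(sp$mz, ~ length(.x) < 2L || all(diff(.x) > 0))
  if (!all(mz_ok)) rlang::abort("pixel m/z arrays must be strictly increasing")
  int_ok <- purrr::map_lgl(sp$intensity, ~ all(.x >= 0))
  if (!all(int_ok)) rlang::abort("intensities must be non-negative")
  sample
}

#' @export
print.msi_sample <- function(x, ...) {
  cat(sprintf(
    "<msi_sample> %s | %s mode | group %s, sex %s | %d pixels%s\n",
    x$sample_id, x$ionization_mode, x$group, x$sex, nrow(x$spectra),
    if (x$centroided) " (centroided)" else ""
  ))
  invisible(x)
}

n_pixels <- function(sample) nrow(sample$spectra)

#' Pixel table of an MSI sample
#'
#' @param x An `msi_sample`.
#' @param ... Unused.
#' @return Long tibble with one row per (pixel, m/z) point.
#' @method as_tibble msi_sample
#' @export
as_tibble.msi_sample <- function(x, ...) {
  sp <- x$spectra
  tibble::tibble(
    sample_id = x$sample_id,
    x = rep(sp$x, lengths(sp$mz)),
    y = rep(sp$y, lengths(sp$mz)),
    acquisition_index = rep(sp$acquisition_index, lengths(sp$mz)),
    mz = unlist(sp$mz, use.names = FALSE),
    intensity = unlist(sp$intensity, use.names = FALSE)
  )
}
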