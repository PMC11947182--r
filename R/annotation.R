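# Accurate-mass annotation of aligned features against an LC-MS/MS library,
# with ionization-mode compatibility filtering and manual exclusion windows.

#' Match aligned features against a lipid library by accurate mass
#'
#' Each feature is matched to library entries within `tolerance_da` of its
#' bin center (10 mDa by default). When several entries qualify, the smallest
#' absolute mass error wins; exact ties are all reported and flagged
#' ambiguous. Unmatched features yield no rows.
#'
#' @param bins A `feature_bins` tibble or a numeric vector of feature m/z.
#' @param library An `annotation_library` tibble
#'   (see [load_annotation_library()]).
#' @param tolerance_da Matching tolerance in Dalton, default 0.010 (10 mDa).
#' @param mode Optional ionization mode; the library is restricted to it
#'   before matching.
#' @param saturated_max_db Double-bond cutoff forwarded to
#'   [classify_saturation()].
#' @return Tibble of class `lipid_annotations`: `feature_mz`, `lipid_name`,
#'   `lipid_class`, `total_carbons`, `total_double_bonds`, `ionization_mode`,
#'   `source`, `mass_error_da` (feature minus library), `ambiguous`,
#'   `saturation`.
#' @export
match_features <- function(bins, library, tolerance_da = 0.010, mode = NULL,
                           saturated_max_db = 1L) {
  assert_scalar_number(tolerance_da, "tolerance_da", lower = 0)
  if (nrow(library) == 0L) rlang::abort("annotation library is empty")
  feature_mz <- if (is.numeric(bins)) bins else bins$mz
  lib <- library
  if (!is.null(mode)) {
    lib <- lib[lib$ionization_mode == normalize_mode(mode), ]
  }

  rows <- purrr::map(feature_mz, function(fmz) {
    err <- fmz - lib$expected_mz
    sel <- which(abs(err) <= tolerance_da)
    if (length(sel) == 0L) return(NULL)
    best <- min(abs(err[sel]))
    hits <- sel[abs(err[sel]) == best]
    out <- lib[hits, ]
    out$feature_mz <- fmz
    out$mass_error_da <- err[hits]
    out$ambiguous <- length(hits) > 1L
    out
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      feature_mz = double(), lipid_name = character(),
      lipid_class = character(), total_carbons = integer(),
      total_double_bonds = integer(), ionization_mode = character(),
      source = character(), mass_error_da = double(), ambiguous = logical())
  } else {
    out <- out[, c("feature_mz", "lipid_name", "lipid_class", "total_carbons",
                   "total_double_bonds", "ionization_mode", "source",
                   "mass_error_da", "ambiguous")]
  }
  out$saturation <- classify_saturation(out$total_double_bonds,
                                        saturated_max_db = saturated_max_db)
  class(out) <- c("lipid_annotations", class(out))
  out
}

#' Remove annotations implausible for the acquisition's ionization mode
#'
#' In positive mode, phosphatidylinositol (PI) and phosphatidylserine (PS)
#' matches are removed: these classes ionize poorly as positive ions, so such
#' matches are likely false. The class sets are configurable per mode; removal
#' counts are reported and kept in the `"removed"` attribute.
#'
#' @param annotations A `lipid_annotations` tibble.
#' @param mode Ionization mode of the acquisition.
#' @param incompatible Named list of class vectors to drop per mode.
#' @return The filtered `lipid_annotations`.
#' @export
filter_incompatible_classes <- function(annotations, mode,
                                        incompatible = list(
                                          positive = c("PI", "PS"),
                                          negative = character())) {
  mode <- normalize_mode(mode)
  drop_classes <- incompatible[[mode]] %||% character()
  drop <- annotations$lipid_class %in% drop_classes
  removed <- annotations[drop, ]
  if (nrow(removed) > 0L) {
    counts <- table(removed$lipid_class)
    rlang::inform(sprintf(
      "removed %d %s-mode-incompatible annotation(s): %s",
      nrow(removed), mode,
      paste(sprintf("%s (%d)", names(counts), counts), collapse = ", ")))
  }
  out <- annotations[!drop, ]
  attr(out, "removed") <- removed
  out
}

#' Remove features on a manual exclusion list
#'
#' Drops annotations whose feature m/z falls within any exclusion window
#' (each entry carries its own ppm tolerance, default 5). An audit log of
#' per-window removal counts is attached as the `"exclusion_log"` attribute.
#'
#' @param annotations A `lipid_annotations` tibble.
#' @param exclusions Data frame with column `mz` and optional
#'   `tolerance_ppm`; or a numeric vector of m/z values.
#' @param default_tolerance_ppm Tolerance used when `exclusions` has none.
#' @return The filtered `lipid_annotations`.
#' @export
apply_exclusion_list <- function(annotations, exclusions,
                                 default_tolerance_ppm = 5) {
  if (is.numeric(exclusions)) {
    exclusions <- tibble::tibble(mz = exclusions)
  }
  exclusions <- tibble::as_tibble(exclusions)
  if (nrow(exclusions) == 0L) {
    attr(annotations, "exclusion_log") <-
      tibble::tibble(mz = double(), tolerance_ppm = double(),
                     n_removed = integer())
    return(annotations)
  }
  if (!"tolerance_ppm" %in% names(exclusions)) {
    exclusions$tolerance_ppm <- default_tolerance_ppm
  }
  exclusions$tolerance_ppm[is.na(exclusions$tolerance_ppm)] <-
    default_tolerance_ppm

  hit <- rep(FALSE, nrow(annotations))
  log_rows <- purrr::pmap(exclusions[c("mz", "tolerance_ppm")],
                          function(mz, tolerance_ppm) {
    in_window <- ppm_distance(annotations$feature_mz, mz) <= tolerance_ppm
    hit <<- hit | in_window
    tibble::tibble(mz = mz, tolerance_ppm = tolerance_ppm,
                   n_removed = sum(in_window))
  })
  log <- dplyr::bind_rows(log_rows)
  if (any(hit)) {
    rlang::inform(sprintf("excluded %d annotation(s) in %d window(s)",
                          sum(hit), sum(log$n_removed > 0)))
  }
  out <- annotations[!hit, ]
  attr(out, "exclusion_log") <- log
  out
}

#' Load an m/z exclusion list
#'
#' @param path CSV/TSV file with column `mz` and optional `tolerance_ppm`.
#' @return Tibble with `mz` and `tolerance_ppm`.
#' @export
load_exclusion_list <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!"mz" %in% names(out)) {
    rlang::abort("exclusion list is missing required column 'mz'")
  }
  tibble::as_tibble(out)
}

#' Classify lipid saturation from the total double-bond count
#'
#' A lipid counts as having a high degree of saturation ("saturated") when its
#' total double bonds are at most `saturated_max_db`; the default of 1 groups
#' monounsaturated with fully saturated species. Unknown double-bond counts
#' map to `"unknown"` and are excluded from saturation-split sets downstream.
#'
#' @param double_bonds Integer vector of total double-bond counts (NA allowed).
#' @param saturated_max_db Cutoff, default 1.
#' @return Character vector over `"saturated"`, `"unsaturated"`, `"unknown"`.
#' @export
classify_saturation <- function(double_bonds, saturated_max_db = 1L) {
  assert_scalar_number(saturated_max_db, "saturated_max_db", lower = 0)
  dplyr::case_when(
    is.na(double_bonds) ~ "unknown",
    double_bonds <= saturated_max_db ~ "saturated",
    TRUE ~ "unsaturated"
  )
}
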