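# Peak detection, ppm binning, and cross-sample feature alignment.

#' Detect peaks in one pixel spectrum
#'
#' Picks local maxima whose intensity exceeds `snr` times a robust noise
#' estimate (1.4826 x the median absolute deviation of the full signal), then
#' enforces a minimum peak separation of one bin width (`min_sep_ppm`),
#' keeping the more intense apex. On centroided spectra detection degenerates
#' to thresholding: every point above the noise threshold is a peak.
#'
#' @param mz Sorted numeric vector of m/z values.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param snr Signal-to-noise threshold (> 0), default 3.
#' @param min_sep_ppm Minimum apex separation in ppm, default 5 (one bin
#'   width at the default binning tolerance).
#' @param centroided Spectrum already centroided?
#' @return Tibble with columns `mz`, `intensity` (apex points, ascending m/z).
#' @export
detect_peaks <- function(mz, intensity, snr = 3, min_sep_ppm = 5,
                         centroided = FALSE) {
  assert_scalar_number(snr, "snr", lower = 0, strict_lower = TRUE)
  if (length(mz) != length(intensity)) {
    rlang::abort("mz and intensity must have the same length")
  }
  empty <- tibble::tibble(mz = double(), intensity = double())
  if (length(mz) == 0L) return(empty)
  if (is.unsorted(mz)) rlang::abort("mz must be sorted ascending")

  if (centroided) {
    keep <- intensity > 0
    return(tibble::tibble(mz = mz[keep], intensity = intensity[keep]))
  }
  kept <- detect_peak_idx(mz, intensity, snr = snr,
                          min_sep_ppm = min_sep_ppm)
  tibble::tibble(mz = mz[kept], intensity = intensity[kept])
}

# apex indices of one profile spectrum (the workhorse behind detect_peaks)
detect_peak_idx <- function(mz, intensity, snr = 3, min_sep_ppm = 5) {
  noise <- stats::mad(intensity)
  threshold <- snr * noise
  n <- length(intensity)
  if (n == 0L) return(integer())
  if (n == 1L) {
    return(if (intensity > max(threshold, 0)) 1L else integer())
  }
  left <- c(-Inf, intensity[-n])
  right <- c(intensity[-1], -Inf)
  cand <- which(intensity > 0 & intensity > threshold &
                  intensity >= left & intensity > right)
  if (length(cand) == 0L) return(integer())

  # enforce minimum apex separation, strongest peaks first
  ord <- cand[order(intensity[cand], decreasing = TRUE)]
  kept_mz <- numeric(0)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept_mz) == 0L ||
        all(abs(mz[i] - kept_mz) > min_sep_ppm * 1e-6 * kept_mz)) {
      kept <- c(kept, i)
      kept_mz <- c(kept_mz, mz[i])
    }
  }
  sort(kept)
}

#' Bin m/z values at a ppm tolerance
#'
#' Greedy left-to-right merge over the sorted values: a value joins the open
#' bin while its ppm distance to the running bin mean is at most
#' `tolerance_ppm`, otherwise it opens a new bin. Bin centers are bin means,
#' so consecutive centers always differ by more than the tolerance.
#'
#' @param values Positive, finite m/z values (any order).
#' @param tolerance_ppm Bin tolerance in ppm, default 5.
#' @param sample_id Optional vector parallel to `values`; when given, each
#'   bin records how many distinct samples contributed to it.
#' @return Tibble of class `feature_bins` with columns `mz` (center),
#'   `n_peaks`, `n_samples`; the tolerance is kept in the
#'   `"tolerance_ppm"` attribute.
#' @export
bin_mz <- function(values, tolerance_ppm = 5, sample_id = NULL) {
  assert_scalar_number(tolerance_ppm, "tolerance_ppm", lower = 0,
                       strict_lower = TRUE)
  if (length(values) == 0L) {
    return(new_feature_bins(double(), integer(), integer(), tolerance_ppm))
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    rlang::abort("m/z values must be positive and finite")
  }
  ord <- order(values)
  v <- values[ord]
  sid <- if (!is.null(sample_id)) as.character(sample_id)[ord] else NULL
  tol <- tolerance_ppm * 1e-6

  # fast path: segments separated by gaps too wide to ever merge; a whole
  # segment collapses to one bin when its spread is within tolerance of its
  # minimum (running mean >= min, so the greedy rule is implied)
  n <- length(v)
  gap_new <- c(TRUE, diff(v) > tol * v[-n])
  seg <- cumsum(gap_new)
  starts <- which(gap_new)
  ends <- c(starts[-1] - 1L, n)

  centers <- numeric(0); counts <- integer(0); bin_of <- integer(n)
  next_bin <- 0L
  for (s in seq_along(starts)) {
    i0 <- starts[s]; i1 <- ends[s]
    seg_v <- v[i0:i1]
    if ((seg_v[length(seg_v)] - seg_v[1]) <= tol * seg_v[1]) {
      next_bin <- next_bin + 1L
      centers[next_bin] <- mean(seg_v)
      counts[next_bin] <- length(seg_v)
      bin_of[i0:i1] <- next_bin
    } else {
      run_sum <- 0; run_n <- 0L
      for (i in i0:i1) {
        if (run_n > 0L &&
            (v[i] - run_sum / run_n) <= tol * (run_sum / run_n)) {
          run_sum <- run_sum + v[i]; run_n <- run_n + 1L
          counts[next_bin] <- counts[next_bin] + 1L
          centers[next_bin] <- run_sum / run_n
          bin_of[i] <- next_bin
        } else {
          next_bin <- next_bin + 1L
          run_sum <- v[i]; run_n <- 1L
          centers[next_bin] <- v[i]
          counts[next_bin] <- 1L
          bin_of[i] <- next_bin
        }
      }
    }
  }

  n_samples <- if (!is.null(sid)) {
    as.integer(tapply(sid, bin_of, function(z) length(unique(z))))
  } else {
    rep(NA_integer_, length(centers))
  }
  new_feature_bins(centers, counts, n_samples, tolerance_ppm)
}

new_feature_bins <- function(mz, n_peaks, n_samples, tolerance_ppm) {
  out <- tibble::tibble(mz = as.numeric(mz), n_peaks = as.integer(n_peaks),
                        n_samples = as.integer(n_samples))
  attr(out, "tolerance_ppm") <- tolerance_ppm
  class(out) <- c("feature_bins", class(out))
  out
}

# per-sample peak tables: one row per (pixel, apex); index lists are
# collected per pixel and materialised in one pass
detect_sample_peaks <- function(sample, snr = 3, min_sep_ppm = 5) {
  sp <- sample$spectra
  if (sample$centroided) {
    idx_list <- purrr::map(sp$intensity, ~ which(.x > 0))
  } else {
    idx_list <- purrr::map2(sp$mz, sp$intensity, detect_peak_idx,
                            snr = snr, min_sep_ppm = min_sep_ppm)
  }
  n_per_pixel <- lengths(idx_list)
  out <- tibble::tibble(
    mz = unlist(purrr::map2(sp$mz, idx_list, ~ .x[.y]), use.names = FALSE),
    intensity = unlist(purrr::map2(sp$intensity, idx_list, ~ .x[.y]),
                       use.names = FALSE),
    acquisition_index = rep(sp$acquisition_index, n_per_pixel)
  )
  out$sample_id <- rep(sample$sample_id, nrow(out))
  out
}

#' Build one shared feature list across samples
#'
#' Pools peak apex m/z values from every pixel of every sample and runs a
#' single global ppm binning pass, so all samples are aligned to the same
#' feature axis.
#'
#' @param samples List of [msi_sample()] objects (same ionization mode).
#' @param tolerance_ppm Binning tolerance in ppm, default 5.
#' @param snr Peak-detection signal-to-noise threshold, default 3.
#' @return A `feature_bins` tibble (see [bin_mz()]).
#' @export
align_features <- function(samples, tolerance_ppm = 5, snr = 3) {
  check_same_mode(samples)
  peaks <- dplyr::bind_rows(
    purrr::map(samples, detect_sample_peaks, snr = snr,
               min_sep_ppm = tolerance_ppm))
  bin_mz(peaks$mz, tolerance_ppm = tolerance_ppm, sample_id = peaks$sample_id)
}

check_same_mode <- function(samples) {
  modes <- unique(purrr::map_chr(samples, "ionization_mode"))
  if (length(modes) != 1L) {
    rlang::abort("samples mix ionization modes; process each mode separately")
  }
  invisible(modes)
}

#' Build aligned pixel-by-feature matrices
#'
#' For each sample, every pixel's bin value is the sum of its detected peak
#' intensities lying within the binning tolerance of the bin center (nearest
#' center wins); absent signal is 0. All returned matrices share the same
#' feature axis.
#'
#' @param samples List of [msi_sample()] objects (same ionization mode).
#' @param bins A `feature_bins` tibble from [bin_mz()]/[align_features()].
#' @param snr Peak-detection signal-to-noise threshold, default 3.
#' @return Named list of [feature_matrix()] objects, one per sample.
#' @export
build_feature_matrix <- function(samples, bins, snr = 3) {
  if (inherits(samples, "msi_sample")) samples <- list(samples)
  check_same_mode(samples)
  if (nrow(bins) == 0L) rlang::abort("bins must be non-empty")
  centers <- bins$mz
  tol <- attr(bins, "tolerance_ppm") %||% 5

  mats <- purrr::map(samples, function(s) {
    pk <- detect_sample_peaks(s, snr = snr, min_sep_ppm = tol)
    npx <- n_pixels(s)
    values <- matrix(0, nrow = npx, ncol = length(centers))
    if (nrow(pk) > 0L) {
      # nearest center by index, accepted within ppm tolerance
      pos <- findInterval(pk$mz, centers)
      lo <- pmax(pos, 1L)
      hi <- pmin(pos + 1L, length(centers))
      d_lo <- abs(pk$mz - centers[lo])
      d_hi <- abs(pk$mz - centers[hi])
      nearest <- ifelse(d_lo <= d_hi, lo, hi)
      ok <- ppm_distance(pk$mz, centers[nearest]) <= tol
      if (any(ok)) {
        idx <- cbind(pk$acquisition_index[ok], nearest[ok])
        agg <- rowsum(pk$intensity[ok],
                      group = (idx[, 1] - 1) * length(centers) + idx[, 2])
        keys <- as.numeric(rownames(agg))
        rows <- ((keys - 1) %/% length(centers)) + 1
        cols <- ((keys - 1) %% length(centers)) + 1
        values[cbind(rows, cols)] <- agg[, 1]
      }
    }
    # matrix rows follow acquisition order
    pixels <- s$spectra[order(s$spectra$acquisition_index),
                        c("x", "y", "acquisition_index")]
    feature_matrix(values, pixels, centers, s$sample_id,
                   meta = list(ionization_mode = s$ionization_mode,
                               group = s$group, sex = s$sex,
                               run_order = s$run_order,
                               centroided = s$centroided))
  })
  names(mats) <- purrr::map_chr(samples, "sample_id")
  mats
}
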