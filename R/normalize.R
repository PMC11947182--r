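# Intra-sample drift and inter-sample scale correction.
#
# TIC normalization rescales each pixel so the summed intensity of the
# (annotated) features hits a common target. Sparse LOESS goes further: for
# every feature of every sample it fits a local polynomial trend of intensity
# against acquisition index using only the non-zero pixels, then divides the
# trend out and rescales to a per-feature reference pooled across samples --
# correcting within-run drift and between-run scale at once while leaving
# zeros untouched.

#' TIC-normalize a feature matrix
#'
#' Every pixel with a non-zero feature sum is scaled so that its sum equals
#' `target`; all-zero pixels are left unchanged.
#'
#' @param fm A [feature_matrix()], restricted to annotated features.
#' @param target Positive scalar the per-pixel sums are scaled to, default 1.
#' @return A [feature_matrix()].
#' @export
tic_normalize <- function(fm, target = 1) {
  assert_scalar_number(target, "target", lower = 0, strict_lower = TRUE)
  sums <- rowSums(fm$values)
  nz <- sums > 0
  values <- fm$values
  values[nz, ] <- values[nz, , drop = FALSE] * (target / sums[nz])
  feature_matrix(values, fm$pixels, fm$mz, fm$sample_id, fm$meta,
                 fm$annotation)
}

#' Sparse LOESS drift normalization across samples
#'
#' Per feature and per sample, a locally weighted polynomial regression of
#' log intensity against acquisition index is fitted on the non-zero pixels
#' only; drift and detector response are multiplicative, so the trend is
#' estimated on the log scale and back-transformed, which also keeps the
#' fitted trend strictly positive at sharp tissue/matrix transitions. The
#' span is chosen so the smoothing window covers `span_fraction` of the
#' sample's total pixel count (clamped to the fit's minimum of `degree + 2`
#' support points, and to 1). Normalized intensity is
#' `raw / max(trend, eps) * reference`, where the reference is the median of
#' that feature's non-zero intensities pooled over all samples and
#' `eps = 1e-8 * reference` is a numerical guard. Zero pixels stay exactly
#' zero; features with fewer non-zero pixels than the minimum window pass
#' through unchanged and are logged.
#'
#' @param matrices List of [feature_matrix()] objects sharing one feature axis.
#' @param span_fraction Window size as a fraction of the sample's total pixel
#'   count, in (0, 1]; default 0.10.
#' @param degree Local polynomial degree, default 2.
#' @return List with `matrices` (normalized, same order), `fits` (tibble of
#'   per sample x feature fits: `sample_id`, `mz`, `span`, `n_support`,
#'   `reference`, plus list columns `support` and `fitted`) and `skipped`
#'   (tibble logging pass-through features).
#' @export
sparse_loess_normalize <- function(matrices, span_fraction = 0.10,
                                   degree = 2) {
  assert_scalar_number(span_fraction, "span_fraction", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (inherits(matrices, "feature_matrix")) matrices <- list(matrices)
  check_shared_axis(matrices)
  mz <- matrices[[1]]$mz
  min_pts <- degree + 2

  # per-feature reference: pooled median of non-zero raw intensities
  references <- vapply(seq_along(mz), function(j) {
    pooled <- unlist(purrr::map(matrices, ~ {
      v <- .x$values[, j]
      v[v > 0]
    }), use.names = FALSE)
    if (length(pooled) == 0L) NA_real_ else stats::median(pooled)
  }, numeric(1))

  fits <- list()
  skipped <- list()
  out <- purrr::map(matrices, function(fm) {
    values <- fm$values
    n_total <- nrow(values)
    x_all <- fm$pixels$acquisition_index
    for (j in seq_along(mz)) {
      y <- values[, j]
      nz <- which(y > 0)
      ref <- references[j]
      if (length(nz) < min_pts || is.na(ref)) {
        skipped[[length(skipped) + 1L]] <<- tibble::tibble(
          sample_id = fm$sample_id, mz = mz[j], n_support = length(nz),
          reason = "fewer non-zero pixels than the minimum window")
        next
      }
      span <- min(1, max(span_fraction * n_total, min_pts) / length(nz))
      x <- x_all[nz]
      ly <- log(y[nz])
      fit <- tryCatch(
        stats::loess(ly ~ x, span = span, degree = degree,
                     family = "gaussian"),
        error = function(e) NULL)
      if (is.null(fit)) {
        skipped[[length(skipped) + 1L]] <<- tibble::tibble(
          sample_id = fm$sample_id, mz = mz[j], n_support = length(nz),
          reason = "local regression failed")
        next
      }
      f <- exp(stats::fitted(fit))
      eps <- 1e-8 * ref
      values[nz, j] <- y[nz] / pmax(f, eps) * ref
      fits[[length(fits) + 1L]] <<- tibble::tibble(
        sample_id = fm$sample_id, mz = mz[j], span = span,
        n_support = length(nz), reference = ref,
        support = list(x), fitted = list(unname(f)))
    }
    feature_matrix(values, fm$pixels, mz, fm$sample_id, fm$meta,
                   fm$annotation)
  })
  names(out) <- names(matrices)
  skipped <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(sample_id = character(), mz = double(),
                   n_support = integer(), reason = character())
  if (nrow(skipped) > 0L) {
    rlang::inform(sprintf(
      "sparse LOESS: %d sample x feature series passed through unchanged",
      nrow(skipped)))
  }
  list(matrices = out,
       fits = if (length(fits)) dplyr::bind_rows(fits) else NULL,
       skipped = skipped)
}

check_shared_axis <- function(matrices) {
  if (length(matrices) == 0L) rlang::abort("no matrices given")
  axes <- purrr::map(matrices, "mz")
  same <- purrr::map_lgl(axes, ~ identical(.x, axes[[1]]))
  if (!all(same)) rlang::abort("matrices do not share one feature axis")
  invisible(TRUE)
}

#' Drift and scale diagnostics for matched matrix sets
#'
#' For every sample in every named normalization set, reports the OLS slope
#' of per-pixel TIC against acquisition index (non-zero-TIC pixels only), the
#' median non-zero TIC, and the relative slope -- the fitted fractional TIC
#' change across the whole acquisition, `slope * n_pixels / median_tic`,
#' which is comparable between normalizations whose output levels differ.
#' [glance()] summarises each set with the inter-sample relative range of
#' median TIC, `(max - min) / median`.
#'
#' @param ... Named lists of [feature_matrix()] objects, e.g.
#'   `raw = mats, tic = mats_tic, loess = mats_loess`. Each set is computed
#'   identically.
#' @return Tibble of class `drift_report` with columns `normalization`,
#'   `sample_id`, `n_pixels`, `n_nonzero`, `slope`, `median_tic`.
#' @export
drift_report <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.null(names(sets))) names(sets) <- "raw"
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    rlang::abort("drift_report() arguments must be named, e.g. raw = , loess = ")
  }
  rows <- purrr::imap(sets, function(mats, set_name) {
    if (inherits(mats, "feature_matrix")) mats <- list(mats)
    dplyr::bind_rows(purrr::map(mats, function(fm) {
      tic <- rowSums(fm$values)
      idx <- fm$pixels$acquisition_index
      nz <- tic > 0
      slope <- ols_slope(idx[nz], tic[nz])
      med <- stats::median(tic[nz])
      tibble::tibble(
        normalization = set_name,
        sample_id = fm$sample_id,
        n_pixels = length(tic),
        n_nonzero = sum(nz),
        slope = slope,
        median_tic = med,
        relative_slope = slope * length(tic) / med
      )
    }))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("drift_report", class(out))
  out
}

#' @rdname drift_report
#' @param x A `drift_report`.
#' @method glance drift_report
#' @export
glance.drift_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$normalization),
    n_samples = dplyr::n(),
    mean_abs_slope = mean(abs(.data$slope)),
    mean_abs_relative_slope = mean(abs(.data$relative_slope)),
    relative_range_median_tic =
      (max(.data$median_tic) - min(.data$median_tic)) /
      stats::median(.data$median_tic),
    .groups = "drop"
  )
}

#' @method tidy drift_report
#' @export
tidy.drift_report <- function(x, ...) tibble::as_tibble(x)
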