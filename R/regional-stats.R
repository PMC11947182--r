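# Region-level differential statistics across biological replicates:
# per-region per-lipid mean pixel abundance (log2), one-way ANOVA over the
# sex x treatment cells with Tukey HSD contrasts, a volcano rule
# (p < 0.05, |log2 FC| > 0.5), and lipid-class enrichment by one-sided
# two-sample Kolmogorov-Smirnov tests with Benjamini-Hochberg FDR.

#' Summarise lipid abundance per sample and region
#'
#' For every (sample, region, lipid): the number of pixels, the mean intensity
#' over ALL pixels of the region (zeros included), and its log2 -- the
#' log-transformed per-pixel average used by the downstream tests. Regions
#' absent from a sample simply yield no record; all-zero region x lipid cells
#' get a missing `log2_mean` and are excluded from tests.
#'
#' @param matrices List of (normalized) [feature_matrix()] objects.
#' @param regions Region assignment: the output of [assign_regions()] for each
#'   sample, either as one combined tibble (with `sample_id`) or a list.
#' @param annotations Optional `lipid_annotations`; when present (or attached
#'   to the matrices) only annotated features enter the summary and lipid
#'   name/class/saturation columns are carried along.
#' @return Tibble of class `region_lipid_summary`: `sample_id`, `group`,
#'   `sex`, `region`, `mz`, `lipid`, `lipid_class`, `double_bonds`,
#'   `saturation`, `pixel_count`, `mean_intensity`, `log2_mean`.
#' @export
summarize_regions <- function(matrices, regions, annotations = NULL) {
  if (inherits(matrices, "feature_matrix")) matrices <- list(matrices)
  if (is.data.frame(regions)) {
    regions <- split(regions, regions$sample_id)
  }
  rows <- purrr::map(matrices, function(fm) {
    reg <- regions[[fm$sample_id]]
    if (is.null(reg)) {
      rlang::abort(sprintf("no region assignment for sample '%s'",
                           fm$sample_id))
    }
    ann <- annotations %||% fm$annotation
    keep <- seq_along(fm$mz)
    if (!is.null(ann)) keep <- which(fm$mz %in% ann$feature_mz)
    if (length(keep) == 0L) {
      rlang::abort("no annotated features present in the matrix")
    }
    region_of <- reg$region[match(fm$pixels$acquisition_index,
                                  reg$acquisition_index)]
    if (anyNA(region_of)) {
      rlang::abort(sprintf("region assignment does not cover sample '%s'",
                           fm$sample_id))
    }
    vals <- fm$values[, keep, drop = FALSE]
    counts <- as.vector(table(region_of))
    region_names <- names(table(region_of))
    means <- rowsum(vals, group = region_of) / counts

    lab <- annotation_lookup(ann, fm$mz[keep])
    purrr::map_dfr(seq_along(region_names), function(ri) {
      m <- unname(means[ri, ])
      tibble::tibble(
        sample_id = fm$sample_id,
        group = fm$meta$group %||% NA_character_,
        sex = fm$meta$sex %||% NA_character_,
        region = region_names[ri],
        mz = fm$mz[keep],
        lipid = lab$lipid,
        lipid_class = lab$lipid_class,
        double_bonds = lab$double_bonds,
        saturation = lab$saturation,
        pixel_count = counts[ri],
        mean_intensity = m,
        log2_mean = ifelse(m > 0, log2(m), NA_real_)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("region_lipid_summary", class(out))
  out
}

annotation_lookup <- function(ann, mz) {
  if (is.null(ann) || nrow(ann) == 0L) {
    return(list(lipid = format_mz(mz), lipid_class = NA_character_,
                double_bonds = NA_integer_, saturation = NA_character_))
  }
  first <- ann[!duplicated(ann$feature_mz), ]
  idx <- match(mz, first$feature_mz)
  list(
    lipid = ifelse(is.na(idx), format_mz(mz), first$lipid_name[idx]),
    lipid_class = first$lipid_class[idx],
    double_bonds = first$total_double_bonds[idx],
    saturation = first$saturation[idx]
  )
}

#' One-way ANOVA with Tukey contrasts per region and lipid
#'
#' For each (region, lipid), fits a one-way ANOVA of `log2_mean` over the
#' design cells -- by default every sex x group combination present -- and
#' reports each pairwise Tukey HSD contrast with its studentized-range
#' adjusted p value and the difference of cell means as the log2 fold change.
#' Cells are ordered with `ref_group` first so contrasts read
#' "exposed - control". Lipids without at least two cells of `min_reps`
#' replicates are skipped and logged in the `"skipped"` attribute.
#'
#' @param summaries A `region_lipid_summary` tibble.
#' @param design `"cells"` (one-way over sex x group cells, the default) or
#'   `"pooled"` (groups only, sexes pooled).
#' @param ref_group Reference group placed first in the factor order,
#'   default `"control"` when present.
#' @param exclude_regions Regions dropped before testing.
#' @param min_reps Minimum replicates per cell, default 2.
#' @param conf_level Tukey confidence level, default 0.95.
#' @return Tibble of class `msi_differential`: `region`, `mz`, `lipid`,
#'   `lipid_class`, `saturation`, `contrast`, `log2_fc`, `f_statistic`,
#'   `p_value` (ANOVA omnibus), `tukey_adjusted_p`, `n_cells`, `n_obs`.
#' @export
differential_anova <- function(summaries, design = c("cells", "pooled"),
                               ref_group = "control",
                               exclude_regions = c("off_tissue", "unassigned"),
                               min_reps = 2, conf_level = 0.95) {
  design <- match.arg(design)
  df <- tibble::as_tibble(summaries)
  df <- df[!df$region %in% exclude_regions & !is.na(df$log2_mean), ]
  if (nrow(df) == 0L) rlang::abort("no testable records after filtering")

  df$cell <- if (design == "cells" && any(!is.na(df$sex)) &&
                 length(unique(df$sex)) > 1L) {
    paste(df$sex, df$group, sep = ":")
  } else if (design == "cells" && any(!is.na(df$sex))) {
    paste(df$sex, df$group, sep = ":")
  } else {
    df$group
  }
  # order cells so the reference group comes first within each sex block
  cell_levels <- sort(unique(df$cell))
  is_ref <- grepl(paste0("(^|:)", ref_group, "$"), cell_levels)
  cell_levels <- c(cell_levels[is_ref], cell_levels[!is_ref])

  skipped <- list()
  results <- list()
  groups <- dplyr::group_split(dplyr::group_by(df, .data$region, .data$mz))
  for (g in groups) {
    region <- g$region[1]; mz <- g$mz[1]
    tab <- table(g$cell)
    usable <- names(tab)[tab >= min_reps]
    if (length(usable) < 2L) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        region = region, mz = mz, lipid = g$lipid[1],
        reason = "fewer than 2 cells with enough replicates")
      next
    }
    gg <- g[g$cell %in% usable, ]
    gg$cell <- factor(gg$cell, levels = intersect(cell_levels, usable))
    an <- anova_with_tukey(gg$log2_mean, gg$cell, conf_level = conf_level)
    res <- an$contrasts
    res$region <- region
    res$mz <- mz
    res$lipid <- g$lipid[1]
    res$lipid_class <- g$lipid_class[1]
    res$saturation <- g$saturation[1]
    res$f_statistic <- an$f_statistic
    res$p_value <- an$p_value
    res$n_cells <- length(usable)
    res$n_obs <- nrow(gg)
    results[[length(results) + 1L]] <- res
  }
  out <- dplyr::bind_rows(results)
  if (nrow(out) > 0L) {
    out <- out[, c("region", "mz", "lipid", "lipid_class", "saturation",
                   "contrast", "log2_fc", "f_statistic", "p_value",
                   "tukey_adjusted_p", "n_cells", "n_obs")]
  }
  class(out) <- c("msi_differential", class(out))
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

# one-way ANOVA + Tukey HSD with guards for degenerate variance
anova_with_tukey <- function(y, cell, conf_level = 0.95) {
  cells <- levels(cell)
  pairs <- utils::combn(cells, 2L)
  contrast_names <- paste(pairs[2, ], pairs[1, ], sep = "-")
  means <- tapply(y, cell, mean)
  diffs <- means[pairs[2, ]] - means[pairs[1, ]]

  ss_total <- sum((y - mean(y))^2)
  ss_within <- sum((y - means[as.character(cell)])^2)
  if (ss_total < .Machine$double.eps * length(y)) {
    # all observations identical: no effect, no evidence
    return(list(f_statistic = 0, p_value = 1,
                contrasts = tibble::tibble(contrast = contrast_names,
                                           log2_fc = unname(diffs),
                                           tukey_adjusted_p = 1)))
  }
  if (ss_within < .Machine$double.eps * ss_total) {
    return(list(f_statistic = Inf, p_value = 0,
                contrasts = tibble::tibble(contrast = contrast_names,
                                           log2_fc = unname(diffs),
                                           tukey_adjusted_p = 0)))
  }
  fit <- stats::aov(y ~ cell, data = data.frame(y = y, cell = cell))
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$cell
  tk_p <- setNames(tk[, "p adj"], rownames(tk))
  list(
    f_statistic = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    contrasts = tibble::tibble(
      contrast = contrast_names,
      log2_fc = unname(diffs),
      tukey_adjusted_p = unname(tk_p[contrast_names])
    )
  )
}

#' Flag volcano-plot significance and effect size
#'
#' Adds `significant` (p below `p_cut`), `high_effect` (|log2 FC| strictly
#' above `lfc_cut`) and their conjunction `hit` to a differential table.
#'
#' @param results An `msi_differential` tibble.
#' @param p_cut P-value cutoff, default 0.05.
#' @param lfc_cut Absolute log2 fold-change cutoff, default 0.5 (strict
#'   inequality: exactly 0.5 is not a high effect).
#' @param p_col Which p value the rule uses, default `"tukey_adjusted_p"`.
#' @return The input with `significant`, `high_effect`, `hit` columns.
#' @export
classify_volcano <- function(results, p_cut = 0.05, lfc_cut = 0.5,
                             p_col = "tukey_adjusted_p") {
  results$significant <- results[[p_col]] < p_cut
  results$high_effect <- abs(results$log2_fc) > lfc_cut
  results$hit <- results$significant & results$high_effect
  results
}

#' @method glance msi_differential
#' @export
glance.msi_differential <- function(x, ...) {
  if (!"hit" %in% names(x)) x <- classify_volcano(x)
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$region, .data$contrast),
    n_lipids = dplyr::n(),
    n_significant = sum(.data$significant, na.rm = TRUE),
    n_hits = sum(.data$hit, na.rm = TRUE),
    .groups = "drop")
}

#' @method tidy msi_differential
#' @export
tidy.msi_differential <- function(x, ...) tibble::as_tibble(x)

#' Lipid-class enrichment by one-sided Kolmogorov-Smirnov tests
#'
#' Lipids are grouped into sets by class crossed with saturation
#' (e.g. "PE Unsat."); per region and contrast, each set's log2 fold changes
#' are compared against all non-member lipids with a two-sample one-sided KS
#' test in both directions ("increase": members stochastically larger;
#' "decrease": smaller), and Benjamini-Hochberg FDR is applied across all
#' set x direction tests within the region/contrast. Undersized sets are
#' skipped and logged in the `"skipped"` attribute.
#'
#' @param results An `msi_differential` tibble (one log2 FC per lipid after
#'   de-duplication within region/contrast).
#' @param min_set_size Minimum members per set, default 3.
#' @param saturated_max_db Double-bond cutoff for the saturation split when it
#'   must be derived from `double_bonds`, default 1.
#' @return Tibble of class `msi_enrichment`: `region`, `contrast`, `set_id`,
#'   `lipid_class`, `saturation`, `direction`, `n_set`, `n_background`,
#'   `ks_statistic`, `p_value`, `fdr_q`.
#' @export
ks_class_enrichment <- function(results, min_set_size = 3,
                                saturated_max_db = 1L) {
  df <- tibble::as_tibble(results)
  need <- c("region", "contrast", "lipid", "lipid_class", "log2_fc")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("results is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (!"saturation" %in% names(df)) {
    df$saturation <- classify_saturation(df$double_bonds, saturated_max_db)
  }
  df <- df[!is.na(df$log2_fc) & !is.na(df$lipid_class) &
             df$saturation %in% c("saturated", "unsaturated"), ]
  sat_label <- c(saturated = "Sat.", unsaturated = "Unsat.")
  df$set_id <- paste(df$lipid_class, sat_label[df$saturation])

  skipped <- list()
  blocks <- dplyr::group_split(dplyr::group_by(df, .data$region,
                                               .data$contrast))
  rows <- purrr::map(blocks, function(block) {
    block <- block[!duplicated(block$lipid), ]
    out <- purrr::map(unique(block$set_id), function(sid) {
      member <- block$log2_fc[block$set_id == sid]
      background <- block$log2_fc[block$set_id != sid]
      if (length(member) < min_set_size || length(background) == 0L) {
        skipped[[length(skipped) + 1L]] <<- tibble::tibble(
          region = block$region[1], contrast = block$contrast[1],
          set_id = sid, n_set = length(member), reason = "undersized set")
        return(NULL)
      }
      one <- function(direction) {
        alt <- if (direction == "increase") "less" else "greater"
        kt <- suppressWarnings(ks.test(member, background, alternative = alt))
        tibble::tibble(
          region = block$region[1], contrast = block$contrast[1],
          set_id = sid,
          lipid_class = block$lipid_class[block$set_id == sid][1],
          saturation = block$saturation[block$set_id == sid][1],
          direction = direction, n_set = length(member),
          n_background = length(background),
          ks_statistic = unname(kt$statistic), p_value = kt$p.value)
      }
      dplyr::bind_rows(one("increase"), one("decrease"))
    })
    out <- dplyr::bind_rows(out)
    if (nrow(out) > 0L) out$fdr_q <- stats::p.adjust(out$p_value, "BH")
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("msi_enrichment", class(out))
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

#' @method tidy msi_enrichment
#' @export
tidy.msi_enrichment <- function(x, ...) tibble::as_tibble(x)

#' @method glance msi_enrichment
#' @export
glance.msi_enrichment <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$region, .data$contrast),
    n_tests = dplyr::n(),
    n_enriched_05 = sum(.data$fdr_q < 0.05, na.rm = TRUE),
    .groups = "drop")
}
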