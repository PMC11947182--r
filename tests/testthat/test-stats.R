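# regional summaries, ANOVA/Tukey, volcano rule, KS class enrichment

make_summary <- function(values_by_cell, region = "alveolar_epithelium",
                         lipid = "PG 34:1", lipid_class = "PG",
                         saturation = "unsaturated", mz = 747.5) {
  rows <- purrr::imap(values_by_cell, function(vals, cell) {
    parts <- strsplit(cell, ":")[[1]]
    tibble::tibble(
      sample_id = paste0(cell, "_", seq_along(vals)),
      group = parts[length(parts)],
      sex = if (length(parts) == 2) parts[1] else NA_character_,
      region = region, mz = mz, lipid = lipid, lipid_class = lipid_class,
      double_bonds = NA_integer_, saturation = saturation,
      pixel_count = 10L, mean_intensity = 2^vals, log2_mean = vals)
  })
  dplyr::bind_rows(rows)
}

test_that("summarize_regions averages over all pixels, zeros included", {
  fm <- toy_feature_matrix(matrix(c(2, 4, 8, 16, 0, 0, 0, 0), ncol = 2),
                           group = "control", sex = "F")
  regions <- tibble::tibble(sample_id = "fm", x = 1:4, y = 1L,
                            acquisition_index = 1:4,
                            cluster = 1L, region = "alveolar_epithelium")
  out <- summarize_regions(list(fm), regions)
  expect_equal(out$mean_intensity[1], 7.5)      # mean of {2,4,8,16}
  expect_equal(out$log2_mean[1], log2(7.5), tolerance = 1e-10)
  expect_equal(round(out$log2_mean[1], 4), 2.9069)
  # all-zero region x lipid -> missing log2, excluded from tests
  expect_true(is.na(out$log2_mean[2]))
  expect_equal(out$pixel_count, c(4L, 4L))

  # single-pixel region: mean equals the pixel value
  regions2 <- regions
  regions2$region[1] <- "airway_epithelium"
  out2 <- summarize_regions(list(fm), regions2)
  one <- out2[out2$region == "airway_epithelium" & out2$mz == fm$mz[1], ]
  expect_equal(one$mean_intensity, 2)
})

test_that("one-way ANOVA matches the hand-computed F on the toy groups", {
  vals <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))
  summ <- make_summary(vals)
  res <- differential_anova(summ, min_reps = 2)
  # sums of squares by hand
  y <- unlist(vals); gm <- mean(y)
  means <- vapply(vals, mean, numeric(1))
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((y - rep(means, each = 3))^2)
  f_expected <- (ssb / 2) / (ssw / 6)
  expect_equal(unique(res$f_statistic), f_expected, tolerance = 1e-10)
  expect_equal(unique(res$p_value), pf(f_expected, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  # log2 fold changes are differences of cell means
  expect_setequal(round(res$log2_fc, 10),
                  round(c(means["g2"] - means["g1"], means["g3"] - means["g1"],
                          means["g3"] - means["g2"]), 10))
})

test_that("two-group ANOVA equals the equal-variance t-test (F = t^2)", {
  vals <- list(control = c(5.1, 4.8, 5.3), HDM_O3 = c(6.2, 6.8, 6.1))
  res <- differential_anova(make_summary(vals))
  tt <- t.test(vals$HDM_O3, vals$control, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  # with two groups the Tukey-adjusted p equals the omnibus p (up to the
  # numerical accuracy of the studentized-range quadrature)
  expect_equal(res$tukey_adjusted_p, res$p_value, tolerance = 1e-2)
  # contrast reads exposed - control
  expect_equal(res$contrast, "HDM_O3-control")
  expect_equal(res$log2_fc, mean(vals$HDM_O3) - mean(vals$control))
})

test_that("identical observations give F = 0, p = 1; F is shift-invariant", {
  res0 <- differential_anova(make_summary(list(a = c(2, 2), b = c(2, 2))))
  expect_equal(res0$f_statistic, 0)
  expect_equal(res0$p_value, 1)

  vals <- list(a = c(1, 2, 3), b = c(4, 6, 5))
  f1 <- differential_anova(make_summary(vals))$f_statistic[1]
  shifted <- purrr::map(vals, ~ .x + 100)
  f2 <- differential_anova(make_summary(shifted))$f_statistic[1]
  expect_equal(f1, f2, tolerance = 1e-9)

  # swapping contrast direction flips the sign of the fold change
  r1 <- differential_anova(make_summary(vals), ref_group = "a")
  r2 <- differential_anova(make_summary(vals), ref_group = "b")
  expect_equal(r1$log2_fc, -r2$log2_fc, tolerance = 1e-12)
})

test_that("insufficient replication is skipped with a reason", {
  summ <- make_summary(list(a = 1, b = c(2, 3)))  # one replicate in 'a'
  res <- differential_anova(summ)
  expect_equal(nrow(res), 0)
  expect_match(attr(res, "skipped")$reason, "replicates")
})

test_that("volcano thresholds: strict inequalities at both cutoffs", {
  res <- tibble::tibble(
    log2_fc = c(0.6, 2.0, 0.5, -0.8),
    tukey_adjusted_p = c(0.04, 0.06, 0.04, 0.01))
  out <- classify_volcano(res)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$high_effect, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$hit, c(TRUE, FALSE, FALSE, TRUE))
})

enrichment_input <- function(lfc, classes, saturation = "unsaturated") {
  tibble::tibble(
    region = "alveolar_epithelium", contrast = "HDM_O3-control",
    lipid = paste0("L", seq_along(lfc)), lipid_class = classes,
    saturation = saturation, log2_fc = lfc)
}

test_that("a 3-member set holding the 3 largest fold changes: KS stat 1, exact tail p", {
  lfc <- c(1:7 / 10, 5, 6, 7)  # members L8..L10 are the top 3
  classes <- c(rep("PC", 7), rep("PG", 3))
  out <- ks_class_enrichment(enrichment_input(lfc, classes))
  inc <- out[out$set_id == "PG Unsat." & out$direction == "increase", ]
  expect_equal(inc$ks_statistic, 1)
  # exact permutation tail: of C(10,3) member assignments, only one places
  # all members above every non-member
  perms <- utils::combn(10, 3)
  stat_of <- function(idx) {
    m <- lfc[idx]; b <- lfc[-idx]
    max(vapply(c(m, b), function(t) mean(m > t) - mean(b > t), numeric(1)))
  }
  observed <- stat_of(8:10)
  tail_p <- mean(apply(perms, 2, stat_of) >= observed - 1e-12)
  expect_equal(inc$p_value, tail_p, tolerance = 1e-10)
  expect_equal(tail_p, 1 / choose(10, 3), tolerance = 1e-12)
})

test_that("undersized sets are skipped and logged", {
  lfc <- rnorm(6)
  out <- ks_class_enrichment(enrichment_input(lfc, c(rep("PC", 4), "PG", "PG")))
  expect_false("PG Unsat." %in% out$set_id)
  expect_match(attr(out, "skipped")$reason, "undersized")
})

test_that("null KS enrichment p-values are uniform (calibration)", {
  withr::local_seed(1)
  n_reps <- 1000
  pvals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    lfc <- rnorm(100)
    classes <- c(rep("PE", 10), rep("PC", 90))  # set and background exchangeable
    out <- ks_class_enrichment(enrichment_input(lfc, classes))
    pvals[r] <- out$p_value[out$set_id == "PE Unsat." &
                              out$direction == "increase"]
  }
  rejection <- mean(pvals < 0.05)
  expect_gt(rejection, 0.03)
  expect_lt(rejection, 0.07)
  ks_unif <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks_unif$p.value, 0.01)
})

test_that("BH q-values are monotone in p-rank and bounded by 1", {
  withr::local_seed(3)
  lfc <- rnorm(40)
  classes <- rep(c("PC", "PE", "PG", "SM"), each = 10)
  out <- ks_class_enrichment(enrichment_input(lfc, classes))
  expect_true(all(out$fdr_q >= out$p_value - 1e-12))
  expect_true(all(out$fdr_q <= 1))
  ord <- order(out$p_value)
  expect_true(all(diff(out$fdr_q[ord]) >= -1e-12))
})
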