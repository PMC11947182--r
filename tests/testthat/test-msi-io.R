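# imzML round trips, sample invariants, and annotation library parsing

test_that("write -> read imzML is the identity on a continuous-mode sample", {
  s <- tiny_sample(n = 4, centroided = FALSE)
  path <- file.path(withr::local_tempdir(), "cont.imzML")
  write_imzml(s, path)
  back <- read_imzml(path, ionization_mode = "negative")
  expect_equal(back$spectra$x, s$spectra$x)
  expect_equal(back$spectra$y, s$spectra$y)
  expect_equal(back$spectra$acquisition_index, s$spectra$acquisition_index)
  expect_identical(back$spectra$mz, s$spectra$mz)
  expect_identical(back$spectra$intensity, s$spectra$intensity)
  expect_false(back$centroided)
})

test_that("processed-mode round trip preserves per-pixel axes and order", {
  mz_axes <- list(c(700.1, 710.2), c(650.5, 700.1, 810.9), 725.0)
  ints <- list(c(5, 6), c(1, 2, 3), 9)
  s <- tiny_sample(n = 3, mz_axes = mz_axes, intensities = ints)
  path <- file.path(withr::local_tempdir(), "proc.imzML")
  write_imzml(s, path)
  back <- read_imzml(path, ionization_mode = "negative")
  expect_identical(lengths(back$spectra$mz), lengths(s$spectra$mz))
  expect_identical(back$spectra$mz, s$spectra$mz)
  expect_identical(back$spectra$intensity, s$spectra$intensity)
  expect_equal(back$spectra$acquisition_index, 1:3)
  expect_true(back$centroided)
})

test_that("generator output survives an imzML round trip bit-exactly", {
  gen <- small_dataset()
  s <- gen$samples[[1]]
  # down-sample pixels for the file round trip, reindexing acquisition order
  sp <- s$spectra[1:25, ]
  sp$acquisition_index <- order(sp$acquisition_index)
  small <- msi_sample(sp, "sub", s$ionization_mode, centroided = TRUE)
  path <- file.path(withr::local_tempdir(), "gen.imzML")
  write_imzml(small, path)
  back <- read_imzml(path, ionization_mode = s$ionization_mode)
  expect_identical(back$spectra$mz, small$spectra$mz)
  expect_identical(back$spectra$intensity, small$spectra$intensity)
})

test_that("missing ibd and degenerate writes raise clear errors", {
  s <- tiny_sample()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "noibd.imzML")
  write_imzml(s, path)
  file.remove(sub("\\.imzML$", ".ibd", path))
  expect_error(read_imzml(path), "\\.ibd")

  empty <- s
  empty$spectra$mz <- list(double(), double(), double())
  empty$spectra$intensity <- list(double(), double(), double())
  expect_error(write_imzml(empty, file.path(dir, "e.imzML")), "no spectra")
})

test_that("sample invariants are enforced", {
  s <- tiny_sample()
  dup <- s$spectra
  dup$x[2] <- dup$x[1]; dup$y[2] <- dup$y[1]
  expect_error(msi_sample(dup, "d", "negative"), "duplicate")

  perm <- s$spectra
  perm$acquisition_index <- c(1L, 1L, 2L)
  expect_error(msi_sample(perm, "p", "negative"), "permutation")

  neg <- s$spectra
  neg$intensity[[1]][1] <- -1
  expect_error(msi_sample(neg, "n", "negative"), "non-negative")

  unsorted <- s$spectra
  unsorted$mz[[1]] <- rev(unsorted$mz[[1]])
  expect_error(msi_sample(unsorted, "u", "negative"), "increasing")
})

test_that("pyimzml reads files we write (independent cross-check)", {
  s <- tiny_sample(n = 3, centroided = FALSE)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "x.imzML")
  write_imzml(s, path)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "for i, (x, y, z) in enumerate(p.coordinates):",
    "    mz, ints = p.getspectrum(i)",
    "    print(x, y, ','.join('%.6f' % v for v in mz),",
    "          ','.join('%.6f' % v for v in ints))"
  ), script)
  out <- system2("python", c(script, path), stdout = TRUE)
  expect_length(out, 3)
  fields <- strsplit(out[2], " +")[[1]]
  expect_equal(as.integer(fields[1:2]), c(s$spectra$x[2], s$spectra$y[2]))
  expect_equal(as.numeric(strsplit(fields[3], ",")[[1]]), s$spectra$mz[[2]],
               tolerance = 1e-6)
  expect_equal(as.numeric(strsplit(fields[4], ",")[[1]]),
               s$spectra$intensity[[2]], tolerance = 1e-6)
})

test_that("lipid shorthand parsing follows the sum rule", {
  p <- parse_lipid_shorthand(c("PE 18:0/22:6", "SM 44:1", "PC 32:0",
                               "FA 22:6", "junk name", "XX 10:1"))
  expect_equal(p$lipid_class[1:4], c("PE", "SM", "PC", "FA"))
  expect_equal(p$total_carbons[1:2], c(40L, 44L))
  expect_equal(p$total_double_bonds[1:4], c(6L, 1L, 0L, 6L))
  expect_true(all(p$parsed[1:4]))
  expect_false(any(p$parsed[5:6]))  # unknown class token falls back too
})

test_that("annotation library loading: parsing, fallback, duplicates, empty", {
  lib <- toy_library()
  expect_s3_class(lib, "annotation_library")
  expect_equal(nrow(lib), 7)
  expect_equal(lib$total_carbons[lib$lipid_name == "PE 18:0/22:6"], 40L)

  dir <- withr::local_tempdir()
  # unparseable name keeps explicit class column, with a warning
  odd <- tibble::tibble(name = c("PC 32:0", "unknown lipid A"),
                        class = c("PC", "Cer"),
                        mz = c(734.569, 600.5), mode = "positive")
  f <- file.path(dir, "odd.csv"); readr::write_csv(odd, f, progress = FALSE)
  expect_warning(lib2 <- load_annotation_library(f), "grammar")
  expect_equal(lib2$lipid_class, c("PC", "Cer"))
  expect_true(is.na(lib2$total_carbons[2]))

  # duplicates dropped with a warning
  dup <- odd[c(1, 1), ]
  f <- file.path(dir, "dup.csv"); readr::write_csv(dup, f, progress = FALSE)
  expect_warning(lib3 <- load_annotation_library(f), "duplicate")
  expect_equal(nrow(lib3), 1)

  # empty table -> empty library plus warning
  f <- file.path(dir, "empty.csv")
  readr::write_csv(odd[0, ], f, progress = FALSE)
  expect_warning(lib4 <- load_annotation_library(f), "empty")
  expect_equal(nrow(lib4), 0)

  # missing required column -> schema error naming it
  bad <- odd[, c("name", "class", "mode")]
  f <- file.path(dir, "bad.csv"); readr::write_csv(bad, f, progress = FALSE)
  expect_error(load_annotation_library(f), "'mz'")
})
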