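# Lipid annotation library: an LC-MS/MS-validated table of observed-species
# m/z values per ionization mode, with lipid shorthand parsed into class /
# total carbons / total double bonds.

#' Lipid classes recognised by the shorthand parser
#' @export
lipid_classes <- c("FA", "AC", "CL", "Cer", "CE", "DhSM", "HexCer",
                   "LPC", "LPE", "LPG", "LPI", "SM",
                   "PA", "PC", "PE", "PG", "PI", "PS", "TG")

# glycerophospholipid classes (incl. lyso forms); used for class summaries
glycerophospholipid_classes <- c("PA", "PC", "PE", "PG", "PI", "PS",
                                 "LPC", "LPE", "LPG", "LPI", "CL")

#' Parse lipid shorthand names
#'
#' Understands `"CLASS C:D"` (total carbons:double bonds, e.g. `"SM 44:1"`)
#' and per-chain forms `"CLASS A:B/C:D"` or `"CLASS A:B_C:D"`
#' (e.g. `"PE 18:0/22:6"`), where carbons and double bonds are summed over
#' chains. Names whose class token is not a recognised lipid class, or that do
#' not match the grammar, are returned unparsed.
#'
#' @param names Character vector of lipid shorthand names.
#' @return Tibble with columns `lipid_name`, `lipid_class`, `total_carbons`,
#'   `total_double_bonds`, `parsed`.
#' @export
parse_lipid_shorthand <- function(names) {
  pattern <- "^([A-Za-z][A-Za-z0-9]*)[ ](\\d+):(\\d+)((?:[/_]\\d+:\\d+)*)$"
  m <- regmatches(names, regexec(pattern, names))
  rows <- purrr::map2(names, m, function(nm, parts) {
    if (length(parts) == 0L || !parts[2] %in% lipid_classes) {
      return(tibble::tibble(lipid_name = nm, lipid_class = NA_character_,
                            total_carbons = NA_integer_,
                            total_double_bonds = NA_integer_, parsed = FALSE))
    }
    carbons <- as.integer(parts[3])
    dbs <- as.integer(parts[4])
    extra <- parts[5]
    if (nzchar(extra)) {
      chain <- regmatches(extra, gregexpr("(\\d+):(\\d+)", extra))[[1]]
      for (ch in chain) {
        cd <- as.integer(strsplit(ch, ":", fixed = TRUE)[[1]])
        carbons <- carbons + cd[1]
        dbs <- dbs + cd[2]
      }
    }
    tibble::tibble(lipid_name = nm, lipid_class = parts[2],
                   total_carbons = carbons, total_double_bonds = dbs,
                   parsed = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Load a lipid annotation library
#'
#' Reads a CSV/TSV table of LC-MS/MS-validated lipids (name, class, adduct
#' m/z, ionization mode) and parses shorthand names into class, total carbons
#' and total double bonds. Rows that fail the shorthand grammar are retained
#' with the class taken from the explicit class column (a warning counts
#' them); duplicate (name, mode, m/z) rows are dropped with a warning so the
#' library invariant holds.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` table.
#' @param columns Named list mapping the required fields `name`, `class`,
#'   `mz`, `mode` (and optional `source`) to the header names in the file.
#' @return A tibble of class `annotation_library` with columns `lipid_name`,
#'   `lipid_class`, `total_carbons`, `total_double_bonds`, `expected_mz`,
#'   `ionization_mode`, `source`, `parsed`.
#' @export
load_annotation_library <- function(path,
                                    columns = list(name = "name",
                                                   class = "class",
                                                   mz = "mz",
                                                   mode = "mode",
                                                   source = "source")) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("name", "class", "mz", "mode")
  for (field in required) {
    col <- columns[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      rlang::abort(sprintf(
        "annotation library is missing required column '%s' (field '%s')",
        col %||% field, field))
    }
  }
  if (nrow(raw) == 0L) {
    rlang::warn("annotation library is empty")
    out <- tibble::tibble(lipid_name = character(), lipid_class = character(),
                          total_carbons = integer(),
                          total_double_bonds = integer(),
                          expected_mz = double(), ionization_mode = character(),
                          source = character(), parsed = logical())
    return(as_annotation_library(out))
  }

  parsed <- parse_lipid_shorthand(as.character(raw[[columns$name]]))
  n_fallback <- sum(!parsed$parsed)
  if (n_fallback > 0L) {
    rlang::warn(sprintf(
      "%d row(s) did not match the lipid shorthand grammar; class taken from the '%s' column",
      n_fallback, columns$class))
    parsed$lipid_class[!parsed$parsed] <-
      as.character(raw[[columns$class]])[!parsed$parsed]
  }

  out <- parsed
  out$expected_mz <- as.numeric(raw[[columns$mz]])
  out$ionization_mode <- normalize_mode(raw[[columns$mode]])
  src_col <- columns$source
  out$source <- if (!is.null(src_col) && src_col %in% names(raw)) {
    as.character(raw[[src_col]])
  } else NA_character_

  if (any(!is.finite(out$expected_mz)) || any(out$expected_mz <= 0)) {
    rlang::abort("library expected m/z values must be positive numbers")
  }

  dup <- duplicated(out[c("lipid_name", "ionization_mode", "expected_mz")])
  if (any(dup)) {
    rlang::warn(sprintf("dropping %d duplicate library row(s)", sum(dup)))
    out <- out[!dup, ]
  }
  as_annotation_library(out)
}

as_annotation_library <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- c("annotation_library", class(x))
  x
}
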