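#' Well roles recognised on a screening plate
#'
#' Six roles cover the plate design: mitogen-rich growth-medium negative
#' controls (`GM_NEG_CONTROL`), differentiation-medium-plus-insulin
#' positive controls (`DM_I_POS_CONTROL`), mock transfections (`MOCK`),
#' universal (non-targeting) siRNA controls (`UNIVERSAL_CONTROL`), the
#' Kif11 positive knockdown control (`KIF11_CONTROL`), and library
#' knockdown wells (`EXPERIMENTAL`).
#'
#' @return character vector of the recognised role labels.
#' @export
well_roles <- function() {
  c("GM_NEG_CONTROL", "DM_I_POS_CONTROL", "MOCK",
    "UNIVERSAL_CONTROL", "KIF11_CONTROL", "EXPERIMENTAL")
}

#' Screen arms
#' @return character vector of the two treatment arms.
#' @export
screen_arms <- function() c("vehicle", "sensitizer")

plate_rows <- function() LETTERS[1:16]
plate_cols <- function() 1:24

#' All valid 384-well coordinates
#'
#' Row letter A--P followed by column number 1--24, e.g. `"A1"`, `"P24"`.
#'
#' @param order `"row"` for row-major (A1, A2, ...) or `"column"` for
#'   column-major (A1, B1, ...) ordering.
#' @return character vector of 384 coordinates.
#' @export
well_coordinates <- function(order = c("column", "row")) {
  order <- match.arg(order)
  if (order == "column") {
    as.vector(outer(plate_rows(), plate_cols(), paste0))
  } else {
    as.vector(t(outer(plate_rows(), plate_cols(), paste0)))
  }
}

parse_well <- function(well) {
  row <- substr(well, 1, 1)
  col <- suppressWarnings(as.integer(substring(well, 2)))
  ok <- row %in% plate_rows() & !is.na(col) & col >= 1 & col <= 24 &
    substring(well, 2) == as.character(col)
  list(row = row, col = col, valid = ok)
}

#' Construct a kinase library
#'
#' The ordered set of gene symbols targeted by the siRNA library.
#' Symbols are stored exactly as given; uniqueness is enforced after
#' case-insensitive normalization.
#'
#' @param genes character vector of gene symbols.
#' @param pool_ids optional character vector of siRNA pool identifiers,
#'   one per gene.
#' @return an object of class `kinase_library`.
#' @export
kinase_library <- function(genes, pool_ids = NULL) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop_format("a kinase library needs at least one gene")
  if (anyNA(genes) || any(trimws(genes) == "")) {
    stop_format("kinase library gene symbols must be non-missing and non-empty")
  }
  if (anyDuplicated(norm_symbol(genes))) {
    dup <- genes[duplicated(norm_symbol(genes))][1]
    stop_format("duplicate gene symbol in library (case-insensitive): '%s'", dup)
  }
  if (!is.null(pool_ids) && length(pool_ids) != length(genes)) {
    stop_format("pool_ids must have one entry per gene")
  }
  structure(list(genes = genes, pool_ids = pool_ids), class = "kinase_library")
}

#' @export
length.kinase_library <- function(x) length(x$genes)

#' @export
print.kinase_library <- function(x, ...) {
  cat(sprintf("<kinase_library> %d genes (%s ... %s)\n",
              length(x$genes), x$genes[1], x$genes[length(x$genes)]))
  invisible(x)
}

#' Synthetic kinase library
#'
#' Generates a library of placeholder gene symbols (`KIN001`,
#' `KIN002`, ...) sized like the screened mouse kinome. Useful for
#' simulations when no annotation table is at hand; the symbols are
#' synthetic and carry no biological meaning.
#'
#' @param n number of genes (default 571, the screened kinome size).
#' @param prefix symbol prefix.
#' @return a [kinase_library()].
#' @export
synthetic_kinase_library <- function(n = 571, prefix = "KIN") {
  kinase_library(sprintf("%s%03d", prefix, seq_len(n)))
}

#' Read a kinase library table
#'
#' One- or two-column CSV: `gene_symbol[, sirna_pool_id]`.
#'
#' @param path CSV file path.
#' @return a [kinase_library()].
#' @export
read_library_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = "", progress = FALSE)
  if (!"gene_symbol" %in% names(df)) {
    stop_format("library table is missing required column 'gene_symbol'")
  }
  kinase_library(df$gene_symbol,
                 pool_ids = if ("sirna_pool_id" %in% names(df)) df$sirna_pool_id)
}

#' The two-plate screen layout
#'
#' Per-plate role counts matching the screen design: 32 GM and 32 DM+I
#' control wells on each plate; 32 (plate 1) or 37 (plate 2) further
#' control wells split across mock, universal and Kif11 controls; and
#' 288 or 283 experimental wells, together covering a 571-gene library
#' on two 384-well plates.
#'
#' @return named list of per-plate named role-count vectors.
#' @export
default_screen_layout <- function() {
  list(
    plate1 = c(GM_NEG_CONTROL = 32L, DM_I_POS_CONTROL = 32L, MOCK = 12L,
               UNIVERSAL_CONTROL = 10L, KIF11_CONTROL = 10L, EXPERIMENTAL = 288L),
    plate2 = c(GM_NEG_CONTROL = 32L, DM_I_POS_CONTROL = 32L, MOCK = 13L,
               UNIVERSAL_CONTROL = 12L, KIF11_CONTROL = 12L, EXPERIMENTAL = 283L)
  )
}

screen_data_columns <- function() {
  c("plate_id", "well", "role", "target_gene", "arm", "replicate",
    "site_index", "total_nuclei", "myogenin_pos_nuclei")
}

#' Assemble and validate a screen dataset
#'
#' The central container: a long tibble with one row per imaged site,
#' annotated with plate, well coordinate, well role, target gene, arm
#' and replicate, plus the kinase library and free-form provenance
#' metadata. Validation enforces the per-record invariants (counts
#' non-negative, Myogenin-positive nuclei never exceeding total nuclei,
#' valid 384-well coordinates, known roles and arms, experimental wells
#' carrying a library gene and control wells carrying none).
#'
#' Layout-level expectations (role counts per plate, replicate
#' completeness) are checked separately by [validate_layout()] so that
#' partial datasets remain representable.
#'
#' @param data tibble/data.frame with columns `plate_id`, `well`,
#'   `role`, `target_gene`, `arm`, `replicate`, `site_index`,
#'   `total_nuclei`, `myogenin_pos_nuclei` (one row per site).
#' @param library a [kinase_library()].
#' @param metadata named list of provenance (seed, generator config,
#'   source file, ...).
#' @return an object of class `screen_dataset`.
#' @export
screen_dataset <- function(data, library, metadata = list()) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(screen_data_columns(), names(data))
  if (length(missing) > 0) {
    stop_format("screen data is missing required column%s: %s",
                if (length(missing) > 1) "s" else "", paste(missing, collapse = ", "))
  }
  if (!inherits(library, "kinase_library")) {
    stop_format("'library' must be a kinase_library")
  }
  data <- data[screen_data_columns()]
  data$plate_id <- as.character(data$plate_id)
  data$well <- as.character(data$well)
  data$role <- as.character(data$role)
  data$target_gene <- as.character(data$target_gene)
  data$arm <- as.character(data$arm)
  data$replicate <- as_int_checked(data$replicate, "replicate")
  data$site_index <- as_int_checked(data$site_index, "site_index")
  data$total_nuclei <- as_int_checked(data$total_nuclei, "total_nuclei")
  data$myogenin_pos_nuclei <- as_int_checked(data$myogenin_pos_nuclei,
                                             "myogenin_pos_nuclei")

  problems <- validate_screen_data(data, library)
  if (length(problems) > 0) {
    stop_format("invalid screen data:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  structure(list(data = data, library = library, metadata = metadata),
            class = "screen_dataset")
}

validate_screen_data <- function(data, library) {
  problems <- character()
  site_tag <- function(i) {
    sprintf("plate %s well %s site %s", data$plate_id[i], data$well[i],
            data$site_index[i])
  }

  bad_role <- which(!data$role %in% well_roles())
  if (length(bad_role) > 0) {
    problems <- c(problems, sprintf("unknown role '%s' (%s)",
                                    data$role[bad_role[1]], site_tag(bad_role[1])))
  }
  bad_arm <- which(!data$arm %in% screen_arms())
  if (length(bad_arm) > 0) {
    problems <- c(problems, sprintf("unknown arm '%s' (%s)",
                                    data$arm[bad_arm[1]], site_tag(bad_arm[1])))
  }
  coord <- parse_well(data$well)
  bad_coord <- which(!coord$valid)
  if (length(bad_coord) > 0) {
    problems <- c(problems,
                  sprintf("invalid 384-well coordinate '%s' on plate %s",
                          data$well[bad_coord[1]], data$plate_id[bad_coord[1]]))
  }
  bad_rep <- which(is.na(data$replicate) | data$replicate < 1)
  if (length(bad_rep) > 0) {
    problems <- c(problems, sprintf("replicate index must be >= 1 (%s)",
                                    site_tag(bad_rep[1])))
  }
  bad_count <- which(is.na(data$total_nuclei) | data$total_nuclei < 0 |
                       is.na(data$myogenin_pos_nuclei) | data$myogenin_pos_nuclei < 0)
  if (length(bad_count) > 0) {
    problems <- c(problems, sprintf("nuclei counts must be non-negative integers (%s)",
                                    site_tag(bad_count[1])))
  }
  bad_excess <- which(!is.na(data$total_nuclei) & !is.na(data$myogenin_pos_nuclei) &
                        data$myogenin_pos_nuclei > data$total_nuclei)
  for (i in utils::head(bad_excess, 3)) {
    problems <- c(problems,
                  sprintf("myogenin_pos_nuclei (%d) exceeds total_nuclei (%d) at %s",
                          data$myogenin_pos_nuclei[i], data$total_nuclei[i], site_tag(i)))
  }

  gene_needed <- data$role %in% c("EXPERIMENTAL", "KIF11_CONTROL")
  missing_gene <- which(data$role == "EXPERIMENTAL" &
                          (is.na(data$target_gene) | trimws(data$target_gene) == ""))
  if (length(missing_gene) > 0) {
    problems <- c(problems, sprintf("EXPERIMENTAL well without target_gene (%s)",
                                    site_tag(missing_gene[1])))
  }
  stray_gene <- which(!gene_needed & !is.na(data$target_gene) &
                        trimws(data$target_gene) != "")
  if (length(stray_gene) > 0) {
    problems <- c(problems,
                  sprintf("control well of role %s carries a target_gene (%s)",
                          data$role[stray_gene[1]], site_tag(stray_gene[1])))
  }
  exp_genes <- data$target_gene[data$role == "EXPERIMENTAL"]
  exp_genes <- exp_genes[!is.na(exp_genes)]
  unknown <- setdiff(unique(norm_symbol(exp_genes)), norm_symbol(library$genes))
  if (length(unknown) > 0) {
    problems <- c(problems, sprintf("experimental target gene(s) not in library: %s",
                                    paste(utils::head(unknown, 5), collapse = ", ")))
  }

  key <- paste(data$plate_id, data$arm, data$replicate, data$well, data$site_index)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    problems <- c(problems, sprintf("duplicate site record (%s, arm %s, replicate %s)",
                                    site_tag(i), data$arm[i], data$replicate[i]))
  }
  problems
}

#' @export
print.screen_dataset <- function(x, ...) {
  wells <- dplyr::distinct(x$data, .data$plate_id, .data$arm, .data$replicate,
                           .data$well)
  cat(sprintf(paste0("<screen_dataset> %d site records, %d wells, ",
                     "%d library genes, plates: %s\n"),
              nrow(x$data), nrow(wells), length(x$library),
              paste(unique(x$data$plate_id), collapse = ", ")))
  invisible(x)
}

screen_csv_col_types <- function() {
  readr::cols(
    plate_id = readr::col_character(),
    well = readr::col_character(),
    role = readr::col_character(),
    target_gene = readr::col_character(),
    arm = readr::col_character(),
    replicate = readr::col_integer(),
    site_index = readr::col_integer(),
    total_nuclei = readr::col_integer(),
    myogenin_pos_nuclei = readr::col_integer()
  )
}

#' Read a screen CSV
#'
#' Reads the one-row-per-site comma-separated export (UTF-8, header
#' required, empty string for missing target genes) and returns a
#' validated [screen_dataset()]. Row order in the file does not affect
#' the result beyond row order in the stored table; all analyses are
#' order-invariant.
#'
#' @param path CSV file path.
#' @param library a [kinase_library()] the experimental wells must
#'   belong to.
#' @param metadata optional provenance list; the source path is added.
#' @return a [screen_dataset()].
#' @export
read_screen_csv <- function(path, library, metadata = list()) {
  if (!file.exists(path)) stop_format("screen CSV not found: %s", path)
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = readr::col_character()),
                                  progress = FALSE))
  missing <- setdiff(screen_data_columns(), header)
  if (length(missing) > 0) {
    stop_format("screen CSV %s is missing required column%s: %s", path,
                if (length(missing) > 1) "s" else "", paste(missing, collapse = ", "))
  }
  data <- readr::read_csv(path, col_types = screen_csv_col_types(), na = "",
                          progress = FALSE)
  metadata$source_file <- metadata$source_file %||% path
  screen_dataset(data, library, metadata)
}

#' Write a screen CSV
#'
#' Emits one row per (well, site) in a deterministic order (plate, arm,
#' replicate, row, column, site), so repeated writes of the same dataset
#' are byte-identical. Missing target genes are written as empty fields.
#'
#' @param dataset a [screen_dataset()].
#' @param path output CSV path.
#' @return the input dataset, invisibly.
#' @export
write_screen_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "screen_dataset"))
  coord <- parse_well(dataset$data$well)
  ord <- order(dataset$data$plate_id, dataset$data$arm, dataset$data$replicate,
               coord$row, coord$col, dataset$data$site_index)
  readr::write_csv(dataset$data[ord, ], path, na = "", progress = FALSE)
  invisible(dataset)
}

#' Check a dataset against a declared plate layout
#'
#' Counts distinct wells per role on every physical plate (a library
#' plate in one arm and replicate) and compares them with the declared
#' per-plate role counts. Deviations are reported, not raised: the
#' report has one row per (plate, arm, replicate, role) whose observed
#' well count differs from the declared count, and is empty exactly
#' when the dataset matches the layout.
#'
#' @param dataset a [screen_dataset()].
#' @param layout_spec named list of per-plate named role-count vectors,
#'   as produced by [default_screen_layout()].
#' @return tibble with columns `plate_id`, `arm`, `replicate`, `role`,
#'   `expected`, `observed`; zero rows iff the dataset matches.
#' @export
validate_layout <- function(dataset, layout_spec = default_screen_layout()) {
  stopifnot(inherits(dataset, "screen_dataset"))
  wells <- dplyr::distinct(dataset$data, .data$plate_id, .data$arm,
                           .data$replicate, .data$well, .data$role)
  observed <- dplyr::count(wells, .data$plate_id, .data$arm, .data$replicate,
                           .data$role, name = "observed")
  plates <- dplyr::distinct(wells, .data$plate_id, .data$arm, .data$replicate)
  expected <- dplyr::bind_rows(lapply(names(layout_spec), function(pid) {
    counts <- layout_spec[[pid]]
    tibble::tibble(plate_id = pid, role = names(counts),
                   expected = as.integer(counts))
  }))
  grid <- dplyr::inner_join(plates, expected, by = "plate_id",
                            relationship = "many-to-many")
  # plates present in the data but absent from the declared layout count too
  stray <- dplyr::anti_join(plates, expected, by = "plate_id")
  report <- dplyr::full_join(grid, observed,
                             by = c("plate_id", "arm", "replicate", "role"))
  report$expected[is.na(report$expected)] <- 0L
  report$observed[is.na(report$observed)] <- 0L
  report <- report[report$expected != report$observed, , drop = FALSE]
  if (nrow(stray) > 0) {
    stray_counts <- dplyr::semi_join(observed, stray,
                                     by = c("plate_id", "arm", "replicate"))
    stray_counts$expected <- 0L
    report <- dplyr::bind_rows(report, stray_counts[, names(report)])
  }
  dplyr::arrange(tibble::as_tibble(report), .data$plate_id, .data$arm,
                 .data$replicate, .data$role)
}
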