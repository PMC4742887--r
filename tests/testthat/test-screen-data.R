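test_that("a minimal 4-site CSV reads into a one-well dataset", {
  lib <- kinase_library("Fyn")
  csv <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    plate_id = "p1", well = "C7", role = "EXPERIMENTAL", target_gene = "Fyn",
    arm = "vehicle", replicate = 1L, site_index = 1:4,
    total_nuclei = c(240L, 260L, 250L, 255L),
    myogenin_pos_nuclei = c(5L, 4L, 6L, 5L)), csv, na = "")
  ds <- read_screen_csv(csv, lib)
  expect_s3_class(ds, "screen_dataset")
  expect_equal(nrow(ds$data), 4)
  expect_equal(unique(ds$data$well), "C7")
  expect_equal(ds$metadata$source_file, csv)
})

test_that("record-level invariant violations are caught and located", {
  lib <- kinase_library("Fyn")
  bad <- tibble::tibble(
    plate_id = "p1", well = "C7", role = "EXPERIMENTAL", target_gene = "Fyn",
    arm = "vehicle", replicate = 1L, site_index = 1L,
    total_nuclei = 10L, myogenin_pos_nuclei = 12L)
  expect_error(screen_dataset(bad, lib), "exceeds total_nuclei.*well C7")
  expect_error(screen_dataset(dplyr::mutate(bad, myogenin_pos_nuclei = 1L,
                                            role = "WEIRD"), lib),
               "unknown role 'WEIRD'")
  expect_error(screen_dataset(dplyr::mutate(bad, myogenin_pos_nuclei = 1L,
                                            well = "Q5"), lib),
               "invalid 384-well coordinate")
  expect_error(screen_dataset(dplyr::mutate(bad, myogenin_pos_nuclei = 1L,
                                            target_gene = NA_character_), lib),
               "without target_gene")
  expect_error(screen_dataset(dplyr::mutate(bad, myogenin_pos_nuclei = 1L,
                                            role = "MOCK"), lib),
               "carries a target_gene")
})

test_that("missing CSV columns are reported by name", {
  csv <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(plate_id = "p1", well = "A1"), csv)
  expect_error(read_screen_csv(csv, kinase_library("Fyn")),
               "missing required columns.*role")
})

test_that("write then read is the identity on a simulated dataset", {
  sim <- small_sim(seed = 21)
  csv <- tempfile(fileext = ".csv")
  write_screen_csv(sim$dataset, csv)
  back <- read_screen_csv(csv, small_library())
  key <- function(d) dplyr::arrange(d$data, .data$plate_id, .data$arm,
                                    .data$replicate, .data$well,
                                    .data$site_index)
  expect_equal(key(back), key(sim$dataset))

  # repeated writes are byte-identical
  csv2 <- tempfile(fileext = ".csv")
  write_screen_csv(sim$dataset, csv2)
  expect_identical(readLines(csv), readLines(csv2))
})

test_that("row order of the input never changes the dataset", {
  sim <- small_sim(seed = 22)
  csv <- tempfile(fileext = ".csv")
  write_screen_csv(sim$dataset, csv)
  rows <- readLines(csv)
  shuffled <- c(rows[1], sample(rows[-1]))
  csv2 <- tempfile(fileext = ".csv")
  writeLines(shuffled, csv2)
  a <- read_screen_csv(csv, small_library())
  b <- read_screen_csv(csv2, small_library())
  key <- function(d) dplyr::arrange(d$data, .data$plate_id, .data$arm,
                                    .data$replicate, .data$well,
                                    .data$site_index)
  expect_equal(key(a), key(b))
  expect_equal(call_screen(a), call_screen(b))
})

test_that("layout validation reports exactly the deviations", {
  sim <- small_sim(seed = 23)
  expect_equal(nrow(validate_layout(sim$dataset, small_layout())), 0)

  # drop one GM well from one physical plate
  d <- sim$dataset$data
  gm_wells <- unique(d$well[d$role == "GM_NEG_CONTROL"])
  drop <- d$role == "GM_NEG_CONTROL" & d$well == gm_wells[1] &
    d$arm == "vehicle" & d$replicate == 1
  ds2 <- screen_dataset(d[!drop, ], small_library())
  report <- validate_layout(ds2, small_layout())
  expect_equal(nrow(report), 1)
  expect_equal(report$role, "GM_NEG_CONTROL")
  expect_equal(report$observed, report$expected - 1L)
})

test_that("experimental wells must target library genes, compared case-insensitively", {
  lib <- kinase_library(c("Src", "Fyn"))
  row <- tibble::tibble(
    plate_id = "p1", well = "C7", role = "EXPERIMENTAL", target_gene = "SRC",
    arm = "vehicle", replicate = 1L, site_index = 1L,
    total_nuclei = 10L, myogenin_pos_nuclei = 1L)
  expect_s3_class(screen_dataset(row, lib), "screen_dataset")
  expect_error(screen_dataset(dplyr::mutate(row, target_gene = "Mtor"), lib),
               "not in library")
  expect_error(kinase_library(c("Src", "src")), "duplicate gene symbol")
})
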