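test_that("attribute registration stores permissible value sets per context", {
  reg <- attribute_registry() |>
    register_attribute("HistologicGrade", "Colon cancer",
      c("Low-grade", "Intermediate-grade", "High-grade"),
      is_ordinal = TRUE
    ) |>
    register_attribute("Apaf-1 Intensity", "Colon cancer", c("0", "1", "2", "3"),
      is_ordinal = TRUE
    )
  grade <- lookup_attribute(reg, "HistologicGrade", "Colon cancer")
  expect_length(grade$values[[1]], 3)
  expect_true(grade$is_ordinal)
  expect_length(permissible_values(reg, "Apaf-1 Intensity", "Colon cancer"), 4)

  expect_error(
    register_attribute(reg, "X", "ctx", character(0)),
    class = "tmatriad_validation_error"
  )
  expect_error(
    register_attribute(reg, "X", "ctx", c("a", "a")),
    class = "tmatriad_validation_error"
  )
  expect_error(
    register_attribute(
      reg, "HistologicGrade", "Colon cancer", c("G1", "G2")
    ),
    class = "tmatriad_conflict_error"
  )
})

test_that("context-specific definitions shadow wildcard definitions", {
  reg <- attribute_registry() |>
    register_attribute("Intensity", "*", c("0", "1", "2", "3"), is_ordinal = TRUE) |>
    register_attribute("Intensity", "Skin", c("neg", "pos"), is_ordinal = FALSE)
  expect_equal(permissible_values(reg, "Intensity", "Skin"), c("neg", "pos"))
  expect_equal(
    permissible_values(reg, "Intensity", "Colon cancer"),
    c("0", "1", "2", "3")
  )
  expect_error(
    lookup_attribute(reg, "Nope", "Skin"),
    class = "tmatriad_lookup_error"
  )
})

test_that("registry YAML round-trips", {
  reg <- demo_registry()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_registry(reg, path)
  reg2 <- read_registry(path)
  expect_equal(tibble::as_tibble(reg), tibble::as_tibble(reg2))
})

test_that("validate_dataset reports dangling foreign keys with coordinates", {
  ds <- make_worked_example_fixture()
  ds$Slide$ExperimentId[2] <- "E99"
  report <- validate_dataset(ds, demo_registry())
  expect_equal(nrow(report), 1)
  expect_equal(report$table, "Slide")
  expect_equal(report$column, "ExperimentId")
  expect_equal(report$kind, "dangling_fk")
  expect_equal(report$row, 2L)
})

test_that("validate_dataset reports out-of-vocabulary values", {
  ds <- make_worked_example_fixture()
  ds$StainingResult$Intensity[5] <- "5"
  report <- validate_dataset(ds, demo_registry())
  expect_equal(nrow(report), 1)
  expect_equal(report$kind, "value")
  expect_equal(report$table, "StainingResult")
  expect_equal(report$row, 5L)

  ds2 <- make_worked_example_fixture()
  ds2$SampleAttribute$Value[60] <- "Ultra-grade"
  report2 <- validate_dataset(ds2, demo_registry())
  expect_equal(nrow(report2), 1)
  expect_equal(report2$table, "SampleAttribute")
})

test_that("consistent datasets validate cleanly and duplicate keys are flagged", {
  ds <- make_worked_example_fixture()
  expect_equal(nrow(validate_dataset(ds, demo_registry())), 0)

  ds$Core$Id[2] <- ds$Core$Id[1]
  report <- validate_dataset(ds, demo_registry())
  expect_true("duplicate_pk" %in% report$kind)
})

test_that("validation is monotone: adding rows never removes violations", {
  ds <- make_worked_example_fixture()
  ds$Slide$ExperimentId[1] <- "E99"
  ds$StainingResult$Intensity[3] <- "9"
  before <- validate_dataset(ds, demo_registry())
  ds2 <- ds
  ds2$Core <- dplyr::bind_rows(
    ds2$Core,
    tibble::tibble(Id = "CRnew", SlideId = "SL1", SampleId = "P1")
  )
  ds2$SampleAttribute <- dplyr::bind_rows(
    ds2$SampleAttribute,
    tibble::tibble(
      Id = "SAnew", SampleId = "P1",
      AttributeName = "HistologicGrade", Value = "Bogus"
    )
  )
  after <- validate_dataset(ds2, demo_registry())
  expect_true(nrow(after) >= nrow(before))
  key <- function(r) paste(r$table, r$row, r$column, r$kind)
  expect_true(all(key(before) %in% key(after)))
})

test_that("TSV write/read round-trips a dataset up to row order", {
  ds <- make_worked_example_fixture()
  dir <- withr::local_tempdir()
  write_tma_dataset(ds, dir)
  ds2 <- read_tma_dataset(dir)
  for (tab in names(ds)) {
    expect_equal(
      dplyr::arrange(tibble::as_tibble(ds[[tab]]), dplyr::across(dplyr::everything())),
      dplyr::arrange(tibble::as_tibble(ds2[[tab]]), dplyr::across(dplyr::everything())),
      info = tab
    )
  }
})

test_that("missing values survive the TSV round trip as explicit NA", {
  ds <- make_worked_example_fixture()
  ds$StainingResult$Intensity[1] <- NA_character_
  dir <- withr::local_tempdir()
  write_tma_dataset(ds, dir)
  ds2 <- read_tma_dataset(dir)
  expect_true(is.na(ds2$StainingResult$Intensity[ds2$StainingResult$Id == "SR1"]))
})

test_that("duplicate primary key in a TSV file is a parse error naming the line", {
  ds <- make_worked_example_fixture()
  ds$Core$Id[3] <- ds$Core$Id[1]
  dir <- withr::local_tempdir()
  write_tma_dataset(ds, dir)
  expect_error(
    read_tma_dataset(dir),
    regexp = "Core\\.tsv.*line 4",
    class = "tmatriad_parse_error"
  )
})

test_that("a header-only table file reads as an empty, valid table", {
  dir <- withr::local_tempdir()
  write_tma_dataset(make_worked_example_fixture(), dir)
  writeLines("Id\tSlideId\tSampleId", file.path(dir, "Core.tsv"))
  ds <- read_tma_dataset(dir)
  expect_equal(nrow(ds$Core), 0)
  # dangling StainingResult FKs are reported, but parsing itself succeeds
  expect_s3_class(ds, "tma_dataset")
})

test_that("malformed headers and unknown tables are parse errors", {
  dir <- withr::local_tempdir()
  write_tma_dataset(make_worked_example_fixture(), dir)
  writeLines(c("Wrong\tHeader", "1\t2"), file.path(dir, "Core.tsv"))
  expect_error(read_tma_dataset(dir), class = "tmatriad_parse_error")
  expect_error(
    tma_dataset(Bogus = tibble::tibble(Id = "1")),
    class = "tmatriad_parse_error"
  )
})
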