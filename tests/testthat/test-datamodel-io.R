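test_that("peptide table TSV round-trips exactly and rejects bad rows", {
  df <- data.frame(
    sample_id = c("s1", "s1", "s2"),
    protein_id = c("TNFR1", "TNFR1", "CYLD"),
    peptide_sequence = c("AAAAAAK", "CCCCCCR", "DDDDDDK"),
    charge = c(2L, 3L, 2L),
    endogenous_intensity = c(2000, 1500, 0),
    reference_intensity = c(1000, 3000, 500),
    spike_amount_amol = c(100, 16, 160),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTsv(df, path)
  back <- readPeptideTable(path)
  expect_equal(back, df)

  # header-only file -> empty table with the right columns
  writeTsv(df[0, ], path)
  empty <- readPeptideTable(path)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, names(df))

  # negative spike amount -> validation error citing the row
  bad <- df
  bad$spike_amount_amol[2] <- -5
  writeTsv(bad, path)
  expect_error(readPeptideTable(path), "row 2")

  # missing required column -> format error naming it
  writeTsv(df[, setdiff(names(df), "reference_intensity")], path)
  expect_error(readPeptideTable(path), "reference_intensity")

  # malformed numeric cell rejected
  txt <- readLines(writeTsv(df, path))
  txt[2] <- sub("2000", "twothousand", txt[2])
  writeLines(txt, path)
  expect_error(readPeptideTable(path), "malformed")
})

test_that("sample metadata validation enforces the field contracts", {
  meta <- data.frame(
    sample_id = c("l1", "b1"),
    sample_type = c("lysate", "bnpage_fraction"),
    timepoint = c(0, 0), replicate = c(1L, 1L),
    cell_equivalents = c(3043, 2.4e6),
    injected_fraction = c(0.007, 1),
    treatment = c("", "minusDUB"),
    fraction_index = c(NA_integer_, 5L),
    stringsAsFactors = FALSE)
  expect_silent(validateSampleMeta(meta))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTsv(meta, path)
  expect_equal(readSampleMeta(path)$cell_equivalents,
               meta$cell_equivalents)

  bad <- meta; bad$injected_fraction[1] <- 1.5
  expect_error(validateSampleMeta(bad), "injected_fraction")
  bad <- meta; bad$fraction_index[1] <- 3L
  expect_error(validateSampleMeta(bad), "fraction_index")
  bad <- meta; bad$fraction_index[2] <- NA_integer_
  expect_error(validateSampleMeta(bad), "fraction_index")
  bad <- meta; bad$cell_equivalents[1] <- 0
  expect_error(validateSampleMeta(bad), "cell_equivalents")
})

test_that("complex config YAML round-trips and is validated", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeComplexConfig(toyComplexSet(), path)
  back <- readComplexConfig(path)
  expect_equal(complexNames(back), c("receptor-core", "CYLD-SPATA2"))
  expect_equal(members(back[["CYLD-SPATA2"]]), c(CYLD = 2L, SPATA2 = 2L))
  expect_true(isReceptor(back[["receptor-core"]]))
  expect_equal(receptorOligomer(back), 3L)
  expect_equal(receptorProtein(back), "TNFR1")

  # two receptor flags -> configuration error
  writeLines(c(
    "schema_version: '1.0'",
    "complexes:",
    "  - name: a",
    "    receptor: true",
    "    members: {X: 3}",
    "  - name: b",
    "    receptor: true",
    "    members: {Y: 1}"), path)
  expect_error(readComplexConfig(path), "receptorFlag")

  # missing multiplicity defaults to 1 with a warning
  writeLines(c(
    "schema_version: '1.0'",
    "complexes:",
    "  - name: a",
    "    receptor: true",
    "    members:",
    "      X: 3",
    "      Z:"), path)
  expect_warning(cs <- readComplexConfig(path), "defaulting to 1")
  expect_equal(members(cs[["a"]])[["Z"]], 1L)

  # duplicated names rejected
  writeLines(c(
    "complexes:",
    "  - name: a",
    "    receptor: true",
    "    members: {X: 3}",
    "  - name: a",
    "    members: {Y: 1}"), path)
  expect_error(readComplexConfig(path), "duplicated")
})

test_that("ComplexSet and ComplexDefinition validity catch bad inputs", {
  expect_error(ComplexDefinition("c", c(A = 0)), "multiplicities")
  expect_error(ComplexDefinition("c", 2), "named")
  expect_error(
    ComplexSet(ComplexDefinition("c", c(A = 1))),  # no receptor
    "receptorFlag")
  expect_error(validObject(
    new("ComplexDefinition", complexName = "x", members = c(A = 1L),
        referencePolicy = "fixed:B", receptorFlag = FALSE,
        receptorOligomer = 3L)), "not a member")
})

test_that("writeReport emits the allocation schema, records the seed, and is byte-stable", {
  alloc <- limitingComponents(
    c(A = 10000, B = 5000), c(A = 8000, B = 8000),
    copies_recovered = c(A = 120, B = 40))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  writeReport(list(allocation = alloc), dir1, seed = 7L,
              params = list(calibrant = "TNFR1"))
  writeReport(list(allocation = alloc), dir2, seed = 7L,
              params = list(calibrant = "TNFR1"))
  tsv <- file.path(dir1, "allocation.tsv")
  expect_true(file.exists(tsv))
  got <- read.delim(tsv)
  expect_named(got, c("protein_id", "copies_available", "copies_required",
                      "copies_recovered", "limiting"))
  js <- jsonlite::read_json(file.path(dir1, "summary.json"))
  expect_equal(js$seed, 7L)
  expect_true(nzchar(js$config_hash))
  # identical inputs and seed -> byte-identical outputs
  expect_equal(unname(tools::md5sum(tsv)),
               unname(tools::md5sum(file.path(dir2, "allocation.tsv"))))

  expect_error(writeReport(list(x = alloc), "/dev/null/nope"), "director")
})
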