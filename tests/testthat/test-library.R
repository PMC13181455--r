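test_that("libraries deduplicate by canonical form and order deterministically", {
  expect_warning(
    lib <- fragment_library(c("CCO", "OCC"), role = "warhead"),
    "duplicate")
  expect_length(lib$fragments, 1L)

  lib2 <- fragment_library(c("c1ccncc1", "C1CCNCC1"), role = "warhead")
  expect_length(lib2$fragments, 2L)
  # descending heavy-atom count, ties lexicographic
  sizes <- vapply(lib2$fragments, `[[`, integer(1), "n_heavy")
  expect_true(all(diff(sizes) <= 0))

  # shuffling input rows yields the identical library ordering
  smis <- fixture_fragments()$warheads
  la <- fragment_library(smis, role = "warhead")
  lb <- fragment_library(rev(smis), role = "warhead")
  expect_identical(
    vapply(la$fragments, `[[`, character(1), "smiles_canonical"),
    vapply(lb$fragments, `[[`, character(1), "smiles_canonical"))
})

test_that("unparseable rows are skipped with a warning, empty libraries error", {
  expect_warning(
    lib <- fragment_library(c("not_a_smiles", "c1ccccc1"), role = "warhead"),
    "unparseable")
  expect_length(lib$fragments, 1L)
  expect_error(suppressWarnings(
    fragment_library("not_a_smiles", role = "warhead")),
    class = "protacR_empty_library_error")
  expect_error(fragment_library(character(0), role = "warhead"),
               class = "protacR_empty_library_error")
})

test_that("file loading accepts SMILES lines and CSV, and round-trips", {
  dir <- withr::local_tempdir()
  smi_path <- file.path(dir, "lib.smi")
  writeLines(c("c1ccncc1 pyr", "C1CCNCC1 pip"), smi_path)
  lib <- load_fragment_library(smi_path, role = "warhead")
  expect_length(lib$fragments, 2L)
  expect_setequal(vapply(lib$fragments, `[[`, character(1), "id"),
                  c("pyr", "pip"))

  csv_path <- file.path(dir, "lib.csv")
  write.csv(data.frame(id = c("a", "b"), smiles = c("c1ccncc1", "CCOCC")),
            csv_path, row.names = FALSE)
  lib2 <- load_fragment_library(csv_path, role = "e3_ligand")
  expect_length(lib2$fragments, 2L)

  # write + reload is idempotent
  out <- file.path(dir, "roundtrip.csv")
  write_fragment_library(lib, out)
  lib3 <- load_fragment_library(out, role = "warhead")
  expect_identical(as.data.frame(lib3)[, c("smiles_canonical", "n_heavy")],
                   as.data.frame(lib)[, c("smiles_canonical", "n_heavy")])

  expect_error(load_fragment_library(file.path(dir, "absent.smi"), "warhead"),
               class = "protacR_io_error")
})

test_that("validate_library reports size, disconnection and id diagnostics", {
  lib_small <- fragment_library("CC", role = "warhead", min_heavy = 1L)
  d <- validate_library(lib_small, min_heavy = 3L)
  expect_true("below_min_size" %in% d$type)

  lib_ok <- fragment_library("c1ccncc1", role = "warhead")
  expect_equal(nrow(validate_library(lib_ok)), 0L)

  lib_dup <- fragment_library(c("c1ccncc1", "C1CCNCC1"),
                              ids = c("w1", "w1"), role = "warhead")
  d2 <- validate_library(lib_dup)
  expect_true("duplicate_id" %in% d2$type)

  lib_salt <- fragment_library("c1ccncc1.[Na+]", role = "warhead")
  d3 <- validate_library(lib_salt)
  expect_true("disconnected_input" %in% d3$type)
})
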