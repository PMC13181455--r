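make_batch_inputs <- function(dir) {
  f <- fixture_fragments()
  sp1 <- assemble_protac(f$warheads[["quinoline"]], "CCC",
                         f$e3s[["phthalimide"]])
  sp2 <- assemble_protac(f$warheads[["benzimidazole"]], "CCOCC",
                         f$e3s[["glutarimide"]])
  input <- file.path(dir, "input.csv")
  write.csv(data.frame(
    id = c("a", "b", "c"),
    smiles = c(sp1$protac_smiles, sp2$protac_smiles,
               "CCCCCCCCCC")),  # decane: matches nothing
    input, row.names = FALSE)
  wlib <- file.path(dir, "warheads.smi")
  writeLines(c(paste(f$warheads[["quinoline"]], "q"),
               paste(f$warheads[["benzimidazole"]], "b")), wlib)
  elib <- file.path(dir, "e3.smi")
  writeLines(c(paste(f$e3s[["phthalimide"]], "p"),
               paste(f$e3s[["glutarimide"]], "g")), elib)
  list(input = input, wlib = wlib, elib = elib)
}

test_that("run_batch splits solved and unresolved rows and counts add up", {
  dir <- withr::local_tempdir()
  io <- make_batch_inputs(dir)
  out <- file.path(dir, "solved.csv")
  unres <- file.path(dir, "unresolved.csv")
  s <- run_batch(io$input, io$wlib, io$elib, out, unres, quiet = TRUE)
  expect_equal(s$n_input, 3L)
  expect_equal(s$n_solved, 2L)
  expect_equal(s$n_failed, 1L)
  expect_equal(s$failure_counts$warhead_not_found, 1L)
  expect_equal(s$n_solved + s$n_failed + s$n_input_error, s$n_input)

  solved <- read.csv(out)
  unresolved <- read.csv(unres)
  expect_setequal(c(solved$protac_id, unresolved$protac_id),
                  c("a", "b", "c"))
  expect_equal(sum(unlist(s$failure_counts)), s$n_failed)
})

test_that("reruns are byte-identical and parse errors land in unresolved", {
  dir <- withr::local_tempdir()
  io <- make_batch_inputs(dir)
  input2 <- file.path(dir, "input2.csv")
  tab <- read.csv(io$input)
  tab$smiles[3] <- "]bogus["
  write.csv(tab, input2, row.names = FALSE)
  out1 <- file.path(dir, "o1.csv"); un1 <- file.path(dir, "u1.csv")
  out2 <- file.path(dir, "o2.csv"); un2 <- file.path(dir, "u2.csv")
  run_batch(input2, io$wlib, io$elib, out1, un1, quiet = TRUE)
  run_batch(input2, io$wlib, io$elib, out2, un2, quiet = TRUE)
  expect_identical(readLines(out1), readLines(out2))
  expect_identical(readLines(un1), readLines(un2))
  un <- read.csv(un1)
  expect_true("input_error" %in% un$failure_category)
  expect_true("c" %in% un$protac_id)
})

test_that("solution emission policy and summary JSON work", {
  dir <- withr::local_tempdir()
  cases <- test_adversarial()
  cs <- cases$boundary_ambiguity
  input <- file.path(dir, "amb.csv")
  write.csv(data.frame(id = "amb", smiles = cs$protac_smiles), input,
            row.names = FALSE)
  wlib <- file.path(dir, "w.csv"); elib <- file.path(dir, "e.csv")
  write_fragment_library(cs$warhead_lib, wlib)
  write_fragment_library(cs$e3_lib, elib)
  out <- file.path(dir, "s.csv"); un <- file.path(dir, "u.csv")
  js <- file.path(dir, "summary.json")
  s <- run_batch(input, wlib, elib, out, un, emit_all_solutions = TRUE,
                 summary_json = js, quiet = TRUE)
  expect_equal(nrow(read.csv(out)), 2L)  # both boundary solutions emitted
  expect_equal(s$n_multi_solution, 1L)
  expect_true(file.exists(js))
  j <- jsonlite::read_json(js)
  expect_equal(j$n_solved, 1L)

  out2 <- file.path(dir, "s2.csv"); un2 <- file.path(dir, "u2.csv")
  run_batch(input, wlib, elib, out2, un2, emit_all_solutions = FALSE,
            quiet = TRUE)
  expect_equal(nrow(read.csv(out2)), 1L)  # top-ranked solution only
})

test_that("degenerate batch inputs raise structured errors", {
  dir <- withr::local_tempdir()
  io <- make_batch_inputs(dir)
  empty <- file.path(dir, "empty.csv")
  writeLines("id,smiles", empty)
  expect_error(
    run_batch(empty, io$wlib, io$elib,
              file.path(dir, "o.csv"), file.path(dir, "u.csv"),
              quiet = TRUE),
    class = "protacR_input_error")
  expect_error(
    run_batch(io$input, io$wlib, io$elib, io$input,
              file.path(dir, "u.csv"), quiet = TRUE),
    class = "protacR_input_error")
})
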