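# Batch driver: read a degrader dataset, decompose every row, write solved
# reports to one file and unresolved cases (with their failure category) to
# a separate file for targeted library expansion.

#' Decompose a degrader dataset in batch
#'
#' Reads an input table of SMILES (CSV with a `smiles` column and optional
#' `id`, or a plain SMILES file), runs [bidirectional_decompose()] on every
#' row against the two libraries, writes solved rows to `output_path` and
#' failed/unparseable rows to `unresolved_path`, and returns a summary.
#' Rows that fail SMILES parsing are exported with category `input_error`
#' (an artifact-level extension of the failure taxonomy) rather than
#' silently dropped; the union of ids across the two output files always
#' equals the input ids.
#'
#' @param input_path Input CSV/SMILES file.
#' @param warhead_lib,e3_lib `fragment_library` objects, or paths to
#'   library files.
#' @param output_path,unresolved_path Output CSV paths.
#' @param emit_all_solutions Emit one row per solution (`TRUE`, default) or
#'   only the top-ranked solution per degrader.
#' @param stereo Stereo mode (see [standardize_molecule()]).
#' @param min_fragment_heavy_atoms Library size threshold when libraries
#'   are given as paths.
#' @param summary_json Optional path for a JSON copy of the summary.
#' @param quiet Suppress the printed summary.
#' @return An object of class `batch_summary`: `n_input`, `n_solved`,
#'   `n_failed`, `n_input_error`, `failure_counts`, `n_multi_solution`.
#' @export
run_batch <- function(input_path, warhead_lib, e3_lib,
                      output_path, unresolved_path,
                      emit_all_solutions = TRUE,
                      stereo = "ignore",
                      min_fragment_heavy_atoms = 3L,
                      summary_json = NULL,
                      quiet = FALSE) {
  paths <- c(input_path, output_path, unresolved_path)
  if (anyDuplicated(paths))
    .pR_error("input, output and unresolved paths must be distinct",
              "protacR_input_error")
  if (is.character(warhead_lib))
    warhead_lib <- load_fragment_library(warhead_lib, role = "warhead",
                                         min_heavy = min_fragment_heavy_atoms,
                                         stereo = stereo)
  if (is.character(e3_lib))
    e3_lib <- load_fragment_library(e3_lib, role = "e3_ligand",
                                    min_heavy = min_fragment_heavy_atoms,
                                    stereo = stereo)
  if (!file.exists(input_path))
    .pR_error(sprintf("input file not found: '%s'", input_path),
              "protacR_io_error")
  tab <- read_molecule_table(input_path)
  if (nrow(tab) == 0)
    .pR_error("no input rows to decompose", "protacR_input_error")

  reports <- lapply(seq_len(nrow(tab)), function(k)
    bidirectional_decompose(tab$smiles[k], warhead_lib, e3_lib,
                            protac_id = tab$id[k], stereo = stereo))

  rows <- lapply(reports, function(rep) {
    df <- as.data.frame(rep)
    if (!emit_all_solutions && rep$status == "solved")
      df <- df[1, , drop = FALSE]
    df
  })
  all_rows <- do.call(rbind, rows)
  solved <- all_rows[all_rows$status == "solved", , drop = FALSE]
  unresolved <- all_rows[all_rows$status != "solved", , drop = FALSE]
  utils::write.csv(solved, output_path, row.names = FALSE)
  utils::write.csv(unresolved, unresolved_path, row.names = FALSE)

  status <- vapply(reports, `[[`, character(1), "status")
  fcat <- vapply(reports, function(r)
    if (is.na(r$failure_category)) "" else r$failure_category, character(1))
  fc <- table(fcat[status == "failed"])
  summary <- structure(list(
    n_input = nrow(tab),
    n_solved = sum(status == "solved"),
    n_failed = sum(status == "failed"),
    n_input_error = sum(status == "input_error"),
    failure_counts = as.list(fc),
    n_multi_solution = sum(vapply(reports, function(r)
      length(r$solutions) > 1, logical(1))),
    output_path = output_path,
    unresolved_path = unresolved_path
  ), class = "batch_summary")
  if (!is.null(summary_json))
    jsonlite::write_json(unclass(summary)[1:6], summary_json,
                         auto_unbox = TRUE)
  if (!quiet) print(summary)
  invisible(summary)
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf(
    "<batch_summary> input=%d  solved=%d  failed=%d  input_error=%d  multi-solution=%d\n",
    x$n_input, x$n_solved, x$n_failed, x$n_input_error, x$n_multi_solution))
  if (length(x$failure_counts)) {
    cat("  failure categories:\n")
    for (nm in names(x$failure_counts))
      cat(sprintf("    %-26s %d\n", nm, x$failure_counts[[nm]]))
  }
  invisible(x)
}
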