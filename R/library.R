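# Fragment libraries: curated sets of warheads or E3 ligase ligands against
# which degraders are matched. Entries are whole ligand molecules (no
# attachment-point annotation); attachment points are discovered at match
# time.

#' Build a fragment library from SMILES
#'
#' Standardizes each SMILES, drops unparseable rows with a warning,
#' collapses duplicates (same canonical SMILES; first occurrence wins) and
#' applies the deterministic library ordering: descending heavy-atom count,
#' ties broken by lexicographic canonical SMILES. Larger fragments are tried
#' first during decomposition, which keeps boundary matches as specific as
#' possible.
#'
#' @param smiles Character vector of fragment SMILES.
#' @param ids Optional character vector of fragment ids (recycled defaults
#'   `w1`, `w2`, ... / `e1`, `e2`, ... by role).
#' @param role `"warhead"` or `"e3_ligand"`.
#' @param min_heavy Minimum fragment size in heavy atoms; smaller entries
#'   are dropped with a warning (default 3, excluding degenerate matches).
#' @param stereo Stereo mode passed to [standardize_molecule()].
#' @param source_path Optional provenance string stored on the library.
#' @return An object of class `fragment_library`.
#' @examples
#' lib <- fragment_library(c("c1ccncc1", "C1CCNCC1"), role = "warhead")
#' length(lib$fragments)
#' @export
fragment_library <- function(smiles, ids = NULL,
                             role = c("warhead", "e3_ligand"),
                             min_heavy = 3L, stereo = "ignore",
                             source_path = NA_character_) {
  role <- match.arg(role)
  if (length(smiles) == 0)
    .pR_error("no fragments supplied", "protacR_empty_library_error")
  prefix <- if (role == "warhead") "w" else "e"
  if (is.null(ids)) ids <- paste0(prefix, seq_along(smiles))
  if (length(ids) != length(smiles))
    .pR_error("'ids' must align 1:1 with 'smiles'", "protacR_input_error")

  frags <- list()
  seen <- character(0)
  for (k in seq_along(smiles)) {
    mol <- tryCatch(standardize_molecule(smiles[k], stereo = stereo),
                    error = function(e) NULL)
    if (is.null(mol)) {
      warning(sprintf("skipping unparseable fragment '%s' (row %d)",
                      smiles[k], k), call. = FALSE)
      next
    }
    if (mol$n_heavy < min_heavy) {
      warning(sprintf(
        "skipping fragment '%s' (%d heavy atoms < min_heavy = %d)",
        smiles[k], mol$n_heavy, min_heavy), call. = FALSE)
      next
    }
    if (mol$smiles %in% seen) {
      warning(sprintf(
        "duplicate fragment '%s' (canonical '%s') collapsed to first occurrence",
        smiles[k], mol$smiles), call. = FALSE)
      next
    }
    seen <- c(seen, mol$smiles)
    frags[[length(frags) + 1L]] <- list(
      id = as.character(ids[k]),
      smiles_input = smiles[k],
      smiles_canonical = mol$smiles,
      role = role,
      n_heavy = mol$n_heavy,
      n_rings = mol$n_rings,
      mol = mol
    )
  }
  if (length(frags) == 0)
    .pR_error("no parseable fragments above the size threshold",
              "protacR_empty_library_error")
  ord <- order(-vapply(frags, `[[`, integer(1), "n_heavy"),
               vapply(frags, `[[`, character(1), "smiles_canonical"))
  structure(list(role = role, fragments = frags[ord],
                 source_path = source_path, min_heavy = min_heavy,
                 stereo = stereo),
            class = "fragment_library")
}

#' Load a fragment library from a file
#'
#' Accepts plain SMILES files (one record per line, optional second
#' whitespace-separated token used as the id) or CSV files with at least a
#' `smiles` column (header-detected) and an optional `id` column.
#'
#' @param path Path to the library file.
#' @inheritParams fragment_library
#' @return A `fragment_library`.
#' @export
load_fragment_library <- function(path, role = c("warhead", "e3_ligand"),
                                  min_heavy = 3L, stereo = "ignore") {
  role <- match.arg(role)
  if (!file.exists(path))
    .pR_error(sprintf("library file not found: '%s'", path),
              "protacR_io_error")
  tab <- read_molecule_table(path)
  if (nrow(tab) == 0)
    .pR_error(sprintf("no rows in library file '%s'", path),
              "protacR_empty_library_error")
  fragment_library(tab$smiles, ids = tab$id, role = role,
                   min_heavy = min_heavy, stereo = stereo,
                   source_path = path)
}

# Shared reader for {smiles, id} tables: CSV with a header containing a
# smiles column, else whitespace-separated SMILES lines.
read_molecule_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(id = character(0), smiles = character(0)))
  header <- gsub("\"", "", trimws(tolower(strsplit(lines[1], ",")[[1]])))
  smi_col <- intersect(c("smiles", "smiles_canonical", "smiles_input"),
                       header)
  if (length(smi_col) > 0) {
    tab <- utils::read.csv(textConnection(paste(lines, collapse = "\n")),
                           stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    id <- if ("id" %in% names(tab)) as.character(tab$id) else
      as.character(seq_len(nrow(tab)))
    data.frame(id = id, smiles = as.character(tab[[smi_col[1]]]),
               stringsAsFactors = FALSE)
  } else {
    toks <- strsplit(trimws(lines), "[ \t]+")
    data.frame(
      id = vapply(seq_along(toks), function(k)
        if (length(toks[[k]]) >= 2) toks[[k]][2] else as.character(k),
        character(1)),
      smiles = vapply(toks, `[[`, character(1), 1),
      stringsAsFactors = FALSE)
  }
}

#' Validate a fragment library
#'
#' Diagnostic-only check: reports fragments below the minimum-size
#' threshold, entries whose input SMILES contained several disconnected
#' components (the largest was kept), and duplicated ids. Never mutates the
#' library.
#'
#' @param lib A `fragment_library`.
#' @param min_heavy Size threshold used for the report (defaults to the
#'   library's own).
#' @return A data frame with columns `id`, `type`, `message` (zero rows if
#'   clean).
#' @export
validate_library <- function(lib, min_heavy = NULL) {
  stopifnot(inherits(lib, "fragment_library"))
  if (is.null(min_heavy)) min_heavy <- lib$min_heavy
  diags <- list()
  add <- function(id, type, msg)
    diags[[length(diags) + 1L]] <<- data.frame(
      id = id, type = type, message = msg, stringsAsFactors = FALSE)
  for (fr in lib$fragments) {
    if (fr$n_heavy < min_heavy)
      add(fr$id, "below_min_size",
          sprintf("%d heavy atoms < threshold %d", fr$n_heavy, min_heavy))
    if (grepl(".", fr$smiles_input, fixed = TRUE))
      add(fr$id, "disconnected_input",
          "input SMILES had multiple components; largest kept")
  }
  ids <- vapply(lib$fragments, `[[`, character(1), "id")
  for (dup in unique(ids[duplicated(ids)]))
    add(dup, "duplicate_id", sprintf("id '%s' used more than once", dup))
  if (length(diags) == 0)
    return(data.frame(id = character(0), type = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, diags)
}

#' @export
as.data.frame.fragment_library <- function(x, ...) {
  data.frame(
    id = vapply(x$fragments, `[[`, character(1), "id"),
    smiles_input = vapply(x$fragments, `[[`, character(1), "smiles_input"),
    smiles_canonical = vapply(x$fragments, `[[`, character(1),
                              "smiles_canonical"),
    n_heavy = vapply(x$fragments, `[[`, integer(1), "n_heavy"),
    n_rings = vapply(x$fragments, `[[`, integer(1), "n_rings"),
    stringsAsFactors = FALSE
  )
}

#' Write a fragment library to CSV
#'
#' Serializes the standardized library; re-loading the file reproduces the
#' library (load/write round trip is idempotent).
#'
#' @param lib A `fragment_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fragment_library <- function(lib, path) {
  utils::write.csv(as.data.frame(lib), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library> role=%s  fragments=%d  (min_heavy=%d)\n",
              x$role, length(x$fragments), x$min_heavy))
  df <- as.data.frame(x)
  print(utils::head(df[, c("id", "smiles_canonical", "n_heavy", "n_rings")],
                    10))
  if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more\n")
  invisible(x)
}
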