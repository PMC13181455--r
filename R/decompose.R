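# The decomposition engine: two directional match-and-subtract passes over
# the warhead and E3 ligand libraries, a bidirectional linker-consistency
# check, structural conservation filters, multiple-solution enumeration and
# failure categorization.
#
# Matching is *induced* subgraph isomorphism (VF2, vertex-colored by
# element/charge/aromaticity, edge-colored by bond order with aromatic bonds
# as their own class): a library fragment must appear in the degrader
# exactly as drawn, with cut bonds only to atoms outside the match.

.vf2_colors <- function(parent, frag) {
  vkey_p <- paste(parent$elem, parent$charge, parent$arom_atom)
  vkey_f <- paste(frag$elem, frag$charge, frag$arom_atom)
  keys <- unique(c(vkey_p, vkey_f))
  ecol_p <- ifelse(parent$arom_bond, 4L, parent$bonds$order)
  ecol_f <- ifelse(frag$arom_bond, 4L, frag$bonds$order)
  list(vp = match(vkey_p, keys), vf = match(vkey_f, keys),
       ep = as.integer(ecol_p), ef = as.integer(ecol_f))
}

#' Find all substructure embeddings of a fragment in a parent molecule
#'
#' Enumerates every symmetry-distinct induced embedding of a library
#' fragment in a degrader. Embeddings identical as atom sets are reported
#' once; a fragment at least as large as the parent never matches (all
#' three moieties of a decomposition must be nonempty). Ordering is
#' deterministic (by sorted atom-index tuple).
#'
#' @param parent A `protac_mol` (or SMILES) for the degrader.
#' @param fragment A library fragment entry (from a `fragment_library`), a
#'   `protac_mol`, or a SMILES string.
#' @return A list of match sites; each has `fragment_id`, `atoms` (sorted
#'   parent atom indices) and `cut_bonds` (data frame of inside/outside
#'   atom-index pairs).
#' @examples
#' sites <- find_matches("c1ccc(nc1)CCCN1CCCCC1", "c1ccncc1")
#' length(sites)            # 1
#' nrow(sites[[1]]$cut_bonds)  # 1
#' @export
find_matches <- function(parent, fragment) {
  parent <- as_protac_mol(parent)
  frag_id <- NA_character_
  if (is.list(fragment) && !inherits(fragment, "protac_mol") &&
      !is.null(fragment$mol)) {
    frag_id <- fragment$id
    fragment <- fragment$mol
  } else {
    fragment <- as_protac_mol(fragment)
  }
  if (fragment$n_heavy >= parent$n_heavy) return(list())
  col <- .vf2_colors(parent, fragment)
  maps <- igraph::subgraph_isomorphisms(
    pattern = fragment$graph, target = parent$graph, method = "vf2",
    vertex.color1 = col$vp, vertex.color2 = col$vf,
    edge.color1 = col$ep, edge.color2 = col$ef)
  if (length(maps) == 0) return(list())
  sets <- unique(lapply(maps, function(mp) sort(as.integer(names(mp)))))
  # enforce induced embeddings: the matched atom set must carry exactly the
  # fragment's bonds -- an extra (chord) bond inside the image disqualifies
  # the site (VF2 only checks the mapped pattern edges)
  n_frag_bonds <- nrow(fragment$bonds)
  sets <- Filter(function(s) {
    inset <- logical(parent$n_heavy); inset[s] <- TRUE
    sum(inset[parent$bonds$i] & inset[parent$bonds$j]) == n_frag_bonds
  }, sets)
  if (length(sets) == 0) return(list())
  ord <- order(vapply(sets, function(s)
    paste(sprintf("%06d", s), collapse = ","), character(1)))
  sets <- sets[ord]
  lapply(sets, function(s) {
    inset <- logical(parent$n_heavy); inset[s] <- TRUE
    b <- parent$bonds
    cut_i <- inset[b$i] & !inset[b$j]
    cut_j <- !inset[b$i] & inset[b$j]
    cut <- rbind(
      data.frame(inside = b$i[cut_i], outside = b$j[cut_i]),
      data.frame(inside = b$j[cut_j], outside = b$i[cut_j]))
    cut <- cut[order(cut$inside, cut$outside), , drop = FALSE]
    rownames(cut) <- NULL
    list(fragment_id = frag_id, atoms = s, cut_bonds = cut)
  })
}

#' Subtract a matched fragment from a parent molecule
#'
#' Removes the matched atoms and all incident bonds and returns the
#' connected components of the remainder, each as a canonical-SMILES record
#' with the original parent atom indices retained for bookkeeping (no dummy
#' attachment atoms are introduced in the emitted SMILES).
#'
#' @param parent A `protac_mol` (or SMILES).
#' @param site A match site from [find_matches()].
#' @return List of remainder components, each with `smiles`, `atoms`,
#'   `n_heavy`, `n_rings`; deterministically ordered (descending size).
#' @export
subtract_fragment <- function(parent, site) {
  parent <- as_protac_mol(parent)
  rest <- setdiff(seq_len(parent$n_heavy), site$atoms)
  if (length(rest) == 0)
    .pR_error("fragment covers the whole molecule (degenerate subtraction)",
              "protacR_degenerate_error")
  subgraph_components(parent, rest)
}

#' One directional match-and-subtract pass
#'
#' Matches every first-library fragment against the degrader; for each
#' match site whose subtraction leaves exactly one connected remainder,
#' matches every second-library fragment inside that remainder. The
#' leftover atoms form the candidate linker, which may still consist of
#' several components at this stage -- the single-linker filter runs later.
#' The trace records how far the pass got (`first_matched`,
#' `second_matched`), which feeds the failure taxonomy.
#'
#' @param parent `protac_mol` or SMILES.
#' @param first_lib,second_lib `fragment_library` objects; pass A uses
#'   (warheads, E3 ligands), pass B the reverse.
#' @return A `decomp_pass` trace: `candidates` (list of triples with atom
#'   bookkeeping) plus the two stage flags.
#' @export
decompose_pass <- function(parent, first_lib, second_lib) {
  parent <- as_protac_mol(parent)
  stopifnot(inherits(first_lib, "fragment_library"),
            inherits(second_lib, "fragment_library"))
  candidates <- list()
  first_matched <- FALSE
  second_matched <- FALSE
  for (fr1 in first_lib$fragments) {
    sites1 <- find_matches(parent, fr1)
    if (length(sites1) > 0) first_matched <- TRUE
    for (s1 in sites1) {
      rem <- setdiff(seq_len(parent$n_heavy), s1$atoms)
      if (length(rem) == 0) next
      rem_mol <- induced_submol(parent, rem)
      if (rem_mol$n_components != 1) next  # first subtraction must not split
      for (fr2 in second_lib$fragments) {
        sites2 <- find_matches(rem_mol, fr2)
        if (length(sites2) > 0) second_matched <- TRUE
        for (s2 in sites2) {
          atoms2 <- rem_mol$parent_atoms[s2$atoms]  # back to parent indexing
          linker_atoms <- setdiff(rem, atoms2)
          if (length(linker_atoms) == 0) next  # linker must be nonempty
          lcomp <- subgraph_components(parent, linker_atoms)
          candidates[[length(candidates) + 1L]] <- list(
            first_id = fr1$id, first_smiles = fr1$smiles_canonical,
            first_n_heavy = fr1$n_heavy, first_n_rings = fr1$n_rings,
            second_id = fr2$id, second_smiles = fr2$smiles_canonical,
            second_n_heavy = fr2$n_heavy, second_n_rings = fr2$n_rings,
            first_atoms = s1$atoms, second_atoms = sort(atoms2),
            linker_atoms = sort(linker_atoms),
            linker_components = vapply(lcomp, `[[`, character(1), "smiles"),
            linker_n_heavy = length(linker_atoms),
            linker_n_rings = sum(vapply(lcomp, `[[`, integer(1), "n_rings"))
          )
        }
      }
    }
  }
  structure(list(candidates = candidates,
                 first_matched = first_matched,
                 second_matched = second_matched),
            class = "decomp_pass")
}

# Identity key of a candidate as (warhead canonical, e3 canonical, linker
# canonical multiset), with `warhead_first` saying which moiety the pass
# matched first.
.candidate_key <- function(cand, warhead_first) {
  w <- if (warhead_first) cand$first_smiles else cand$second_smiles
  e <- if (warhead_first) cand$second_smiles else cand$first_smiles
  paste(w, e, paste(sort(cand$linker_components), collapse = "."),
        sep = "\r")
}

#' Structural filters on a decomposition candidate
#'
#' Checks, in order: the linker is exactly one connected component with at
#' least one heavy atom; heavy-atom conservation (warhead + linker + E3
#' equals the parent); ring-count conservation (SSSR; no ring may be cut).
#' All violations are reported, not just the first.
#'
#' @param candidate A candidate triple from [decompose_pass()].
#' @param parent The parent `protac_mol`.
#' @param warhead_first Whether the candidate came from a warhead-first pass.
#' @return List with `pass` (logical) and `violations` (character vector
#'   drawn from `multiple_linker_fragments`, `count_discrepancy`).
#' @export
apply_filters <- function(candidate, parent, warhead_first = TRUE) {
  parent <- as_protac_mol(parent)
  violations <- character(0)
  if (length(candidate$linker_components) != 1 ||
      candidate$linker_n_heavy < 1)
    violations <- c(violations, "multiple_linker_fragments")
  heavy_sum <- candidate$first_n_heavy + candidate$second_n_heavy +
    candidate$linker_n_heavy
  if (heavy_sum != parent$n_heavy)
    violations <- c(violations, "count_discrepancy")
  ring_sum <- candidate$first_n_rings + candidate$second_n_rings +
    candidate$linker_n_rings
  if (ring_sum != parent$n_rings)
    violations <- unique(c(violations, "count_discrepancy"))
  list(pass = length(violations) == 0, violations = violations)
}

#' Categorize a failed decomposition
#'
#' Assigns exactly one failure category when no valid solution survived,
#' using an earliest-stage priority order: `warhead_not_found` (no
#' warhead-library match anywhere) takes precedence over `e3_not_found`,
#' then `linker_inconsistent` (matches existed but no identical
#' warhead/linker/E3 triple in both passes), then
#' `multiple_linker_fragments` (consistent candidates existed but all had
#' disconnected linkers), then `count_discrepancy`.
#'
#' @param pass_a Trace of the warhead-first pass ([decompose_pass()]).
#' @param pass_b Trace of the E3-first pass.
#' @param consistent_filtered List of `apply_filters()` results for the
#'   bidirectionally consistent candidates (all of which failed).
#' @return One of the five category strings.
#' @export
categorize_failure <- function(pass_a, pass_b, consistent_filtered) {
  if (length(consistent_filtered) > 0 &&
      any(vapply(consistent_filtered, function(x) x$pass, logical(1))))
    .pR_error("categorize_failure called although valid solutions exist",
              "protacR_contract_error")
  warhead_matched <- pass_a$first_matched
  e3_matched <- pass_b$first_matched
  if (!warhead_matched) return("warhead_not_found")
  if (!e3_matched) return("e3_not_found")
  if (length(consistent_filtered) == 0) return("linker_inconsistent")
  all_multi <- all(vapply(consistent_filtered, function(x)
    "multiple_linker_fragments" %in% x$violations, logical(1)))
  if (all_multi) return("multiple_linker_fragments")
  "count_discrepancy"
}

#' Bidirectional PROTAC decomposition
#'
#' Runs the warhead-first pass (A) and the E3-first pass (B); a candidate
#' survives only if an identical triple (same warhead canonical SMILES, same
#' E3 canonical SMILES, identical canonical linker) appears in both
#' directions. Survivors then go through the structural filters; passing
#' solutions are deduplicated by the (warhead, linker, E3) canonical triple
#' and returned in a stable order (descending warhead size, then descending
#' E3 size, then lexicographic linker SMILES). If none survive, a single
#' failure category is assigned.
#'
#' @param parent Degrader SMILES or `protac_mol`.
#' @param warhead_lib,e3_lib `fragment_library` objects.
#' @param protac_id Identifier carried into the report.
#' @param stereo Stereo mode for parent standardization.
#' @return A `decomp_report` with `status` (`"solved"`, `"failed"` or
#'   `"input_error"`), `solutions` and `failure_category`.
#' @examples
#' wl <- fragment_library("c1ccncc1", role = "warhead")
#' el <- fragment_library("C1CCNCC1", role = "e3_ligand")
#' rep <- bidirectional_decompose("c1ccc(nc1)CCCN1CCCCC1", wl, el)
#' rep$status
#' rep$solutions[[1]]$linker_smiles  # "CCC"
#' @export
bidirectional_decompose <- function(parent, warhead_lib, e3_lib,
                                    protac_id = NA_character_,
                                    stereo = "ignore") {
  stopifnot(inherits(warhead_lib, "fragment_library"),
            inherits(e3_lib, "fragment_library"))
  input_smiles <- if (inherits(parent, "protac_mol")) parent$smiles else
    as.character(parent)
  pmol <- tryCatch(as_protac_mol(parent, stereo = stereo),
                   error = function(e) e)
  if (inherits(pmol, "error")) {
    return(new_decomp_report(protac_id, input_smiles, status = "input_error",
                             solutions = list(),
                             failure_category = "input_error"))
  }
  pass_a <- decompose_pass(pmol, warhead_lib, e3_lib)
  pass_b <- decompose_pass(pmol, e3_lib, warhead_lib)
  keys_a <- vapply(pass_a$candidates, .candidate_key, character(1),
                   warhead_first = TRUE)
  keys_b <- vapply(pass_b$candidates, .candidate_key, character(1),
                   warhead_first = FALSE)
  shared <- intersect(keys_a, keys_b)
  consistent <- pass_a$candidates[match(shared, keys_a)]

  filtered <- lapply(consistent, apply_filters, parent = pmol)
  keep <- vapply(filtered, function(x) x$pass, logical(1))
  sols <- consistent[keep]

  if (length(sols) > 0) {
    triple <- vapply(sols, function(s)
      paste(s$first_smiles, s$linker_components, s$second_smiles,
            sep = "\r"), character(1))
    sols <- sols[!duplicated(triple)]
    ord <- order(-vapply(sols, `[[`, integer(1), "first_n_heavy"),
                 -vapply(sols, `[[`, integer(1), "second_n_heavy"),
                 vapply(sols, function(s) s$linker_components[1],
                        character(1)))
    sols <- sols[ord]
    solutions <- lapply(sols, function(s) list(
      warhead_id = s$first_id, warhead_smiles = s$first_smiles,
      warhead_atoms = s$first_atoms, warhead_n_heavy = s$first_n_heavy,
      e3_id = s$second_id, e3_smiles = s$second_smiles,
      e3_atoms = s$second_atoms, e3_n_heavy = s$second_n_heavy,
      linker_smiles = s$linker_components[1],
      linker_atoms = s$linker_atoms,
      n_heavy_linker = s$linker_n_heavy,
      n_rings_linker = s$linker_n_rings,
      found_in_pass_a = TRUE, found_in_pass_b = TRUE))
    return(new_decomp_report(protac_id, pmol$smiles, status = "solved",
                             solutions = solutions,
                             failure_category = NA_character_,
                             parent_n_heavy = pmol$n_heavy,
                             parent_n_rings = pmol$n_rings))
  }
  cat_fail <- categorize_failure(pass_a, pass_b, filtered)
  new_decomp_report(protac_id, pmol$smiles, status = "failed",
                    solutions = list(), failure_category = cat_fail,
                    parent_n_heavy = pmol$n_heavy,
                    parent_n_rings = pmol$n_rings)
}

new_decomp_report <- function(protac_id, protac_smiles, status, solutions,
                              failure_category, parent_n_heavy = NA_integer_,
                              parent_n_rings = NA_integer_) {
  structure(list(
    protac_id = protac_id,
    protac_smiles_canonical = protac_smiles,
    status = status,
    solutions = solutions,
    failure_category = failure_category,
    parent_n_heavy = parent_n_heavy,
    parent_n_rings = parent_n_rings
  ), class = "decomp_report")
}

#' @export
print.decomp_report <- function(x, ...) {
  cat(sprintf("<decomp_report> %s  [%s]\n",
              ifelse(is.na(x$protac_id), "", x$protac_id), x$status))
  cat("  ", x$protac_smiles_canonical, "\n", sep = "")
  if (x$status == "solved") {
    for (k in seq_along(x$solutions)) {
      s <- x$solutions[[k]]
      cat(sprintf("  solution %d:\n    warhead [%s]  %s\n    linker        %s\n    E3      [%s]  %s\n",
                  k, s$warhead_id, s$warhead_smiles, s$linker_smiles,
                  s$e3_id, s$e3_smiles))
    }
  } else {
    cat("  failure category:", x$failure_category, "\n")
  }
  invisible(x)
}

#' Tabulate a decomposition report
#'
#' One row per solution for solved reports, one row for failed ones;
#' the schema matches the batch driver's output files.
#' @param x A `decomp_report`.
#' @param ... Unused.
#' @export
as.data.frame.decomp_report <- function(x, ...) {
  base <- data.frame(
    protac_id = x$protac_id,
    protac_smiles = x$protac_smiles_canonical,
    status = x$status,
    n_solutions = length(x$solutions),
    stringsAsFactors = FALSE)
  if (length(x$solutions) == 0) {
    return(cbind(base, data.frame(
      solution_index = NA_integer_, warhead_smiles = NA_character_,
      linker_smiles = NA_character_, e3_smiles = NA_character_,
      warhead_id = NA_character_, e3_id = NA_character_,
      failure_category = x$failure_category, stringsAsFactors = FALSE)))
  }
  do.call(rbind, lapply(seq_along(x$solutions), function(k) {
    s <- x$solutions[[k]]
    cbind(base, data.frame(
      solution_index = k, warhead_smiles = s$warhead_smiles,
      linker_smiles = s$linker_smiles, e3_smiles = s$e3_smiles,
      warhead_id = s$warhead_id, e3_id = s$e3_id,
      failure_category = NA_character_, stringsAsFactors = FALSE))
  }))
}
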