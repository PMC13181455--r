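# Synthetic PROTAC-like molecules with known ground-truth decomposition.
# Fragment pools use small, well-known drug-like ring systems (azaarene
# warhead mimics, imide-type cereblon-binder mimics, alkyl/PEG/piperazine
# linkers) so every other module is testable without any download; real
# curated libraries are drop-ins via the custom-library path.

#' Built-in fixture fragment pools
#'
#' Small warhead-, linker- and E3-ligand-like fragment pools used by the
#' synthetic corpus generator. Warheads are fused azaarene cores (the kind
#' of hinge-binder chemotypes common in kinase-directed degraders); E3
#' entries are imide/glutarimide chemotypes mimicking cereblon binders
#' (including thalidomide itself); linkers are short alkyl, PEG-like and
#' piperazine chains.
#'
#' @return Named list with character vectors `warheads`, `linkers`, `e3s`.
#' @export
fixture_fragments <- function() {
  list(
    warheads = c(
      quinoline      = "c1ccc2ncccc2c1",
      aminoquinazoline = "Nc1ncnc2ccccc12",
      benzimidazole  = "c1ccc2[nH]cnc2c1",
      indole         = "c1ccc2c(c1)cc[nH]2",
      methylquinoline = "Cc1ccc2ncccc2c1"
    ),
    linkers = c(
      propyl     = "CCC",
      hexyl      = "CCCCCC",
      peg2       = "CCOCCOCC",
      etherethyl = "CCOCC",
      piperazine = "C1CNCCN1",
      methylene  = "C"
    ),
    e3s = c(
      thalidomide  = "O=C1CCC(N2C(=O)c3ccccc3C2=O)C(=O)N1",
      phthalimide  = "O=C1NC(=O)c2ccccc12",
      glutarimide  = "O=C1CCCC(=O)N1",
      dihydrouracil = "O=C1CCNC(=O)N1",
      benzamide    = "NC(=O)c1ccccc1"
    )
  )
}

# Atoms eligible as attachment sites: carbon or nitrogen with at least
# `need_h` implicit hydrogens.
attachment_sites <- function(mol, need_h = 1L) {
  which(mol$elem %in% c("C", "N") & mol$implicit_h >= need_h)
}

# Join standardized parts with new single bonds. `joins` is a data frame
# with columns part_a, atom_a, part_b, atom_b (part index into `parts`,
# atom index local to that part). Returns the canonical SMILES of the
# assembly.
join_molecules <- function(parts, joins) {
  offs <- cumsum(c(0L, vapply(parts, `[[`, integer(1), "n_heavy")))
  used <- integer(0)  # extra valence used per global atom
  elem <- unlist(lapply(parts, `[[`, "elem"))
  charge <- unlist(lapply(parts, `[[`, "charge"))
  implh <- unlist(lapply(parts, `[[`, "implicit_h"))
  bonds <- do.call(rbind, lapply(seq_along(parts), function(k) {
    b <- parts[[k]]$bonds
    if (nrow(b) == 0) return(b)
    data.frame(i = b$i + offs[k], j = b$j + offs[k], order = b$order)
  }))
  extra <- integer(length(elem))
  for (r in seq_len(nrow(joins))) {
    ga <- joins$atom_a[r] + offs[joins$part_a[r]]
    gb <- joins$atom_b[r] + offs[joins$part_b[r]]
    extra[ga] <- extra[ga] + 1L
    extra[gb] <- extra[gb] + 1L
    bonds <- rbind(bonds, data.frame(i = ga, j = gb, order = 1L))
  }
  bad <- which(extra > implh)
  if (length(bad))
    .pR_error(sprintf(
      "assembly error: atom %d (%s) lacks an available hydrogen for the new bond",
      bad[1], elem[bad[1]]), "protacR_assembly_error")
  txt <- mol_to_sdf_text(elem, charge, bonds)
  smi <- ob_convert(txt, "SDF", "CAN")
  if (!nzchar(smi))
    .pR_error("assembly produced an unparseable structure",
              "protacR_assembly_error")
  smi
}

#' Assemble a synthetic PROTAC from a known fragment triple
#'
#' Forms single bonds warhead-linker and linker-E3 at the given attachment
#' atoms and records the standardized parts as the ground truth.
#' Conservation invariants (heavy atoms, rings) hold by construction.
#'
#' @param warhead,linker,e3 SMILES strings or `protac_mol` objects.
#' @param wh_site,e3_site Attachment atom index on the warhead / E3 ligand
#'   (canonical atom order); `NULL` picks the first eligible atom.
#' @param linker_sites Integer pair of linker attachment atoms; the two
#'   sites must be distinct unless the linker has a single atom (which then
#'   needs two available hydrogens).
#' @param seed Optional bookkeeping seed stored on the object.
#' @return An object of class `synthetic_protac` with `protac_smiles`,
#'   `truth` (warhead/linker/E3 canonical SMILES) and the sites used.
#' @examples
#' sp <- assemble_protac("c1ccncc1", "CCC", "C1CCNCC1")
#' sp$protac_smiles
#' @export
assemble_protac <- function(warhead, linker, e3,
                            wh_site = NULL, linker_sites = NULL,
                            e3_site = NULL, seed = NA_integer_) {
  w <- as_protac_mol(warhead)
  l <- as_protac_mol(linker)
  e <- as_protac_mol(e3)
  if (is.null(wh_site)) wh_site <- attachment_sites(w)[1]
  if (is.null(e3_site)) e3_site <- attachment_sites(e)[1]
  if (is.null(linker_sites)) {
    ls <- attachment_sites(l)
    linker_sites <- if (l$n_heavy == 1L) c(ls[1], ls[1]) else
      c(ls[1], ls[length(ls)])
  }
  if (any(is.na(c(wh_site, e3_site, linker_sites))))
    .pR_error("no eligible attachment site", "protacR_assembly_error")
  if (linker_sites[1] == linker_sites[2] && l$n_heavy > 1L)
    .pR_error("linker attachment sites must be distinct",
              "protacR_assembly_error")
  need2 <- linker_sites[1] == linker_sites[2]
  if (need2 && l$implicit_h[linker_sites[1]] < 2L)
    .pR_error(sprintf(
      "assembly error: linker atom %d needs two available hydrogens",
      linker_sites[1]), "protacR_assembly_error")
  smi <- join_molecules(
    list(w, l, e),
    data.frame(part_a = c(1L, 2L), atom_a = c(wh_site, linker_sites[2]),
               part_b = c(2L, 3L), atom_b = c(linker_sites[1], e3_site)))
  pm <- standardize_molecule(smi)
  stopifnot(pm$n_heavy == w$n_heavy + l$n_heavy + e$n_heavy,
            pm$n_rings == w$n_rings + l$n_rings + e$n_rings)
  structure(list(
    protac_smiles = pm$smiles,
    truth = list(warhead_smiles = w$smiles, linker_smiles = l$smiles,
                 e3_smiles = e$smiles),
    sites = list(wh_site = wh_site, linker_sites = linker_sites,
                 e3_site = e3_site),
    seed = seed
  ), class = "synthetic_protac")
}

#' Seeded random corpus of synthetic PROTACs
#'
#' Reproducible sampling of (warhead, linker, E3) triples and valid
#' attachment sites; the same seed yields an identical corpus. Triples with
#' no valid attachment geometry are resampled (bounded retries, then
#' skipped with a warning).
#'
#' @param n Number of molecules.
#' @param seed Integer RNG seed.
#' @param warhead_pool,linker_pool,e3_pool SMILES character vectors
#'   (defaults: [fixture_fragments()]).
#' @param max_retry Retries per slot before skipping.
#' @return List of `synthetic_protac`, with ids `sp001`, ... as names.
#' @export
random_corpus <- function(n, seed, warhead_pool = NULL, linker_pool = NULL,
                          e3_pool = NULL, max_retry = 20L) {
  stopifnot(n >= 1)
  pools <- fixture_fragments()
  if (is.null(warhead_pool)) warhead_pool <- pools$warheads
  if (is.null(linker_pool)) linker_pool <- pools$linkers
  if (is.null(e3_pool)) e3_pool <- pools$e3s
  wmols <- lapply(warhead_pool, as_protac_mol)
  lmols <- lapply(linker_pool, as_protac_mol)
  emols <- lapply(e3_pool, as_protac_mol)
  withr::with_seed(seed, {
    out <- list()
    for (k in seq_len(n)) {
      sp <- NULL
      for (try in seq_len(max_retry)) {
        w <- wmols[[sample.int(length(wmols), 1)]]
        l <- lmols[[sample.int(length(lmols), 1)]]
        e <- emols[[sample.int(length(emols), 1)]]
        ws <- attachment_sites(w); es <- attachment_sites(e)
        ls1 <- attachment_sites(l)
        if (!length(ws) || !length(es) || !length(ls1)) next
        wh_site <- ws[sample.int(length(ws), 1)]
        e3_site <- es[sample.int(length(es), 1)]
        if (l$n_heavy == 1L) {
          if (l$implicit_h[ls1[1]] < 2L) next
          lsites <- c(ls1[1], ls1[1])
        } else {
          if (length(ls1) < 2) next
          lsites <- sort(sample(ls1, 2))
        }
        sp <- tryCatch(
          assemble_protac(w, l, e, wh_site = wh_site,
                          linker_sites = lsites, e3_site = e3_site,
                          seed = seed),
          error = function(err) NULL)
        if (!is.null(sp)) break
      }
      if (is.null(sp)) {
        warning(sprintf("corpus slot %d skipped after %d retries", k,
                        max_retry), call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- sp
    }
    names(out) <- sprintf("sp%03d", seq_along(out))
    out
  })
}

#' Adversarial fixtures for the failure taxonomy
#'
#' Fixed, deterministic cases engineered so that decomposition triggers
#' each failure category exactly once, plus a boundary-ambiguity case with
#' two valid solutions (terminal methylene assignable to either the
#' warhead or the linker). Each element carries the parent SMILES, the two
#' libraries to use, and the expected outcome.
#'
#' @return Named list of cases; each is a list with `protac_smiles`,
#'   `warhead_lib`, `e3_lib` and either `expected_category` or
#'   `expected_n_solutions`.
#' @export
adversarial_cases <- function() {
  f <- fixture_fragments()
  quin <- as_protac_mol(f$warheads[["quinoline"]])
  benz <- f$warheads[["benzimidazole"]]
  phth <- as_protac_mol(f$e3s[["phthalimide"]])
  dhu <- f$e3s[["dihydrouracil"]]
  pipz <- as_protac_mol(f$linkers[["piperazine"]])
  ccc <- as_protac_mol("CCC")

  base <- assemble_protac(quin, ccc, phth)
  wlib1 <- function(s) fragment_library(s, role = "warhead")
  elib1 <- function(s) fragment_library(s, role = "e3_ligand")

  cases <- list()

  # 1. warhead absent from the library
  cases$warhead_not_found <- list(
    protac_smiles = base$protac_smiles,
    warhead_lib = wlib1(benz), e3_lib = elib1(phth$smiles),
    expected_category = "warhead_not_found")

  # 2. E3 ligand absent
  cases$e3_not_found <- list(
    protac_smiles = base$protac_smiles,
    warhead_lib = wlib1(quin$smiles), e3_lib = elib1(dhu),
    expected_category = "e3_not_found")

  # 3. linker inconsistency between passes: the only warhead-library entry
  # (piperazine) matches a mid-molecule moiety, so removing it first splits
  # the degrader (pass A yields nothing), while the E3-first pass still
  # produces candidates -- no triple appears in both directions.
  quin_q <- attachment_sites(quin)[1]
  p_sites <- attachment_sites(pipz)
  pn <- p_sites[pipz$elem[p_sites] == "N"]
  mid <- join_molecules(
    list(quin, as_protac_mol("CC"), pipz, as_protac_mol("CC"), phth),
    data.frame(part_a = c(1L, 2L, 3L, 4L),
               atom_a = c(quin_q, 2L, pn[2], 2L),
               part_b = c(2L, 3L, 4L, 5L),
               atom_b = c(1L, pn[1], 1L, attachment_sites(phth)[1])))
  cases$linker_inconsistent <- list(
    protac_smiles = standardize_molecule(mid)$smiles,
    warhead_lib = wlib1(pipz$smiles), e3_lib = elib1(phth$smiles),
    expected_category = "linker_inconsistent")

  # 4. multiple linker fragments: macrocyclic architecture, warhead and E3
  # bridged by two independent chains; removing either moiety leaves a
  # connected remainder, but the final linker has two components.
  wa <- attachment_sites(quin)
  ea <- attachment_sites(phth)
  macro <- join_molecules(
    list(quin, as_protac_mol("CCC"), as_protac_mol("CCCC"), phth),
    data.frame(part_a = c(1L, 2L, 1L, 3L),
               atom_a = c(wa[1], 3L, wa[2], 4L),
               part_b = c(2L, 4L, 3L, 4L),
               atom_b = c(1L, ea[1], 1L, ea[2])))
  cases$multiple_linker_fragments <- list(
    protac_smiles = standardize_molecule(macro)$smiles,
    warhead_lib = wlib1(quin$smiles), e3_lib = elib1(phth$smiles),
    expected_category = "multiple_linker_fragments")

  # 5. count discrepancy: the linker loops back onto the warhead (two cut
  # bonds into the same moiety), creating a ring in the parent that no
  # fragment retains -- single linker, heavy atoms conserved, ring counts
  # not.
  chain <- as_protac_mol("CCCCC")
  loop <- join_molecules(
    list(quin, chain, phth),
    data.frame(part_a = c(1L, 1L, 2L),
               atom_a = c(wa[1], wa[2], 3L),
               part_b = c(2L, 2L, 3L),
               atom_b = c(1L, 5L, ea[1])))
  cases$count_discrepancy <- list(
    protac_smiles = standardize_molecule(loop)$smiles,
    warhead_lib = wlib1(quin$smiles), e3_lib = elib1(phth$smiles),
    expected_category = "count_discrepancy")

  # 6. boundary ambiguity: library holds both the bare core and the core
  # extended by the first linker methylene, so the boundary can be drawn on
  # either side -- two valid solutions.
  ext <- join_molecules(
    list(quin, as_protac_mol("C")),
    data.frame(part_a = 1L, atom_a = wa[1], part_b = 2L, atom_b = 1L))
  cases$boundary_ambiguity <- list(
    protac_smiles = base$protac_smiles,
    warhead_lib = fragment_library(c(quin$smiles, ext), role = "warhead"),
    e3_lib = elib1(phth$smiles),
    expected_n_solutions = 2L)

  cases
}

#' @export
print.synthetic_protac <- function(x, ...) {
  cat("<synthetic_protac> ", x$protac_smiles, "\n", sep = "")
  cat("  truth: W=", x$truth$warhead_smiles, "  L=", x$truth$linker_smiles,
      "  E3=", x$truth$e3_smiles, "\n", sep = "")
  invisible(x)
}
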