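# Molecule standardization layer.
#
# Molecules are held as light graph records ("protac_mol"): element vector,
# formal charges, a kekulized bond table, OpenBabel aromaticity flags and the
# OpenBabel canonical SMILES that serves as the identity key everywhere else
# in the package. SMILES parsing, canonicalization and SDF interconversion go
# through ChemmineR/ChemmineOB; only the bookkeeping on top is ours.

# Canonical-SMILES cache: OpenBabel conversion dominates runtime on large
# batches and the same fragments recur constantly.
.canon_cache <- new.env(parent = emptyenv())

.pR_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "protacR_error", "error")))
}

#' @noRd
ob_convert <- function(text, from, to) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, text),
    error = function(e) ""
  )
  # OpenBabel appends a title field (tab) and newline; strip both.
  out <- sub("[ \t].*$", "", sub("\n.*$", "", out))
  out
}

# Canonical SMILES of a single SMILES string ("" on parse failure).
canonical_smiles <- function(smiles) {
  key <- paste0("S\r", smiles)
  hit <- get0(key, envir = .canon_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  out <- ob_convert(smiles, "SMI", "CAN")
  assign(key, out, envir = .canon_cache)
  out
}

# Remove stereo descriptors (@, @@, /, \) from a SMILES string. [C@@H] -> [CH]
# keeps the explicit hydrogen count, so the constitution is unchanged.
strip_stereo <- function(smiles) {
  gsub("[@/\\\\]", "", smiles)
}

# Aromatic flag per atom, in order of appearance, scanned from a SMILES
# string (lowercase organic-subset atoms and lowercase bracket atoms are
# aromatic under the Daylight model OpenBabel writes).
.smiles_atom_arom <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  arom <- logical(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- chars[(i + 1L):(j - 1L)]
      sym <- body[grep("[A-Za-z]", body)[1]]  # first letter = element start
      arom <- c(arom, sym %in% c("c", "n", "o", "p", "s", "b"))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      arom <- c(arom, FALSE)  # Cl / Br
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      arom <- c(arom, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      arom <- c(arom, TRUE)
      i <- i + 1L
    } else {
      i <- i + 1L  # bonds, digits, ring closures, branches, dots
    }
  }
  arom
}

# Default valences used to derive implicit hydrogen counts from the
# kekulized bond table; hypervalent S/P pick the smallest allowed valence
# that covers the bond order sum.
.default_valence <- function(elem, bondsum) {
  allowed <- switch(elem,
    C = 4L, B = 3L, N = 3L, O = 2L, F = 1L, Cl = 1L, Br = 1L, I = 1L,
    Si = 4L,
    P = c(3L, 5L), S = c(2L, 4L, 6L),
    0L)
  ok <- allowed[allowed >= bondsum]
  if (length(ok) == 0) max(allowed) else ok[1]
}

.implicit_h <- function(elem, charge, bondsum) {
  adj <- ifelse(elem %in% c("N", "P", "O", "S"), charge,
                ifelse(elem == "C", -abs(charge), 0L))
  v <- vapply(seq_along(elem),
              function(i) .default_valence(elem[i], bondsum[i]), integer(1))
  pmax(0L, v + adj - bondsum)
}

# Single-atom molecules are handled directly from the SMILES token (the
# SDF round trip has no bond block to anchor on).
.parse_single_atom <- function(smiles) {
  body <- sub("^\\[", "", sub("\\]$", "", smiles))
  mm <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(H[0-9]*)?(\\+[0-9]*|-[0-9]*|\\++|-+)?$",
    body))[[1]]
  if (length(mm) == 0)
    .pR_error(sprintf("cannot parse SMILES: '%s'", smiles),
              "protacR_parse_error")
  elem0 <- mm[3]
  arom <- elem0 %in% c("c", "n", "o", "p", "s", "b")
  elem <- paste0(toupper(substring(elem0, 1, 1)), substring(elem0, 2))
  chg_tok <- mm[5]
  charge <- if (!nzchar(chg_tok)) 0L else {
    sign <- if (substring(chg_tok, 1, 1) == "+") 1L else -1L
    digits <- gsub("[+-]", "", chg_tok)
    if (nzchar(digits)) sign * as.integer(digits) else
      sign * nchar(chg_tok)
  }
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  g <- igraph::graph_from_data_frame(bonds[, c("i", "j")], directed = FALSE,
                                     vertices = data.frame(name = 1L))
  structure(list(
    smiles = smiles, elem = elem, charge = charge, bonds = bonds,
    arom_atom = arom, arom_bond = logical(0),
    implicit_h = .implicit_h(elem, charge, 0L),
    n_heavy = 1L, n_rings = 0L, n_components = 1L, graph = g
  ), class = "protac_mol")
}

# Parse a (canonical) SMILES into the internal graph record. Atom order in
# the SDF produced by OpenBabel follows the order of appearance in the
# SMILES, which lets the aromaticity scan line up with the atom block.
parse_molecule <- function(smiles_canonical) {
  if (length(.smiles_atom_arom(smiles_canonical)) == 1L)
    return(.parse_single_atom(smiles_canonical))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles_canonical)),
    error = function(e) NULL
  )
  if (is.null(sdf) || !methods::is(sdf, "SDFset"))
    .pR_error(sprintf("cannot parse SMILES: '%s'", smiles_canonical),
              "protacR_parse_error")
  sdf <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- gsub("_.*$", "", rownames(ab))
  code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else
    integer(length(elem))
  charge <- ifelse(code == 0L | code == 4L, 0L, 4L - code)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  n <- length(elem)
  arom_atom <- .smiles_atom_arom(smiles_canonical)
  if (length(arom_atom) != n) arom_atom <- rep(FALSE, n)  # defensive
  g <- igraph::graph_from_data_frame(
    bonds[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  ncomp <- igraph::count_components(g)
  arom_bond <- logical(nrow(bonds))
  if (nrow(bonds) > 0 && any(arom_atom)) {
    br <- igraph::bridges(g)
    is_bridge <- logical(nrow(bonds))
    if (length(br)) is_bridge[as.integer(br)] <- TRUE
    arom_bond <- arom_atom[bonds$i] & arom_atom[bonds$j] & !is_bridge
  }
  bondsum <- integer(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      bondsum[bonds$i[k]] <- bondsum[bonds$i[k]] + bonds$order[k]
      bondsum[bonds$j[k]] <- bondsum[bonds$j[k]] + bonds$order[k]
    }
  }
  structure(list(
    smiles = smiles_canonical,
    elem = elem,
    charge = charge,
    bonds = bonds,
    arom_atom = arom_atom,
    arom_bond = arom_bond,
    implicit_h = .implicit_h(elem, charge, bondsum),
    n_heavy = n,
    n_rings = as.integer(nrow(bonds) - n + ncomp),
    n_components = as.integer(ncomp),
    graph = g
  ), class = "protac_mol")
}

#' Standardize a molecule from SMILES
#'
#' Canonicalizes a SMILES string with OpenBabel, keeps the largest covalently
#' bonded component (salt/counter-ion stripping) and returns the parsed
#' molecule record used throughout the package. Standardization is
#' idempotent: standardizing the canonical SMILES of the result returns the
#' same record.
#'
#' @param smiles A single non-empty SMILES string.
#' @param stereo `"ignore"` (default) strips stereo descriptors before
#'   canonicalization, so enantiomers share one canonical form; `"strict"`
#'   keeps them.
#' @return An object of class `protac_mol` with elements `smiles` (canonical
#'   SMILES), `n_heavy`, `n_rings`, the bond table and per-atom annotations.
#' @examples
#' m <- standardize_molecule("OCC")
#' m$smiles          # same canonical form as "CCO"
#' m$n_heavy         # 3
#' standardize_molecule("CCO.[Na+]")$n_heavy  # largest component kept
#' @export
standardize_molecule <- function(smiles, stereo = c("ignore", "strict")) {
  stereo <- match.arg(stereo)
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    .pR_error("'smiles' must be a single non-empty string",
              "protacR_input_error")
  smi <- trimws(smiles)
  if (stereo == "ignore") smi <- strip_stereo(smi)
  can <- canonical_smiles(smi)
  if (!nzchar(can))
    .pR_error(sprintf("cannot parse SMILES: '%s'", smiles),
              "protacR_parse_error")
  comps <- strsplit(can, ".", fixed = TRUE)[[1]]
  if (length(comps) > 1) {
    sizes <- vapply(comps, function(x) length(.smiles_atom_arom(x)),
                    integer(1))
    can <- canonical_smiles(comps[which.max(sizes)])
  }
  mol <- parse_molecule(can)
  mol
}

#' @export
print.protac_mol <- function(x, ...) {
  cat("<protac_mol> ", x$smiles, "\n", sep = "")
  cat("  heavy atoms: ", x$n_heavy, "   rings (SSSR): ", x$n_rings,
      "   aromatic atoms: ", sum(x$arom_atom), "\n", sep = "")
  invisible(x)
}

# Coerce SMILES / protac_mol to protac_mol.
as_protac_mol <- function(x, stereo = "ignore") {
  if (inherits(x, "protac_mol")) return(x)
  standardize_molecule(x, stereo = stereo)
}

# ---- subgraph extraction -------------------------------------------------

# V2000 SDF text for an explicit atom/bond table (zeroed coordinates);
# implicit hydrogens are re-derived by OpenBabel from valence and charge.
mol_to_sdf_text <- function(elem, charge, bonds) {
  na <- length(elem)
  nb <- nrow(bonds)
  hdr <- c("", "  protacR", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atoms <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, elem)
  bl <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$i, bonds$j, bonds$order)
  } else character(0)
  ci <- which(charge != 0L)
  chg <- if (length(ci)) {
    sprintf("M  CHG%3d%s", length(ci),
            paste0(sprintf("%4d%4d", ci, charge[ci]), collapse = ""))
  } else character(0)
  paste(c(hdr, atoms, bl, chg, "M  END", "$$$$"), collapse = "\n")
}

# Induced subgraph of `mol` on `atoms` (kept in ascending parent-index
# order) as a matchable `protac_mol`; aromaticity and charges are inherited
# from the parent perception, i.e. the remainder is matched "as it sits in
# the parent". `parent_atoms` maps local indices back to the parent.
induced_submol <- function(mol, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  inset <- logical(mol$n_heavy); inset[atoms] <- TRUE
  bsel <- inset[mol$bonds$i] & inset[mol$bonds$j]
  remap <- match(seq_len(mol$n_heavy), atoms)
  bonds <- data.frame(i = remap[mol$bonds$i[bsel]],
                      j = remap[mol$bonds$j[bsel]],
                      order = mol$bonds$order[bsel])
  n <- length(atoms)
  g <- igraph::graph_from_data_frame(
    bonds[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  structure(list(
    smiles = NA_character_,
    elem = mol$elem[atoms],
    charge = mol$charge[atoms],
    bonds = bonds,
    arom_atom = mol$arom_atom[atoms],
    arom_bond = mol$arom_bond[bsel],
    implicit_h = mol$implicit_h[atoms],
    n_heavy = n,
    n_rings = as.integer(nrow(bonds) - n + igraph::count_components(g)),
    n_components = as.integer(igraph::count_components(g)),
    graph = g,
    parent_atoms = atoms
  ), class = "protac_mol")
}

# Connected components of the induced subgraph on `atoms`, as parent
# atom-index vectors, ordered by descending size then smallest atom index.
induced_components <- function(mol, atoms) {
  sub <- induced_submol(mol, atoms)
  memb <- igraph::components(sub$graph)$membership
  comps <- lapply(sort(unique(memb)), function(cid)
    sub$parent_atoms[which(memb == cid)])
  ord <- order(-lengths(comps), vapply(comps, min, integer(1)))
  comps[ord]
}

# Canonical SMILES of the induced subgraph on `atoms` (one string per
# connected component, deterministically ordered: descending heavy-atom
# count, ties lexicographic).
subgraph_components <- function(mol, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  if (length(atoms) == 0) return(list())
  keep <- atoms
  inset <- logical(mol$n_heavy); inset[keep] <- TRUE
  bsel <- mol$bonds[inset[mol$bonds$i] & inset[mol$bonds$j], , drop = FALSE]
  remap <- match(seq_len(mol$n_heavy), keep)
  # component membership on the induced subgraph
  gg <- igraph::graph_from_data_frame(
    data.frame(i = remap[bsel$i], j = remap[bsel$j]),
    directed = FALSE, vertices = data.frame(name = seq_along(keep)))
  memb <- igraph::components(gg)$membership
  out <- lapply(sort(unique(memb)), function(cid) {
    sub <- which(memb == cid)            # indices into keep
    orig <- keep[sub]
    inssub <- logical(mol$n_heavy); inssub[orig] <- TRUE
    bs <- mol$bonds[inssub[mol$bonds$i] & inssub[mol$bonds$j], , drop = FALSE]
    remap2 <- match(seq_len(mol$n_heavy), orig)
    bs2 <- data.frame(i = remap2[bs$i], j = remap2[bs$j], order = bs$order)
    txt <- mol_to_sdf_text(mol$elem[orig], mol$charge[orig], bs2)
    key <- paste0("D\r", txt)
    smi <- get0(key, envir = .canon_cache, inherits = FALSE)
    if (is.null(smi)) {
      smi <- ob_convert(txt, "SDF", "CAN")
      assign(key, smi, envir = .canon_cache)
    }
    list(atoms = orig, smiles = smi, n_heavy = length(orig),
         n_rings = nrow(bs2) - length(orig) + 1L)
  })
  ord <- order(-vapply(out, `[[`, integer(1), "n_heavy"),
               vapply(out, `[[`, character(1), "smiles"))
  out[ord]
}
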