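# Physicochemical descriptors for linkerology analysis: size (MW),
# hydrophobicity (carbon count), polarity (TPSA, HBD, HBA) and flexibility
# (Kier's PHI). MW/TPSA/HBD/HBA come from OpenBabel's standard descriptor
# implementations (MW is the average molecular weight including implicit
# hydrogens; HBD and HBA1 are OpenBabel's donor/acceptor definitions); the
# Kier index is computed here from the molecular graph.

# Hall-Kier alpha contributions by element and hybridization, relative to
# sp3 carbon (covalent-radius ratios; Kier 1989).
.kier_alpha_tab <- list(
  C  = c(sp3 = 0.00,  sp2 = -0.13, sp = -0.22),
  N  = c(sp3 = -0.04, sp2 = -0.20, sp = -0.29),
  O  = c(sp3 = -0.04, sp2 = -0.20, sp = -0.20),
  F  = c(sp3 = -0.07, sp2 = -0.07, sp = -0.07),
  P  = c(sp3 = 0.43,  sp2 = 0.30,  sp = 0.30),
  S  = c(sp3 = 0.35,  sp2 = 0.22,  sp = 0.22),
  Cl = c(sp3 = 0.29,  sp2 = 0.29,  sp = 0.29),
  Br = c(sp3 = 0.48,  sp2 = 0.48,  sp = 0.48),
  I  = c(sp3 = 0.73,  sp2 = 0.73,  sp = 0.73)
)

# Per-atom hybridization from the kekulized bond table: triple bond or two
# cumulated double bonds -> sp; any double or aromatic bond -> sp2; else sp3.
.hybridization <- function(mol) {
  n <- mol$n_heavy
  n_double <- integer(n); n_triple <- integer(n); touches_arom <- logical(n)
  b <- mol$bonds
  if (nrow(b) > 0) {
    for (k in seq_len(nrow(b))) {
      if (b$order[k] == 2L && !mol$arom_bond[k]) {
        n_double[b$i[k]] <- n_double[b$i[k]] + 1L
        n_double[b$j[k]] <- n_double[b$j[k]] + 1L
      } else if (b$order[k] == 3L) {
        n_triple[b$i[k]] <- n_triple[b$i[k]] + 1L
        n_triple[b$j[k]] <- n_triple[b$j[k]] + 1L
      }
      if (mol$arom_bond[k])
        touches_arom[c(b$i[k], b$j[k])] <- TRUE
    }
  }
  ifelse(n_triple > 0 | n_double >= 2, "sp",
         ifelse(n_double > 0 | touches_arom | mol$arom_atom, "sp2", "sp3"))
}

.kier_alpha <- function(mol) {
  hyb <- .hybridization(mol)
  sum(vapply(seq_len(mol$n_heavy), function(i) {
    tab <- .kier_alpha_tab[[mol$elem[i]]]
    if (is.null(tab)) 0 else unname(tab[hyb[i]])
  }, numeric(1)))
}

#' Kier molecular flexibility index (PHI)
#'
#' Computes the Kier flexibility index
#' \eqn{\Phi = {}^1\kappa_\alpha \, {}^2\kappa_\alpha / A} from the
#' alpha-modified kappa shape indices, with \eqn{A} the heavy-atom count,
#' \eqn{{}^1P} the bond count and \eqn{{}^2P} the number of two-bond paths:
#' \deqn{{}^1\kappa_\alpha = (A+\alpha)(A+\alpha-1)^2/({}^1P+\alpha)^2}
#' \deqn{{}^2\kappa_\alpha = (A+\alpha-1)(A+\alpha-2)^2/({}^2P+\alpha)^2}
#' \eqn{\alpha} sums Hall-Kier covalent-radius contributions over atoms.
#' On an unbranched sp3 alkane of A atoms PHI reduces to A-1. Molecules
#' with fewer than three heavy atoms have no two-bond path and PHI is
#' reported as 0.
#'
#' @param mol SMILES string or `protac_mol`.
#' @return The flexibility index (dimensionless, >= 0).
#' @examples
#' kier_phi("CCCC")  # 3
#' @export
kier_phi <- function(mol) {
  mol <- as_protac_mol(mol)
  A <- mol$n_heavy
  P1 <- nrow(mol$bonds)
  deg <- igraph::degree(mol$graph)
  P2 <- sum(choose(deg, 2))
  if (A < 3 || P1 == 0 || P2 == 0) return(0)
  a <- .kier_alpha(mol)
  k1 <- (A + a) * (A + a - 1)^2 / (P1 + a)^2
  k2 <- (A + a - 1) * (A + a - 2)^2 / (P2 + a)^2
  max(0, k1 * k2 / A)
}

#' Compute the linkerology descriptor record for one molecule
#'
#' Returns the six descriptors used for linker structure-activity profiling
#' -- MW (average molecular weight, Da), nC (carbon count), TPSA
#' (topological polar surface area, A^2), HBD, HBA and PHI (Kier
#' flexibility) -- plus heavy-atom and SSSR ring counts.
#'
#' @param mol SMILES string or `protac_mol` (standardized, >= 1 heavy atom).
#' @return One-row data frame with columns `mw`, `nC`, `tpsa`, `hbd`,
#'   `hba`, `phi`, `n_heavy`, `n_rings`.
#' @examples
#' compute_descriptors("c1ccccc1")  # tpsa 0, nC 6, hbd 0
#' @export
compute_descriptors <- function(mol) {
  mol <- as_protac_mol(mol)
  obmol <- ChemmineOB::forEachMol("SMILES", mol$smiles, identity)
  p <- ChemmineOB::prop_OB(obmol)
  data.frame(
    mw = as.numeric(p$MW),
    nC = sum(mol$elem == "C"),
    tpsa = as.numeric(p$TPSA),
    hbd = as.integer(p$HBD),
    hba = as.integer(p$HBA1),
    phi = kier_phi(mol),
    n_heavy = mol$n_heavy,
    n_rings = mol$n_rings
  )
}

#' Descriptor table for a set of molecules, with group means
#'
#' One descriptor row per molecule plus per-label group means. Labels are
#' opaque strings supplied by the user (e.g. degradation-efficacy classes
#' from experimental data); without labels a single overall mean is
#' reported.
#'
#' @param molecules Character vector of SMILES (or list of `protac_mol`).
#' @param labels Optional character vector aligned 1:1 with `molecules`.
#' @param ids Optional identifiers (default `m1`, `m2`, ...).
#' @return An object of class `descriptor_profile`: list with `descriptors`
#'   (one row per molecule) and `group_means`.
#' @export
profile_set <- function(molecules, labels = NULL, ids = NULL) {
  n <- length(molecules)
  if (n < 1)
    .pR_error("at least one molecule is required", "protacR_input_error")
  if (!is.null(labels) && length(labels) != n)
    .pR_error("'labels' must align 1:1 with 'molecules'",
              "protacR_input_error")
  if (is.null(ids)) ids <- paste0("m", seq_len(n))
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    mol <- as_protac_mol(if (is.list(molecules)) molecules[[k]] else
      molecules[k])
    rows[[k]] <- cbind(
      data.frame(id = ids[k], smiles = mol$smiles,
                 stringsAsFactors = FALSE),
      compute_descriptors(mol))
  }
  desc <- do.call(rbind, rows)
  if (!is.null(labels)) desc$label <- as.character(labels)
  grp <- if (is.null(labels)) rep("(all)", n) else as.character(labels)
  num_cols <- c("mw", "nC", "tpsa", "hbd", "hba", "phi", "n_heavy",
                "n_rings")
  gm <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- desc[grp == g, num_cols, drop = FALSE]
    cbind(data.frame(label = g, n = sum(grp == g),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(sel))))
  }))
  structure(list(descriptors = desc, group_means = gm),
            class = "descriptor_profile")
}

#' @export
print.descriptor_profile <- function(x, ...) {
  cat(sprintf("<descriptor_profile> %d molecules\n", nrow(x$descriptors)))
  print(utils::head(x$descriptors, 10), digits = 4)
  cat("group means:\n")
  print(x$group_means, digits = 4)
  invisible(x)
}

#' Write a descriptor profile to CSV
#' @param x A `descriptor_profile`.
#' @param path Output CSV path (group means are appended to
#'   `<path>` with suffix `_group_means.csv` stripped-in before the
#'   extension when `group_path` is NULL).
#' @param group_path Optional separate path for the group-mean table.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path, group_path = NULL) {
  stopifnot(inherits(x, "descriptor_profile"))
  utils::write.csv(x$descriptors, path, row.names = FALSE)
  if (is.null(group_path))
    group_path <- sub("(\\.[^.]+)?$", "_group_means.csv", path)
  utils::write.csv(x$group_means, group_path, row.names = FALSE)
  invisible(path)
}
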