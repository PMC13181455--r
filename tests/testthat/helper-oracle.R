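# Brute-force two-cut oracle, independent of the match-and-subtract engine:
# enumerate all pairs of acyclic single bonds of the parent, cut both, keep
# partitions whose two end pieces are canonical-equal to library members
# and whose middle piece is the linker. By construction the linker is a
# single nonempty component and heavy-atom/ring conservation hold (cutting
# two bridges destroys no ring), i.e. the same filters the engine applies.

oracle_decompose <- function(parent_smiles, warhead_smiles, e3_smiles) {
  mol <- standardize_molecule(parent_smiles)
  wset <- vapply(warhead_smiles, function(s) standardize_molecule(s)$smiles,
                 character(1))
  eset <- vapply(e3_smiles, function(s) standardize_molecule(s)$smiles,
                 character(1))
  b <- mol$bonds
  n <- mol$n_heavy
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], k)
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], k)
  }
  comp_of <- function(start, dropped) {
    seen <- logical(n); seen[start] <- TRUE; queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in adj[[v]]) {
        if (k %in% dropped) next
        w <- if (b$i[k] == v) b$j[k] else b$i[k]
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    which(seen)
  }
  is_bridge <- vapply(seq_len(nrow(b)), function(k)
    !(b$j[k] %in% comp_of(b$i[k], k)), logical(1))
  single_bridges <- which(is_bridge & b$order == 1L)
  sols <- character(0)
  out <- list()
  if (length(single_bridges) >= 2) {
    pairs <- utils::combn(single_bridges, 2)
    for (p in seq_len(ncol(pairs))) {
      k1 <- pairs[1, p]; k2 <- pairs[2, p]
      dropped <- c(k1, k2)
      ends <- c(b$i[k1], b$j[k1], b$i[k2], b$j[k2])
      comps <- list()
      assigned <- integer(0)
      for (v in ends) {
        if (v %in% assigned) next
        cc <- comp_of(v, dropped)
        assigned <- c(assigned, cc)
        comps[[length(comps) + 1L]] <- cc
      }
      if (length(comps) != 3) next  # the two cuts did not trisect
      touches <- vapply(comps, function(cc)
        sum(c(b$i[k1], b$j[k1]) %in% cc) +
        sum(c(b$i[k2], b$j[k2]) %in% cc), integer(1))
      mid <- which(touches == 2)
      if (length(mid) != 1) next
      endc <- comps[-mid]
      smi <- vapply(c(endc, comps[mid]), function(cc)
        subgraph_components(mol, cc)[[1]]$smiles, character(1))
      for (ord in list(c(1, 2), c(2, 1))) {
        w <- smi[ord[1]]; e <- smi[ord[2]]; l <- smi[3]
        if (w %in% wset && e %in% eset) {
          key <- paste(w, l, e, sep = "\r")
          if (!key %in% sols) {
            sols <- c(sols, key)
            out[[length(out) + 1L]] <- list(warhead_smiles = w,
                                            linker_smiles = l,
                                            e3_smiles = e)
          }
        }
      }
    }
  }
  out
}

solution_keys <- function(solutions) {
  sort(vapply(solutions, function(s)
    paste(s$warhead_smiles, s$linker_smiles, s$e3_smiles, sep = "\r"),
    character(1)))
}
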