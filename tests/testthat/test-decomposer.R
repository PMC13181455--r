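# The worked example throughout: P1 = pyridine--CH2CH2CH2--piperidine.

test_that("find_matches enumerates symmetry-distinct induced embeddings", {
  sites <- find_matches(p1_smiles, "c1ccncc1")
  expect_length(sites, 1L)
  expect_length(sites[[1]]$atoms, 6L)
  expect_equal(nrow(sites[[1]]$cut_bonds), 1L)

  expect_length(find_matches("c1ccccc1", "c1ccncc1"), 0L)

  pip <- find_matches(p1_smiles, "C1CCNCC1")
  expect_length(pip, 1L)
  expect_equal(nrow(pip[[1]]$cut_bonds), 1L)

  # a fragment as large as the parent never matches
  expect_length(find_matches("c1ccncc1", "c1ccncc1"), 0L)
})

test_that("matching is induced: embeddings with chord bonds are rejected", {
  # pentane in methylcyclopentane: only the two methyl-containing paths
  # qualify; the pure ring subset induces a 5-cycle (extra chord) and is
  # rejected, where plain monomorphism matching would accept it
  mcp <- standardize_molecule("CC1CCCC1")
  methyl <- which(tabulate(c(mcp$bonds$i, mcp$bonds$j), mcp$n_heavy) == 1L)
  sets <- find_matches(mcp, "CCCCC")
  expect_length(sets, 2L)
  expect_true(all(vapply(sets, function(s) methyl %in% s$atoms, logical(1))))
  # benzene is not an induced subgraph of the pyridine-containing ring
  expect_length(find_matches(p1_smiles, "c1ccccc1"), 0L)
})

test_that("subtract_fragment returns canonical remainders and flags degeneracy", {
  p1 <- standardize_molecule(p1_smiles)
  site <- find_matches(p1, "c1ccncc1")[[1]]
  rem <- subtract_fragment(p1, site)
  expect_length(rem, 1L)
  expect_identical(rem[[1]]$smiles, standardize_molecule("CCCN1CCCCC1")$smiles)
  expect_equal(rem[[1]]$n_heavy, 9L)

  # cutting an internal chain atom disconnects the molecule
  chain <- standardize_molecule("CCCCC")
  mid <- list(fragment_id = NA, atoms = 3L,
              cut_bonds = data.frame(inside = 3L, outside = c(2L, 4L)))
  expect_length(subtract_fragment(chain, mid), 2L)

  all_atoms <- list(fragment_id = NA, atoms = seq_len(p1$n_heavy),
                    cut_bonds = data.frame())
  expect_error(subtract_fragment(p1, all_atoms),
               class = "protacR_degenerate_error")
})

test_that("decompose_pass enumerates candidates and records its stage", {
  p1 <- standardize_molecule(p1_smiles)
  pass <- decompose_pass(p1, p1_wlib(), p1_elib())
  expect_length(pass$candidates, 1L)
  expect_identical(pass$candidates[[1]]$linker_components, "CCC")
  expect_true(pass$first_matched && pass$second_matched)

  naph <- fragment_library("c1ccc2ccccc2c1", role = "warhead")
  pass2 <- decompose_pass(p1, naph, p1_elib())
  expect_length(pass2$candidates, 0L)
  expect_false(pass2$first_matched)

  # boundary ambiguity: pyridine vs methylpyridine-like warhead
  two <- suppressWarnings(fragment_library(c("c1ccncc1", "Cc1ccccn1"),
                                           role = "warhead"))
  pass3 <- decompose_pass(p1, two, p1_elib())
  linkers <- sort(vapply(pass3$candidates, function(x)
    x$linker_components[1], character(1)))
  expect_identical(linkers, c("CC", "CCC"))
})

test_that("bidirectional decomposition solves, fails and enumerates correctly", {
  rep <- bidirectional_decompose(p1_smiles, p1_wlib(), p1_elib(),
                                 protac_id = "P1")
  expect_s3_class(rep, "decomp_report")
  expect_identical(rep$status, "solved")
  expect_length(rep$solutions, 1L)
  s <- rep$solutions[[1]]
  expect_identical(s$linker_smiles, "CCC")
  expect_identical(s$warhead_smiles, standardize_molecule("c1ccncc1")$smiles)
  expect_identical(s$e3_smiles, standardize_molecule("C1CCNCC1")$smiles)
  expect_true(s$found_in_pass_a && s$found_in_pass_b)

  naph <- fragment_library("c1ccc2ccccc2c1", role = "warhead")
  rep2 <- bidirectional_decompose(p1_smiles, naph, p1_elib())
  expect_identical(rep2$status, "failed")
  expect_identical(rep2$failure_category, "warhead_not_found")

  two <- suppressWarnings(fragment_library(c("c1ccncc1", "Cc1ccccn1"),
                                           role = "warhead"))
  rep3 <- bidirectional_decompose(p1_smiles, two, p1_elib())
  expect_identical(rep3$status, "solved")
  expect_length(rep3$solutions, 2L)
  # stable ordering: larger warhead first
  expect_true(rep3$solutions[[1]]$warhead_n_heavy >=
              rep3$solutions[[2]]$warhead_n_heavy)

  bad <- bidirectional_decompose("][", p1_wlib(), p1_elib())
  expect_identical(bad$status, "input_error")
})

test_that("solution invariants: conservation and atom-set disjointness", {
  two <- suppressWarnings(fragment_library(c("c1ccncc1", "Cc1ccccn1"),
                                           role = "warhead"))
  rep <- bidirectional_decompose(p1_smiles, two, p1_elib())
  parent <- standardize_molecule(p1_smiles)
  for (s in rep$solutions) {
    expect_length(intersect(s$warhead_atoms, s$e3_atoms), 0)
    expect_length(intersect(s$warhead_atoms, s$linker_atoms), 0)
    expect_equal(s$warhead_n_heavy + s$n_heavy_linker + s$e3_n_heavy,
                 parent$n_heavy)
  }
})

test_that("apply_filters reports every violation, not just the first", {
  parent <- standardize_molecule(p1_smiles)
  good <- decompose_pass(parent, p1_wlib(), p1_elib())$candidates[[1]]
  f <- apply_filters(good, parent)
  expect_true(f$pass)
  expect_length(f$violations, 0L)

  split_linker <- good
  split_linker$linker_components <- c("C", "CC")
  f2 <- apply_filters(split_linker, parent)
  expect_false(f2$pass)
  expect_true("multiple_linker_fragments" %in% f2$violations)

  double_count <- good
  double_count$first_n_heavy <- double_count$first_n_heavy + 1L
  f3 <- apply_filters(double_count, parent)
  expect_false(f3$pass)
  expect_true("count_discrepancy" %in% f3$violations)

  both <- good
  both$linker_components <- c("C", "CC")
  both$first_n_rings <- both$first_n_rings + 1L
  f4 <- apply_filters(both, parent)
  expect_setequal(f4$violations,
                  c("multiple_linker_fragments", "count_discrepancy"))
})

test_that("categorize_failure refuses to run when solutions exist", {
  expect_error(
    categorize_failure(list(first_matched = TRUE),
                       list(first_matched = TRUE),
                       list(list(pass = TRUE, violations = character(0)))),
    class = "protacR_contract_error")
})

test_that("directional symmetry: swapping libraries swaps the labels", {
  wl <- p1_wlib(); el <- p1_elib()
  fwd <- bidirectional_decompose(p1_smiles, wl, el)
  swl <- fragment_library("C1CCNCC1", role = "warhead")
  sel <- fragment_library("c1ccncc1", role = "e3_ligand")
  rev <- bidirectional_decompose(p1_smiles, swl, sel)
  expect_identical(rev$status, "solved")
  expect_identical(rev$solutions[[1]]$warhead_smiles,
                   fwd$solutions[[1]]$e3_smiles)
  expect_identical(rev$solutions[[1]]$e3_smiles,
                   fwd$solutions[[1]]$warhead_smiles)
  expect_identical(rev$solutions[[1]]$linker_smiles,
                   fwd$solutions[[1]]$linker_smiles)
})

test_that("runs are deterministic and library growth is monotone", {
  two <- suppressWarnings(fragment_library(c("c1ccncc1", "Cc1ccccn1"),
                                           role = "warhead"))
  r1 <- bidirectional_decompose(p1_smiles, two, p1_elib())
  r2 <- bidirectional_decompose(p1_smiles, two, p1_elib())
  expect_identical(r1, r2)

  # adding a fragment never removes a previously found solution
  small <- p1_wlib()
  before <- bidirectional_decompose(p1_smiles, small, p1_elib())
  after <- bidirectional_decompose(p1_smiles, two, p1_elib())
  keys_before <- solution_keys(before$solutions)
  keys_after <- solution_keys(after$solutions)
  expect_true(all(keys_before %in% keys_after))
  expect_gt(length(keys_after), length(keys_before))
})
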