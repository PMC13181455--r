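# Shared fixtures, built once per test run (corpus generation and
# decomposition dominate suite runtime).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  hit <- get0(key, envir = .fixture_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  assign(key, val, envir = .fixture_cache)
  val
}

# The P1 worked example: pyridine -- propyl -- piperidine.
p1_smiles <- "c1ccc(nc1)CCCN1CCCCC1"
p1_wlib <- function() fragment_library("c1ccncc1", role = "warhead")
p1_elib <- function() fragment_library("C1CCNCC1", role = "e3_ligand")

test_corpus <- function(n = 200, seed = 42) {
  cached(sprintf("corpus_%d_%d", n, seed), random_corpus(n, seed))
}

# Per-molecule truth decomposition of the corpus (round-trip workhorse).
test_roundtrip_reports <- function(n = 200, seed = 42) {
  cached(sprintf("roundtrip_%d_%d", n, seed), {
    lapply(test_corpus(n, seed), function(sp) {
      wl <- suppressWarnings(
        fragment_library(sp$truth$warhead_smiles, role = "warhead"))
      el <- suppressWarnings(
        fragment_library(sp$truth$e3_smiles, role = "e3_ligand"))
      bidirectional_decompose(sp$protac_smiles, wl, el)
    })
  })
}

test_adversarial <- function() cached("adversarial", adversarial_cases())

# Small pools whose assemblies stay at or below 30 heavy atoms, for the
# exhaustive-oracle comparison.
oracle_pools <- function() {
  f <- fixture_fragments()
  list(
    warheads = f$warheads[c("quinoline", "benzimidazole", "indole")],
    linkers = f$linkers[c("propyl", "hexyl", "etherethyl", "methylene")],
    e3s = f$e3s[c("phthalimide", "glutarimide", "dihydrouracil")]
  )
}
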