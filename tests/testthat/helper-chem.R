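# Shared fixtures and independent oracles for the test suite.

# Naive bit-by-bit Tanimoto, independent of the package's vectorized path.
popcount_tanimoto <- function(a, b) {
  stopifnot(a$n_bits == b$n_bits)
  inter <- 0L
  uni <- 0L
  for (i in seq_len(a$n_bits)) {
    if (a$bits[i] && b$bits[i]) inter <- inter + 1L
    if (a$bits[i] || b$bits[i]) uni <- uni + 1L
  }
  if (uni == 0L) 0 else inter / uni
}

# Reference ligand SMILES used across tests (from the packaged library).
ref_smiles <- function(id) {
  lib <- load_reference_library(validate = FALSE)
  lib$smiles[match(id, lib$id)]
}

# A small fragment library assembled directly: two single-marker headers,
# three bodies.  Used for exhaustive-enumeration comparisons.
tiny_library <- function() {
  headers <- list(
    fragment_ligand("Cc1ccccc1")[[2]],   # *c1ccccc1
    fragment_ligand("Cc1ccncc1")[[2]]    # *c1ccncc1
  )
  stopifnot(vapply(headers, function(h) h$n_attach, integer(1)) == c(1L, 1L))
  bodies <- lapply(c("C", "CC", "N"), function(s) {
    structure(list(molecule = canonicalize(s), parent_id = "tiny"),
              class = "fragment_body")
  })
  structure(list(headers = headers, bodies = bodies,
                 n_kl = 2L, n_fl = 5L, n_df = 0L, n_sl = 5L),
            class = "fragment_library")
}

# Exhaustive minimum over every header x bodies assignment of a library
# (single-marker headers assumed), using the same public evaluate().
brute_force_minimum <- function(lib, scorer) {
  best <- Inf
  for (h in lib$headers) {
    combos <- expand.grid(rep(list(seq_along(lib$bodies)), h$n_attach))
    for (r in seq_len(nrow(combos))) {
      sol <- structure(list(header = h,
                            bodies = lib$bodies[as.integer(combos[r, ])]),
                       class = "sa_solution")
      e <- evaluate(sol, scorer)
      if (e < best) best <- e
    }
  }
  best
}

# Pool of small ligands for randomized library generation.
small_ligand_pool <- c(
  "Cc1ccccc1", "CCc1ccncc1", "Cc1ccco1", "CCOc1ccccc1", "Cc1cccs1",
  "NCc1ccccc1", "OCc1ccco1", "Clc1ccc(C)cc1", "Cc1ccncc1C", "COc1ccccc1")

random_small_library <- function() {
  n <- sample(2:3, 1)
  build_library(as.list(sample(small_ligand_pool, n)))
}
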