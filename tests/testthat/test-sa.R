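# Simulated-annealing search: representation, evaluation, moves, and the
# full annealing loop against an exhaustive-enumeration oracle.

solution <- function(header, bodies) {
  structure(list(header = header, bodies = bodies), class = "sa_solution")
}

body_of <- function(smiles) {
  structure(list(molecule = canonicalize(smiles), parent_id = "t"),
            class = "fragment_body")
}

test_that("realization assembles bodies into markers deterministically", {
  h1 <- fragment_ligand("Cc1ccccc1")[[2]]            # *c1ccccc1
  sol <- solution(h1, list(body_of("C")))
  expect_identical(realize(sol)$smiles_canonical,
                   canonicalize("Cc1ccccc1")$smiles_canonical)
  expect_identical(realize(sol)$smiles_canonical,
                   realize(sol)$smiles_canonical)

  # two-body solution: both bodies attached
  h2 <- structure(list(smiles_with_markers =
                         canonicalize("*c1ccc(*)cc1")$smiles_canonical,
                       n_attach = 2L, parent_id = "t"),
                  class = "fragment_header")
  mol <- realize(solution(h2, list(body_of("C"), body_of("N"))))
  expect_identical(mol$heavy_atom_count, 8L)
  expect_false(grepl("*", mol$smiles_canonical, fixed = TRUE))
})

test_that("evaluation filters infeasible realizations and defers to the scorer", {
  h <- fragment_ligand("Cc1ccccc1")[[2]]
  sol <- solution(h, list(body_of("C")))
  expect_identical(evaluate(sol, function(mol) score_result(energy = -4.2)),
                   -4.2)

  # an oversize body pushes the realization past the drug-likeness filter
  big <- solution(h, list(body_of(strrep("C", 45))))   # MW > 500, rot > 10
  expect_identical(evaluate(big, function(mol) score_result(energy = 0)), Inf)

  # lookup scorer serves the printed library value for M37
  ref <- load_reference_library(validate = FALSE)
  lk <- lookup_scorer(ref)
  m37 <- canonicalize(ref_smiles("M37"))
  expect_identical(lk(m37)$energy, -11.3)
})

test_that("initial-solution tournament picks the best of k and is seeded", {
  lib <- tiny_library()
  sc <- surrogate_scorer()

  set.seed(9)
  r1 <- generate_initial_ligand(lib, k = 5, scorer = sc)
  set.seed(9)
  r2 <- generate_initial_ligand(lib, k = 5, scorer = sc)
  expect_identical(r1, r2)
  expect_false(r1$infeasible_start)

  # k = 1 returns exactly the single sampled solution
  set.seed(4)
  one <- generate_initial_ligand(lib, k = 1, scorer = sc)
  set.seed(4)
  h <- lib$headers[[sample.int(2L, 1L)]]
  idx <- sample.int(3L, h$n_attach, replace = TRUE)
  expect_identical(one$solution$header, h)
  expect_identical(one$solution$bodies, lib$bodies[idx])

  # tournament winner has the minimal energy among its candidates
  set.seed(9)
  k <- 6
  cand_e <- numeric(k)
  set.seed(9)
  for (i in seq_len(k)) {
    hh <- lib$headers[[sample.int(2L, 1L)]]
    ii <- sample.int(3L, hh$n_attach, replace = TRUE)
    cand_e[i] <- evaluate(solution(hh, lib$bodies[ii]), sc)
  }
  set.seed(9)
  win <- generate_initial_ligand(lib, k = k, scorer = sc)
  expect_identical(win$energy, min(cand_e))
})

test_that("change replaces one body inside its Tanimoto neighbourhood", {
  lib <- tiny_library()
  sol <- solution(lib$headers[[1]], list(lib$bodies[[1]]))   # body C
  set.seed(2)
  moved <- change(sol, lib)
  expect_length(moved$bodies, 1)
  # original untouched
  expect_identical(sol$bodies[[1]]$molecule$smiles_canonical,
                   canonicalize("C")$smiles_canonical)

  # forced move: pool of two, the other body shares fingerprint bits
  lib2 <- lib
  lib2$bodies <- list(body_of("CC"), body_of("CCC"))
  t_cc <- tanimoto(fingerprint(canonicalize("CC")),
                   fingerprint(canonicalize("CCC")))
  expect_gt(t_cc, 0)
  sol2 <- solution(lib$headers[[1]], list(lib2$bodies[[1]]))
  set.seed(3)
  expect_identical(change(sol2, lib2)$bodies[[1]]$molecule$smiles_canonical,
                   canonicalize("CCC")$smiles_canonical)

  # empty neighbourhood falls back to the whole pool
  lib3 <- lib
  lib3$bodies <- list(body_of("C"))
  sol3 <- solution(lib$headers[[1]], list(body_of("C")))
  set.seed(5)
  fb <- change(sol3, lib3)
  expect_identical(fb$bodies[[1]]$molecule$smiles_canonical,
                   canonicalize("C")$smiles_canonical)

  # seeded replay of position and replacement draw
  sol4 <- solution(lib$headers[[1]], list(lib$bodies[[1]], lib$bodies[[2]]))
  lib4 <- lib
  lib4$headers <- list(structure(list(
    smiles_with_markers = canonicalize("*c1ccc(*)cc1")$smiles_canonical,
    n_attach = 2L, parent_id = "t"), class = "fragment_header"))
  set.seed(7)
  mv <- change(sol4, lib4)
  set.seed(7)
  pos <- sample.int(2L, 1L)
  removed <- sol4$bodies[[pos]]$molecule
  neigh <- which(vapply(lib4$bodies, function(b) {
    b$molecule$smiles_canonical != removed$smiles_canonical &&
      tanimoto(fingerprint(b$molecule), fingerprint(removed)) > 0
  }, logical(1)))
  pick <- if (length(neigh)) neigh[sample.int(length(neigh), 1L)]
          else sample.int(3L, 1L)
  expect_identical(mv$bodies[[pos]], lib4$bodies[[pick]])
})

test_that("swap exchanges two positions and is the identity on one body", {
  h <- tiny_library()$headers[[1]]
  one <- solution(h, list(body_of("C")))
  set.seed(1)
  expect_identical(swap(one), one)

  two <- solution(h, list(body_of("C"), body_of("N")))
  set.seed(1)
  sw <- swap(two)
  expect_identical(sw$bodies[[1]], two$bodies[[2]])
  expect_identical(sw$bodies[[2]], two$bodies[[1]])

  three <- solution(h, list(body_of("C"), body_of("N"), body_of("O")))
  set.seed(8)
  sw3 <- swap(three)
  set.seed(8)
  ij <- sample.int(3L, 2L)
  expd <- three$bodies
  expd[c(ij[1], ij[2])] <- three$bodies[c(ij[2], ij[1])]
  expect_identical(sw3$bodies, expd)
})

test_that("annealing traces are monotone, geometric, and reproducible", {
  lib <- tiny_library()
  sc <- surrogate_scorer()
  cfg <- sa_config(initial_temp = 5, final_temp = 0.05, alpha = 0.9,
                   max_tries = 2, stuck_limit = 40, competition_size = 3,
                   seed = 13)
  tr <- anneal(lib, sc, cfg)

  # best energy never increases along the trace
  expect_true(all(diff(tr$trace$best_energy) <= 0))
  # reported best equals the minimum current energy ever logged
  expect_identical(tr$best_energy, min(tr$trace$current_energy))

  # temperatures: strictly decreasing geometric with ratio alpha, > final
  for (t in unique(tr$trace$try)) {
    temps <- tr$trace$temperature[tr$trace$try == t &
                                    tr$trace$move == "change"]
    expect_gt(min(temps), cfg$final_temp)
    if (length(temps) > 1) {
      expect_equal(temps[-1] / temps[-length(temps)],
                   rep(cfg$alpha, length(temps) - 1), tolerance = 1e-12)
    }
  }

  # byte-identical repetition under the same seed
  expect_identical(anneal(lib, sc, cfg), tr)
})

test_that("annealing never beats exhaustive enumeration and usually matches it", {
  lib <- tiny_library()
  sc <- surrogate_scorer()
  opt <- brute_force_minimum(lib, sc)
  hits <- 0L
  for (seed in 1:5) {
    cfg <- sa_config(initial_temp = 10, final_temp = 0.01, alpha = 0.9,
                     max_tries = 3, stuck_limit = 50, competition_size = 3,
                     seed = seed)
    tr <- anneal(lib, sc, cfg)
    expect_gte(tr$best_energy, opt - 1e-9)
    if (isTRUE(all.equal(tr$best_energy, opt))) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("near-zero temperature degenerates to greedy descent", {
  lib <- tiny_library()
  sc <- surrogate_scorer()
  cfg <- sa_config(initial_temp = 1e-8, final_temp = 1e-9, alpha = 0.5,
                   max_tries = 2, stuck_limit = 50, competition_size = 3,
                   seed = 21)
  tr <- anneal(lib, sc, cfg)
  # only improving (non-worsening) moves accepted: per-try current energy
  # is non-increasing
  for (t in unique(tr$trace$try)) {
    cur <- tr$trace$current_energy[tr$trace$try == t]
    cur <- cur[is.finite(cur)]
    if (length(cur) > 1) expect_true(all(diff(cur) <= 1e-9))
  }
})

test_that("a constant scorer accepts every proposal and keeps its energy", {
  lib <- tiny_library()
  const <- function(mol) score_result(energy = -1)
  cfg <- sa_config(initial_temp = 1, final_temp = 0.5, alpha = 0.9,
                   max_tries = 1, stuck_limit = 10, competition_size = 2,
                   seed = 2)
  tr <- anneal(lib, const, cfg)
  expect_identical(tr$best_energy, -1)
  expect_true(all(tr$trace$accepted[tr$trace$move == "change"]))
})

test_that("trace files echo the seed and tabulate every iteration", {
  lib <- tiny_library()
  cfg <- sa_config(initial_temp = 1, final_temp = 0.2, alpha = 0.8,
                   max_tries = 1, stuck_limit = 10, competition_size = 2,
                   seed = 6)
  tr <- anneal(lib, surrogate_scorer(), cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  lines <- readLines(path)
  expect_match(lines[1], "seed=6")
  tab <- utils::read.delim(path, skip = 1)
  expect_identical(nrow(tab), nrow(tr$trace))
  expect_named(tab, c("try", "iteration", "temperature", "move",
                      "current_energy", "best_energy", "accepted"))
})
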