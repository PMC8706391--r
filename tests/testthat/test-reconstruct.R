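# Reconstruction: coupling, random fills, the semi-exhaustive cross product
# and the census identity.

test_that("coupling consumes the first marker and forms a valid bond", {
  expect_identical(couple("*c1ccccc1", canonicalize("C")),
                   canonicalize("Cc1ccccc1")$smiles_canonical)

  # double-marker header: one marker consumed, one remains
  out <- couple("*c1ccc(*)cc1", canonicalize("C"))
  expect_identical(lengths(regmatches(out, gregexpr("*", out, fixed = TRUE))),
                   1L)

  # amide + amine: the product passes an independent valence audit
  out <- couple("*C(=O)O", canonicalize("N"))
  expect_identical(out, canonicalize("NC(=O)O")$smiles_canonical)
  g <- fragrecon:::mol_graph(out)
  h <- fragrecon:::implicit_hydrogens(g)     # errors on violation
  bs <- fragrecon:::bond_order_sum(g)
  for (i in seq_along(g$sym)) {
    av <- fragrecon:::atom_allowed_valence(g$sym[i], g$chg[i])
    expect_true((bs[i] + h[i]) %in% av)
  }
})

test_that("coupling fails cleanly when no body atom can accept a bond", {
  expect_error(couple("*c1ccccc1", canonicalize("FC(F)(F)F")),
               class = "coupling_infeasible")
})

test_that("marker filling is exhaustive, forced when possible, and replayable", {
  bodies1 <- list(structure(list(molecule = canonicalize("C"), parent_id = "p"),
                            class = "fragment_body"))
  # no markers: unchanged
  set.seed(1)
  out <- fill_remaining(canonicalize("Cc1ccccc1")$smiles_canonical, bodies1)
  expect_identical(out$molecule$smiles_canonical,
                   canonicalize("Cc1ccccc1")$smiles_canonical)
  expect_length(out$body_idx, 0)

  # two markers, single body: both filled with it
  set.seed(1)
  out <- fill_remaining("*c1ccc(*)cc1", bodies1)
  expect_identical(out$molecule$smiles_canonical,
                   canonicalize("Cc1ccc(C)cc1")$smiles_canonical)
  expect_identical(out$body_idx, c(1L, 1L))

  # seeded draw replays the documented uniform sequence
  bodies3 <- lapply(c("C", "CC", "N"), function(s) {
    structure(list(molecule = canonicalize(s), parent_id = "p"),
              class = "fragment_body")
  })
  set.seed(42)
  out <- fill_remaining("*c1ccccc1", bodies3)
  set.seed(42)
  expect_identical(out$body_idx, sample.int(3L, 1L))
})

test_that("semi-exhaustive crosses headers and bodies with exact accounting", {
  lib <- build_library(list(canonicalize("Cc1ccccc1", id = "T")))
  # toluene: 2 fragments, both marker-bearing -> generated == 4
  expect_identical(lib$n_sl, 2L)
  res <- semi_exhaustive(lib, seed = 3)
  expect_identical(res$accounting$generated, 4L)
  expect_true(verify_accounting(res$accounting)$pass)

  for (nl in res$ligands) {
    expect_s3_class(nl, "new_ligand")
    expect_false(grepl("*", nl$molecule$smiles_canonical, fixed = TRUE))
    expect_true(check_lipinski_veber(compute_descriptors(nl$molecule))$pass)
  }

  # emitted count equals headers x bodies when nothing is rejected or dup
  if (res$accounting$rnl == 0 && res$accounting$dnl == 0) {
    expect_identical(res$accounting$n, 4L)
  }
})

test_that("semi-exhaustive output is deterministic under a fixed seed", {
  lib <- build_library(list(canonicalize("Cc1ccccc1", id = "A"),
                            canonicalize("CCc1ccncc1", id = "B")))
  r1 <- semi_exhaustive(lib, seed = 11)
  r2 <- semi_exhaustive(lib, seed = 11)
  expect_identical(r1, r2)
  s1 <- vapply(r1$ligands, function(x) x$molecule$smiles_canonical, character(1))
  expect_identical(s1, sort(s1, method = "radix"))
})

test_that("census identity verification accepts the printed group-1 census", {
  # group 1: 25 sub-ligands square to 625 candidate unions, 581 survive
  acc <- reconstruction_accounting(n_fl = 25, df = 0, rnl = 44, dnl = 0,
                                   n = 581)
  expect_true(verify_accounting(acc)$pass)
  expect_true(verify_accounting(
    reconstruction_accounting(n_fl = 3, df = 1, rnl = 0, dnl = 0, n = 4))$pass)
  bad <- reconstruction_accounting(n_fl = 3, df = 1, rnl = 5, dnl = 0, n = 4)
  expect_false(verify_accounting(bad)$pass)
  expect_true("census_identity" %in% verify_accounting(bad)$violations)
})

test_that("reconstruction output files carry records and census", {
  lib <- build_library(list(canonicalize("Cc1ccccc1", id = "T")))
  res <- semi_exhaustive(lib, seed = 5)
  dir <- withr::local_tempdir()
  write_reconstruction(res, dir)
  rec <- read_smiles_file(file.path(dir, "new_ligands.smi"))
  expect_identical(nrow(rec), res$accounting$n)
  acc <- fragrecon:::read_keyvalue(file.path(dir, "accounting.txt"))
  expect_identical(as.integer(acc$n), res$accounting$n)
  expect_identical(as.integer(acc$generated), res$accounting$generated)
})
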