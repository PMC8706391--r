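# Pluggable scoring.  A scorer is a function(molecule) -> score_result.
# Binding energies are on the docking scale: lower (more negative) is
# better.  Ligands that cannot be evaluated score "unavailable", which every
# selection path treats as worse than any finite energy.

#' Score result
#'
#' Either a finite energy or an unavailability sentinel with a reason;
#' exactly one of the two is set.
#'
#' @param energy Finite numeric energy (lower is better), or `NULL`.
#' @param unavailable Reason string when the ligand cannot be scored.
#' @return A `score_result`.
#' @export
score_result <- function(energy = NULL, unavailable = NULL) {
  if (is.null(energy) == is.null(unavailable)) {
    stop("exactly one of 'energy' and 'unavailable' must be given", call. = FALSE)
  }
  structure(list(energy = energy, unavailable = unavailable),
            class = "score_result")
}

#' @rdname score_result
#' @param x A `score_result`.
#' @export
is_unavailable <- function(x) {
  stopifnot(inherits(x, "score_result"))
  !is.null(x$unavailable)
}

#' @export
print.score_result <- function(x, ...) {
  if (is_unavailable(x)) cat("<score> unavailable:", x$unavailable, "\n")
  else cat("<score>", x$energy, "\n")
  invisible(x)
}

#' Lookup scorer over a reference table
#'
#' Serves tabulated binding energies: a molecule whose canonical SMILES
#' matches a table entry gets its printed energy; anything else is
#' unavailable.
#'
#' @param table data.frame with columns `smiles` and `be`.
#' @return A scorer function.
#' @export
lookup_scorer <- function(table) {
  stopifnot(all(c("smiles", "be") %in% names(table)))
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(table))) {
    assign(ob_canonical(table$smiles[i]), as.numeric(table$be[i]), envir = env)
  }
  function(mol) {
    mol <- as_molecule(mol)
    key <- mol$smiles_canonical
    if (exists(key, envir = env, inherits = FALSE)) {
      score_result(energy = get(key, envir = env, inherits = FALSE))
    } else {
      score_result(unavailable = "not in reference table")
    }
  }
}

#' Default surrogate scorer weights
#'
#' `energy = -(w_mw * log(1 + MW) + w_hba * HBA + w_ring * rings)
#'  + w_clogp * cLogP^2`.
#' @export
SURROGATE_WEIGHTS <- c(w_mw = 1.0, w_hba = 0.3, w_ring = 0.5, w_clogp = 0.05)

#' Deterministic surrogate scorer
#'
#' A desk-scale stand-in for docking: a fixed, documented function of
#' descriptors that rewards size, acceptors and ring systems and penalizes
#' extreme lipophilicity.  The same molecule always gets the same energy.
#' Molecules whose heavy-atom count exceeds `size_cap` are unavailable,
#' mirroring a ligand too large for a docking grid.  The weights are fixed
#' constants, not fitted to anything.
#'
#' @param weights Named numeric vector (`w_mw`, `w_hba`, `w_ring`,
#'   `w_clogp`).
#' @param size_cap Heavy-atom cap above which scoring is unavailable.
#' @return A scorer function.
#' @export
surrogate_scorer <- function(weights = SURROGATE_WEIGHTS, size_cap = 60L) {
  stopifnot(all(c("w_mw", "w_hba", "w_ring", "w_clogp") %in% names(weights)))
  function(mol) {
    mol <- as_molecule(mol)
    if (mol$heavy_atom_count > size_cap) {
      return(score_result(unavailable = sprintf(
        "heavy-atom count %d exceeds grid cap %d", mol$heavy_atom_count,
        size_cap)))
    }
    d <- compute_descriptors(mol)
    rings <- ring_count(mol_graph(mol$smiles_canonical))
    e <- -(weights[["w_mw"]] * log1p(d$mw) +
             weights[["w_hba"]] * d$hba +
             weights[["w_ring"]] * rings) +
      weights[["w_clogp"]] * d$clogp^2
    score_result(energy = as.numeric(e))
  }
}

#' External docking adapter (optional)
#'
#' Contract for plugging a docking engine (AutoDock-family or similar)
#' behind the scorer interface.  The engine executable and a prepared
#' receptor are supplied by the user; both are checked at construction, so
#' a misconfiguration fails before any search starts.  The scorer writes
#' the ligand SMILES to a temp file, invokes the engine as
#' `engine <receptor> <ligand.smi> <args...>`, parses one energy per pose
#' from stdout, and returns the most negative; any engine failure yields an
#' unavailable score.
#'
#' @param engine Path to the docking executable.
#' @param receptor Path to the prepared receptor file.
#' @param grid_points Grid dimensions in points (default 45 x 45 x 45).
#' @param grid_spacing Grid spacing in Angstrom (default 0.375).
#' @param runs Docking runs per ligand (default 100).
#' @param population Genetic-algorithm population (default 150).
#' @param rms_cluster Pose-clustering RMS threshold in Angstrom (default 1).
#' @param pos Number of poses requested from the engine.
#' @return A scorer function; its `config` attribute carries the serialized
#'   engine parameters.
#' @export
docking_adapter <- function(engine, receptor,
                            grid_points = c(45L, 45L, 45L),
                            grid_spacing = 0.375,
                            runs = 100L, population = 150L,
                            rms_cluster = 1.0, pos = 10L) {
  if (!file.exists(engine)) {
    stop("docking engine not found: ", engine, call. = FALSE)
  }
  if (!file.exists(receptor)) {
    stop("receptor file not found: ", receptor, call. = FALSE)
  }
  config <- list(engine = engine, receptor = receptor,
                 grid_points = grid_points, grid_spacing = grid_spacing,
                 runs = runs, population = population,
                 rms_cluster = rms_cluster, pos = pos)
  args_for <- function(ligand_file) {
    c(receptor, ligand_file,
      paste0("--grid=", paste(grid_points, collapse = "x")),
      paste0("--spacing=", grid_spacing),
      paste0("--runs=", runs),
      paste0("--population=", population),
      paste0("--rms=", rms_cluster),
      paste0("--poses=", pos))
  }
  scorer <- function(mol) {
    mol <- as_molecule(mol)
    lf <- tempfile(fileext = ".smi")
    on.exit(unlink(lf))
    writeLines(paste0(mol$smiles_canonical, "\tligand"), lf)
    out <- tryCatch(
      suppressWarnings(system2(engine, args_for(lf), stdout = TRUE,
                               stderr = FALSE)),
      error = function(e) NULL)
    status <- attr(out, "status")
    if (is.null(out) || (!is.null(status) && status != 0)) {
      return(score_result(unavailable = "docking engine failure"))
    }
    energies <- suppressWarnings(
      as.numeric(unlist(regmatches(out, gregexpr("-?[0-9]+\\.?[0-9]*", out)))))
    energies <- energies[is.finite(energies)]
    if (!length(energies)) {
      return(score_result(unavailable = "no pose energies in engine output"))
    }
    score_result(energy = min(energies))
  }
  attr(scorer, "config") <- config
  scorer
}
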