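# Simulated-annealing search over header-plus-bodies assemblies.
#
# One solution = one header and an ordered list of bodies, one per
# attachment marker.  The change move replaces a random body within its
# Tanimoto neighbourhood; the swap move exchanges two body positions and is
# proposed once after each accepted, improving change.  Worsening change
# moves are accepted with probability exp(-(f(new) - f(cur)) / T) under a
# geometric cooling schedule; the search restarts max_tries times with a
# fresh header.

#' Simulated-annealing configuration
#'
#' @param initial_temp Starting temperature (> final_temp).
#' @param final_temp Stopping temperature (> 0).
#' @param alpha Geometric cooling factor, strictly inside (0, 1).
#' @param max_tries Number of restarts (fresh header each restart).
#' @param stuck_limit Consecutive iterations without improving the best
#'   energy before a restart is abandoned.
#' @param competition_size Random candidates entering the initial-solution
#'   tournament.
#' @param seed Integer seed for all randomness in [anneal()].
#' @param pos Poses parameter forwarded to docking scorers; ignored by the
#'   lookup and surrogate scorers.
#' @return An `sa_config` list.
#' @export
sa_config <- function(initial_temp = 10, final_temp = 0.01, alpha = 0.95,
                      max_tries = 5, stuck_limit = 50, competition_size = 5,
                      seed = 1L, pos = 10) {
  stopifnot(initial_temp > 0, final_temp > 0, final_temp < initial_temp,
            alpha > 0, alpha < 1,
            max_tries >= 1, stuck_limit >= 1, competition_size >= 1)
  structure(list(initial_temp = initial_temp, final_temp = final_temp,
                 alpha = alpha, max_tries = as.integer(max_tries),
                 stuck_limit = as.integer(stuck_limit),
                 competition_size = as.integer(competition_size),
                 seed = as.integer(seed), pos = pos),
            class = "sa_config")
}

new_solution <- function(header, bodies) {
  stopifnot(inherits(header, "fragment_header"),
            length(bodies) == header$n_attach)
  structure(list(header = header, bodies = bodies), class = "sa_solution")
}

#' Realize a solution into a molecule
#'
#' Couples the solution's bodies, in list order, into the header's
#' attachment markers (first remaining marker each time).
#'
#' @param sol An `sa_solution`.
#' @return A marker-free `molecule`.  Signals a `coupling_infeasible`
#'   condition when a body cannot accept the bond.
#' @export
realize <- function(sol) {
  stopifnot(inherits(sol, "sa_solution"))
  smi <- sol$header$smiles_with_markers
  for (b in sol$bodies) {
    smi <- couple(new_fragment(smi, NA_character_), b)
  }
  canonicalize(smi)
}

#' Evaluate a solution
#'
#' Feasibility first (realizable and Lipinski/Veber-compliant), then the
#' scorer's energy.  Infeasible solutions and unavailable scores evaluate
#' to `+Inf`, which compares worse than any finite energy.
#'
#' @param sol An `sa_solution`.
#' @param scorer A scorer function (see [surrogate_scorer()]).
#' @return Finite energy, or `+Inf` for infeasible/unavailable.
#' @export
evaluate <- function(sol, scorer) {
  mol <- tryCatch(realize(sol), coupling_infeasible = function(e) NULL,
                  error = function(e) NULL)
  if (is.null(mol)) return(Inf)
  if (!check_lipinski_veber(compute_descriptors(mol))$pass) return(Inf)
  s <- scorer(mol)
  if (is_unavailable(s)) Inf else s$energy
}

random_solution <- function(lib) {
  h <- lib$headers[[sample.int(length(lib$headers), 1L)]]
  idx <- sample.int(length(lib$bodies), h$n_attach, replace = TRUE)
  new_solution(h, lib$bodies[idx])
}

#' Generate an initial solution by tournament
#'
#' Draws `k` random solutions (random header; one random body per marker)
#' and returns the best under the scorer.  If every candidate is infeasible
#' the draw is repeated once; if still infeasible, the last candidate is
#' returned flagged `infeasible_start` (energy `+Inf`), from which annealing
#' can still recover since any feasible move improves on `+Inf`.
#'
#' @param lib A `fragment_library` with at least one header.
#' @param k Tournament size.
#' @param scorer Scorer function.
#' @return List with `solution`, `energy`, `infeasible_start`.
#' @export
generate_initial_ligand <- function(lib, k, scorer) {
  stopifnot(length(lib$headers) >= 1, k >= 1)
  for (round in 1:2) {
    best <- NULL
    best_e <- Inf
    last <- NULL
    for (i in seq_len(k)) {
      s <- random_solution(lib)
      last <- s
      e <- evaluate(s, scorer)
      if (is.null(best) || e < best_e) {
        best <- s
        best_e <- e
      }
    }
    if (is.finite(best_e)) {
      return(list(solution = best, energy = best_e, infeasible_start = FALSE))
    }
  }
  list(solution = last, energy = Inf, infeasible_start = TRUE)
}

#' Change move: replace one body within its Tanimoto neighbourhood
#'
#' A uniformly chosen body position is replaced by a body drawn uniformly
#' from the pool members with Tanimoto similarity strictly above 0 to the
#' removed body (the removed body itself excluded).  When that
#' neighbourhood is empty the replacement is drawn from the whole pool.
#' The input solution is not modified.
#'
#' @param sol An `sa_solution` with at least one body.
#' @param lib The `fragment_library` supplying the body pool.
#' @return A new `sa_solution`.
#' @export
change <- function(sol, lib) {
  stopifnot(inherits(sol, "sa_solution"), length(sol$bodies) >= 1)
  pos <- sample.int(length(sol$bodies), 1L)
  removed <- sol$bodies[[pos]]
  fp_rm <- fingerprint(removed$molecule)
  pool <- lib$bodies
  neigh <- which(vapply(pool, function(b) {
    b$molecule$smiles_canonical != removed$molecule$smiles_canonical &&
      tanimoto(fingerprint(b$molecule), fp_rm) > 0
  }, logical(1)))
  pick <- if (length(neigh)) neigh[sample.int(length(neigh), 1L)]
          else sample.int(length(pool), 1L)
  out <- sol
  out$bodies[[pos]] <- pool[[pick]]
  out
}

#' Swap move: exchange two body positions
#'
#' Two distinct uniformly chosen positions exchange their bodies; a
#' single-body solution is returned unchanged.
#'
#' @param sol An `sa_solution`.
#' @return A new `sa_solution`.
#' @export
swap <- function(sol) {
  stopifnot(inherits(sol, "sa_solution"))
  nb <- length(sol$bodies)
  if (nb < 2) return(sol)
  ij <- sample.int(nb, 2L)
  out <- sol
  out$bodies[c(ij[1], ij[2])] <- sol$bodies[c(ij[2], ij[1])]
  out
}

#' Simulated-annealing search
#'
#' Runs `max_tries` restarts.  Each restart draws a tournament initial
#' solution and iterates while the temperature exceeds `final_temp` and the
#' best energy has improved within the last `stuck_limit` iterations.  Every
#' iteration proposes a change move, accepted when not worse; an accepted
#' change is followed by one swap proposal, accepted only when not worse.
#' A worsening change is accepted with probability
#' `exp(-(f(new) - f(cur)) / T)`.  Temperature is multiplied by `alpha`
#' once per iteration.
#'
#' @param lib A `fragment_library` with at least one header.
#' @param scorer Scorer function.
#' @param cfg An [sa_config()].
#' @return An `sa_trace`: list with `trace` (data.frame: try, iteration,
#'   temperature, move, current_energy, best_energy, accepted),
#'   `best_solution`, `best_energy`, `best_molecule`, `seed`.
#' @export
anneal <- function(lib, scorer, cfg = sa_config()) {
  stopifnot(inherits(lib, "fragment_library"), inherits(cfg, "sa_config"))
  if (!length(lib$headers)) {
    stop("fragment library has no marker-bearing headers", call. = FALSE)
  }
  set.seed(cfg$seed)
  best_sol <- NULL
  best_e <- Inf
  rows <- list()
  log_row <- function(try, it, temp, move, cur_e, acc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      try = try, iteration = it, temperature = temp, move = move,
      current_energy = cur_e, best_energy = best_e, accepted = acc)
  }
  for (try in seq_len(cfg$max_tries)) {
    init <- generate_initial_ligand(lib, cfg$competition_size, scorer)
    cur <- init$solution
    f_cur <- init$energy
    if (f_cur <= best_e) {
      best_e <- f_cur
      best_sol <- cur
    }
    temp <- cfg$initial_temp
    stuck_n <- 0L
    it <- 0L
    while (temp > cfg$final_temp && stuck_n < cfg$stuck_limit) {
      it <- it + 1L
      prev_best <- best_e
      new <- change(cur, lib)
      f_new <- evaluate(new, scorer)
      imp <- isTRUE(f_new <= f_cur) ||
        (is.infinite(f_new) && is.infinite(f_cur))   # Inf <= Inf
      if (imp) {
        cur <- new
        f_cur <- f_new
        if (f_cur <= best_e) { best_e <- f_cur; best_sol <- cur }
        log_row(try, it, temp, "change", f_cur, TRUE)
        sw <- swap(cur)
        f_sw <- evaluate(sw, scorer)
        sw_ok <- isTRUE(f_sw <= f_cur) ||
          (is.infinite(f_sw) && is.infinite(f_cur))
        if (sw_ok) {
          cur <- sw
          f_cur <- f_sw
          if (f_cur <= best_e) { best_e <- f_cur; best_sol <- cur }
        }
        log_row(try, it, temp, "swap", f_cur, sw_ok)
      } else {
        p <- exp(-(f_new - f_cur) / temp)
        acc <- stats::runif(1) < p
        if (acc) {
          cur <- new
          f_cur <- f_new
          if (f_cur <= best_e) { best_e <- f_cur; best_sol <- cur }
        }
        log_row(try, it, temp, "change", f_cur, acc)
      }
      stuck_n <- if (best_e < prev_best) 0L else stuck_n + 1L
      temp <- temp * cfg$alpha
    }
  }
  best_mol <- if (!is.null(best_sol) && is.finite(best_e)) {
    tryCatch(realize(best_sol), error = function(e) NULL)
  } else {
    NULL
  }
  structure(
    list(trace = do.call(rbind, rows),
         best_solution = best_sol, best_energy = best_e,
         best_molecule = best_mol, seed = cfg$seed),
    class = "sa_trace")
}

#' @export
print.sa_trace <- function(x, ...) {
  cat("<sa_trace> iterations:", nrow(x$trace),
      " best energy:", x$best_energy,
      if (!is.null(x$best_molecule)) paste0(" (", x$best_molecule$smiles_canonical, ")"),
      "\n")
  invisible(x)
}

#' Write an annealing trace as TSV
#'
#' Columns: try, iteration, temperature, move, current_energy, best_energy,
#' accepted.  The seed is echoed in a `#` header line.
#'
#' @param trace An `sa_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sa_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed=", trace$seed, " best_energy=", trace$best_energy),
             con)
  utils::write.table(trace$trace, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
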