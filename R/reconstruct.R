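# Reconstruction: semi-exhaustive coupling of headers and bodies, random
# filling of residual attachment points, Lipinski/Veber rejection, final
# deduplication, and the census identity
#   N = (NFL - DF)^2 - RNL - DNL
# (generalized to N = generated - RNL - DNL when the header and body sets
# differ in size because some fragments carry no markers).

coupling_infeasible <- function(msg) {
  structure(class = c("coupling_infeasible", "error", "condition"),
            list(message = msg, call = NULL))
}

# Index of the first heavy atom (canonical order) able to accept one more
# single bond, i.e. carrying at least one implicit hydrogen.
first_attachable_atom <- function(g) {
  h <- implicit_hydrogens(g)
  ok <- which(g$sym != "*" & g$sym != "H" & h >= 1)
  if (!length(ok)) NA_integer_ else ok
}

#' Couple a body into the first attachment marker of a header
#'
#' Forms a single bond between the header atom that carries the first
#' marker (in canonical atom order) and an attachment atom of the body;
#' the marker is consumed.  By default the attachment atom is the first
#' heavy atom in canonical order with a free valence; with
#' `policy = "random"` it is drawn uniformly from all free-valence atoms
#' using the current RNG state.
#'
#' @param header A `fragment_header` or marker-bearing SMILES string.
#' @param body A `fragment_body`, `molecule` or SMILES string.
#' @param attach_atom Optional explicit body atom index (canonical order).
#' @param policy `"first"` (default, deterministic) or `"random"`.
#' @return Canonical SMILES of the coupled structure; it retains one marker
#'   per remaining open attachment point.
#' @export
couple <- function(header, body, attach_atom = NULL,
                   policy = c("first", "random")) {
  policy <- match.arg(policy)
  hsmi <- if (is.character(header)) ob_canonical(header) else header$smiles_with_markers
  bsmi <- if (is.character(body)) ob_canonical(body)
          else if (inherits(body, "fragment_body")) body$molecule$smiles_canonical
          else body$smiles_canonical
  gh <- mol_graph(hsmi)
  mk <- which(gh$sym == "*")
  if (!length(mk)) stop("header has no attachment marker", call. = FALSE)
  gb <- mol_graph(bsmi)
  if (n_markers(gb) > 0) stop("body must be marker-free", call. = FALSE)
  cand <- first_attachable_atom(gb)
  if (length(cand) == 1 && is.na(cand)) {
    stop(coupling_infeasible(paste0("no body atom can accept a bond in '",
                                    bsmi, "'")))
  }
  at <- if (!is.null(attach_atom)) {
    if (!attach_atom %in% cand) {
      stop(coupling_infeasible(paste0("body atom ", attach_atom,
                                      " has no free valence in '", bsmi, "'")))
    }
    attach_atom
  } else if (policy == "random" && length(cand) > 1) {
    cand[sample.int(length(cand), 1L)]
  } else {
    cand[1]
  }
  marker <- mk[1]
  anchor <- {
    b <- gh$bonds
    hit <- which(b$a1 == marker | b$a2 == marker)
    ifelse(b$a1[hit[1]] == marker, b$a2[hit[1]], b$a1[hit[1]])
  }
  keep <- setdiff(seq_along(gh$sym), marker)
  remap <- match(seq_along(gh$sym), keep)
  hb <- gh$bonds[gh$bonds$a1 != marker & gh$bonds$a2 != marker, , drop = FALSE]
  hb$a1 <- remap[hb$a1]
  hb$a2 <- remap[hb$a2]
  off <- length(keep)
  bb <- gb$bonds
  bb$a1 <- bb$a1 + off
  bb$a2 <- bb$a2 + off
  sym <- c(gh$sym[keep], gb$sym)
  chg <- c(gh$chg[keep], gb$chg)
  bonds <- rbind(hb, bb,
                 data.frame(a1 = remap[anchor], a2 = at + off, order = 1L))
  graph_to_smiles(sym, chg, bonds)
}

#' Fill every remaining attachment marker with random bodies
#'
#' Repeatedly couples a uniformly drawn body (current RNG state; seed
#' upstream for determinism) into the first remaining marker until the
#' structure is marker-free.
#'
#' @param partial SMILES (possibly marker-bearing) or `fragment_header`.
#' @param bodies Non-empty list of `fragment_body` objects.
#' @return List with `molecule` (marker-free) and `body_idx` (indices drawn,
#'   in fill order).
#' @export
fill_remaining <- function(partial, bodies) {
  smi <- if (is.character(partial)) ob_canonical(partial) else partial$smiles_with_markers
  stopifnot(length(bodies) >= 1)
  drawn <- integer(0)
  while (grepl("*", smi, fixed = TRUE)) {
    i <- sample.int(length(bodies), 1L)
    drawn <- c(drawn, i)
    smi <- couple(new_fragment(smi, NA_character_), bodies[[i]])
  }
  list(molecule = canonicalize(smi), body_idx = drawn)
}

new_ligand <- function(molecule, header_parent, body_parents) {
  structure(list(molecule = molecule,
                 header_parent = header_parent,
                 body_parents = body_parents),
            class = "new_ligand")
}

#' Reconstruction census
#'
#' Bundles the counts tracked across the reconstruction stages.  `generated`
#' defaults to `(n_fl - df)^2`, the square cross-product form of the census;
#' pass it explicitly when the header and body sets differ in size.
#'
#' @param n_fl Fragments before deduplication (NFL).
#' @param df Duplicated fragments removed (DF).
#' @param rnl Candidates rejected by the Lipinski/Veber filter or by coupling
#'   infeasibility (RNL).
#' @param dnl Duplicated new ligands removed (DNL).
#' @param n Final new-ligand count (N).
#' @param n_kl Known ligands (optional).
#' @param generated Candidate unions attempted; default `(n_fl - df)^2`.
#' @param n_headers,n_bodies Sizes of the two coupling sets (optional).
#' @return A `reconstruction_accounting` list.
#' @export
reconstruction_accounting <- function(n_fl, df, rnl, dnl, n, n_kl = NA_integer_,
                                      generated = NULL,
                                      n_headers = NA_integer_,
                                      n_bodies = NA_integer_) {
  if (is.null(generated)) generated <- (n_fl - df)^2
  structure(list(n_kl = n_kl, n_fl = n_fl, df = df, n_sl = n_fl - df,
                 n_headers = n_headers, n_bodies = n_bodies,
                 generated = generated, rnl = rnl, dnl = dnl, n = n),
            class = "reconstruction_accounting")
}

#' @export
print.reconstruction_accounting <- function(x, ...) {
  cat("<reconstruction_accounting>\n")
  for (f in c("n_kl", "n_fl", "df", "n_sl", "generated", "rnl", "dnl", "n")) {
    cat(" ", f, "=", x[[f]], "\n")
  }
  invisible(x)
}

#' Verify the reconstruction census identity
#'
#' Checks `n == generated - rnl - dnl` together with non-negativity of every
#' field; when headers and bodies are equinumerous with the sub-ligand set,
#' `generated` equals `(n_fl - df)^2` and the check is the census identity
#' `N = (NFL - DF)^2 - RNL - DNL`.
#'
#' @param acc A `reconstruction_accounting`.
#' @return A `rule_check` with `pass` and the violated clauses.
#' @export
verify_accounting <- function(acc) {
  stopifnot(inherits(acc, "reconstruction_accounting"))
  v <- character(0)
  num <- unlist(acc[c("n_fl", "df", "n_sl", "generated", "rnl", "dnl", "n")])
  if (any(num < 0, na.rm = TRUE)) v <- c(v, "negative_count")
  if (acc$n_sl != acc$n_fl - acc$df) v <- c(v, "nsl_identity")
  if (acc$n != acc$generated - acc$rnl - acc$dnl) v <- c(v, "census_identity")
  square_sets <- !is.na(acc$n_headers) && !is.na(acc$n_bodies) &&
    acc$n_headers == acc$n_sl && acc$n_bodies == acc$n_sl
  if (square_sets && acc$generated != (acc$n_fl - acc$df)^2) {
    v <- c(v, "square_form")
  }
  rule_check(v)
}

#' Semi-exhaustive reconstruction of new ligands
#'
#' Crosses every header with every body: the body is coupled into the
#' header's first marker, any residual markers are filled with uniformly
#' drawn bodies, and the realized structure is kept only if it passes the
#' Lipinski/Veber filter.  Survivors are deduplicated (first seen kept) and
#' returned sorted by canonical SMILES.  Coupling-infeasible pairs count as
#' rejections so the census identity stays exact.
#'
#' @param lib A `fragment_library` with at least one header.
#' @param seed Integer seed driving the random fills.
#' @return List with `ligands` (list of `new_ligand`) and `accounting`
#'   (a `reconstruction_accounting`, identity-verified).
#' @export
semi_exhaustive <- function(lib, seed = 1L) {
  stopifnot(inherits(lib, "fragment_library"))
  if (!length(lib$headers)) {
    stop("fragment library has no marker-bearing headers", call. = FALSE)
  }
  if (!length(lib$bodies)) stop("fragment library has no bodies", call. = FALSE)
  set.seed(as.integer(seed))
  candidates <- list()
  rnl <- 0L
  for (h in lib$headers) {
    for (bi in seq_along(lib$bodies)) {
      b <- lib$bodies[[bi]]
      res <- tryCatch({
        smi <- couple(h, b)
        fill <- fill_remaining(smi, lib$bodies)
        fill$header <- h
        fill$first_body <- bi
        fill
      }, coupling_infeasible = function(e) NULL)
      if (is.null(res)) {
        rnl <- rnl + 1L
        next
      }
      d <- compute_descriptors(res$molecule)
      if (!check_lipinski_veber(d)$pass) {
        rnl <- rnl + 1L
        next
      }
      parents <- vapply(c(bi, res$body_idx), function(i) {
        lib$bodies[[i]]$parent_id %||% NA_character_
      }, character(1))
      candidates[[length(candidates) + 1L]] <-
        new_ligand(res$molecule, h$parent_id, parents)
    }
  }
  dd <- deduplicate(candidates)
  ligands <- dd$kept
  ord <- order(vapply(ligands, function(x) x$molecule$smiles_canonical,
                      character(1)), method = "radix")
  ligands <- ligands[ord]
  acc <- reconstruction_accounting(
    n_fl = lib$n_fl, df = lib$n_df, rnl = rnl, dnl = dd$n_removed,
    n = length(ligands), n_kl = lib$n_kl,
    generated = length(lib$headers) * length(lib$bodies),
    n_headers = length(lib$headers), n_bodies = length(lib$bodies))
  stopifnot(verify_accounting(acc)$pass)
  list(ligands = ligands, accounting = acc)
}

#' Write semi-exhaustive output
#'
#' `new_ligands.smi` holds one record per ligand (id, SMILES, provenance);
#' `accounting.txt` holds the census.
#'
#' @param result Output of [semi_exhaustive()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_reconstruction <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lg <- result$ligands
  df <- data.frame(
    id = sprintf("NL%05d", seq_along(lg)),
    smiles = vapply(lg, function(x) x$molecule$smiles_canonical, character(1)),
    provenance = vapply(lg, function(x) {
      paste0(x$header_parent %||% "NA", "<-",
             paste(x$body_parents, collapse = "+"))
    }, character(1)),
    stringsAsFactors = FALSE)
  write_smiles_file(df, file.path(dir, "new_ligands.smi"),
                    comment = "new ligands: id, smiles, header<-bodies provenance")
  acc <- result$accounting
  writeLines(sprintf("%s=%s",
                     c("nkl", "nfl", "df", "nsl", "generated", "rnl", "dnl", "n"),
                     unlist(acc[c("n_kl", "n_fl", "df", "n_sl", "generated",
                                  "rnl", "dnl", "n")])),
             file.path(dir, "accounting.txt"))
  invisible(dir)
}
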