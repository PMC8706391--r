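# Deconstruction: cut known ligands into sub-ligands with attachment markers,
# filter by the rule of three, deduplicate, and assemble the paired
# header (SL*, markers kept) / body (SL, markers hydrogenated) library.

new_fragment <- function(smiles_with_markers, parent_id) {
  g <- mol_graph(smiles_with_markers)
  structure(
    list(smiles_with_markers = g$smiles,
         n_attach = n_markers(g),
         parent_id = parent_id),
    class = "fragment_header")
}

#' @export
print.fragment_header <- function(x, ...) {
  cat("<fragment>", x$smiles_with_markers, " markers:", x$n_attach,
      " parent:", x$parent_id %||% "?", "\n")
  invisible(x)
}

# Remove every "*" atom from a marker-bearing SMILES; the freed valence
# becomes an implicit hydrogen on re-canonicalization.
strip_marker_smiles <- function(smiles_with_markers) {
  hit <- cache_get("strip", smiles_with_markers)
  if (!is.null(hit)) return(hit)
  g <- mol_graph(smiles_with_markers)
  keep <- which(g$sym != "*")
  if (length(keep) == length(g$sym)) return(cache_set("strip", smiles_with_markers, g$smiles))
  if (length(keep) == 0) stop("fragment consists only of markers", call. = FALSE)
  remap <- match(seq_along(g$sym), keep)
  bonds <- g$bonds[g$bonds$a1 %in% keep & g$bonds$a2 %in% keep, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]
  bonds$a2 <- remap[bonds$a2]
  cache_set("strip", smiles_with_markers,
            graph_to_smiles(g$sym[keep], g$chg[keep], bonds))
}

#' Strip attachment markers from a fragment
#'
#' Replaces every attachment marker by an implicit hydrogen and
#' re-canonicalizes, producing the fragment's body form.
#'
#' @param h A `fragment_header` (or marker-bearing SMILES string).
#' @return A `fragment_body`: list with `molecule` and `parent_id`.
#' @export
strip_markers <- function(h) {
  if (is.character(h)) h <- new_fragment(h, parent_id = NA_character_)
  stopifnot(inherits(h, "fragment_header"))
  structure(
    list(molecule = canonicalize(strip_marker_smiles(h$smiles_with_markers)),
         parent_id = h$parent_id),
    class = "fragment_body")
}

#' Cut a ligand at every cleavable bond (raw pieces)
#'
#' The cleavable-bond set is every acyclic single bond between two heavy
#' atoms of which at least one lies in a ring; all such bonds are cut
#' simultaneously.  Each broken bond leaves one attachment marker (`*`) on
#' both pieces.  Heavy atoms are conserved across the pieces.  A molecule
#' with no cleavable bond is returned whole as a single marker-free piece.
#'
#' @param mol A `molecule` or SMILES string.
#' @return List of `fragment_header` objects (raw, unfiltered).
#' @export
cleave_ligand <- function(mol) {
  mol <- as_molecule(mol)
  g <- mol_graph(mol$smiles_canonical)
  acyc <- acyclic_bonds(g)
  ring <- ring_atoms(g)
  cut <- which(acyc & g$bonds$order == 1 &
                 (ring[g$bonds$a1] | ring[g$bonds$a2]) &
                 g$sym[g$bonds$a1] != "H" & g$sym[g$bonds$a2] != "H")
  if (!length(cut)) {
    return(list(new_fragment(g$smiles, parent_id = mol$id)))
  }
  sym <- g$sym
  chg <- g$chg
  bonds <- g$bonds[-cut, , drop = FALSE]
  for (j in cut) {
    for (end in c(g$bonds$a1[j], g$bonds$a2[j])) {
      sym <- c(sym, "*")
      chg <- c(chg, 0L)
      bonds <- rbind(bonds, data.frame(a1 = end, a2 = length(sym), order = 1L))
    }
  }
  pieces <- graph_components(sym, chg, bonds)
  lapply(pieces, new_fragment, parent_id = mol$id)
}

# RO3 gate on the marker-stripped form of a fragment.
fragment_passes_ro3 <- function(fr) {
  body <- canonicalize(strip_marker_smiles(fr$smiles_with_markers))
  check_ro3(compute_descriptors(body))$pass
}

#' Fragment a ligand into its sub-ligands
#'
#' Cuts all cleavable bonds simultaneously (see [cleave_ligand()]), discards
#' pieces whose marker-stripped form fails the rule of three, and collapses
#' duplicated pieces within the ligand (first occurrence kept).  The result
#' is the ligand's set of sub-ligands; applied to PU3 it yields the five
#' sub-ligands of the worked deconstruction example.
#'
#' @param mol A `molecule` or SMILES string.
#' @return List of `fragment_header` objects (`n_attach` may be 0 for a
#'   ligand with no cleavable bonds).
#' @export
fragment_ligand <- function(mol) {
  raw <- cleave_ligand(mol)
  kept <- Filter(fragment_passes_ro3, raw)
  deduplicate(kept)$kept
}

# Duplicate key: the marker-stripped constitution of the item.
dedup_key <- function(x) {
  smi <- if (inherits(x, "fragment_header")) {
    strip_marker_smiles(x$smiles_with_markers)
  } else if (inherits(x, "fragment_body")) {
    x$molecule$smiles_canonical
  } else if (inherits(x, "new_ligand")) {
    x$molecule$smiles_canonical
  } else if (is_molecule(x)) {
    x$smiles_canonical
  } else if (is.character(x)) {
    ob_canonical(x)
  } else {
    stop("cannot deduplicate objects of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  if (grepl("*", smi, fixed = TRUE)) smi <- strip_marker_smiles(smi)
  smi
}

#' Remove duplicated structures from a list
#'
#' Two items are duplicates iff their fingerprints have Tanimoto similarity
#' exactly 1 or their canonical SMILES are equal; fragments are compared on
#' their marker-stripped forms, so marker placement does not distinguish
#' copies.  The first occurrence in input order survives; order is preserved.
#'
#' @param items List of molecules, fragments, bodies or SMILES strings.
#' @return List with `kept` (surviving items) and `n_removed`.
#' @export
deduplicate <- function(items) {
  stopifnot(is.list(items))
  if (!length(items)) return(list(kept = items, n_removed = 0L))
  keys <- vapply(items, dedup_key, character(1))
  fps <- lapply(keys, fingerprint)
  keep <- logical(length(items))
  kept_idx <- integer(0)
  for (i in seq_along(items)) {
    dup <- FALSE
    for (k in kept_idx) {
      if (keys[[i]] == keys[[k]] || tanimoto(fps[[i]], fps[[k]]) == 1) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  list(kept = items[keep], n_removed = sum(!keep))
}

#' Build the sub-ligand library from known ligands
#'
#' Runs the deconstruction stages over a set of known ligands: every ligand
#' is fragmented ([fragment_ligand()]), the pooled sub-ligands are
#' deduplicated across ligands, and the surviving fragments are split into
#' the header set (marker-bearing forms, SL*) and the body set
#' (marker-stripped forms, SL).  The census satisfies
#' `n_sl == n_fl - n_df`.
#'
#' @param ligands Non-empty list of `molecule` objects or SMILES strings.
#' @return A `fragment_library`: list with `headers`, `bodies`, `n_kl`,
#'   `n_fl`, `n_df`, `n_sl`.
#' @export
build_library <- function(ligands) {
  if (!is.list(ligands) || !length(ligands)) {
    stop("'ligands' must be a non-empty list", call. = FALSE)
  }
  ligands <- lapply(ligands, as_molecule)
  per <- lapply(ligands, fragment_ligand)
  pooled <- do.call(c, per)
  n_fl <- length(pooled)
  dd <- deduplicate(pooled)
  n_df <- dd$n_removed
  frs <- dd$kept
  headers <- Filter(function(f) f$n_attach >= 1, frs)
  bodies <- lapply(frs, strip_markers)
  lib <- structure(
    list(headers = headers, bodies = bodies,
         n_kl = length(ligands), n_fl = n_fl, n_df = n_df,
         n_sl = n_fl - n_df),
    class = "fragment_library")
  stopifnot(lib$n_sl == length(frs))
  lib
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("<fragment_library> known ligands:", x$n_kl,
      " fragments:", x$n_fl, " duplicates removed:", x$n_df,
      " sub-ligands:", x$n_sl,
      " (headers:", length(x$headers), ", bodies:", length(x$bodies), ")\n")
  invisible(x)
}

#' Write a fragment library to a directory
#'
#' Serializes the header set to `sl_star.smi`, the body set to `sl.smi`
#' (SMILES record files, one `<id>TAB<smiles>` per line) and the census to
#' `accounting.txt` (key=value text).
#'
#' @param lib A `fragment_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "fragment_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hl <- vapply(seq_along(lib$headers), function(i) {
    h <- lib$headers[[i]]
    paste(sprintf("H%03d", i), h$smiles_with_markers, h$parent_id %||% "NA",
          sep = "\t")
  }, character(1))
  bl <- vapply(seq_along(lib$bodies), function(i) {
    b <- lib$bodies[[i]]
    paste(sprintf("B%03d", i), b$molecule$smiles_canonical,
          b$parent_id %||% "NA", sep = "\t")
  }, character(1))
  writeLines(c("# header sub-ligands (SL*): id, smiles with markers, parent", hl),
             file.path(dir, "sl_star.smi"))
  writeLines(c("# body sub-ligands (SL): id, smiles, parent", bl),
             file.path(dir, "sl.smi"))
  writeLines(sprintf("%s=%d", c("nkl", "nfl", "df", "nsl"),
                     c(lib$n_kl, lib$n_fl, lib$n_df, lib$n_sl)),
             file.path(dir, "accounting.txt"))
  invisible(dir)
}

#' Read a fragment library written by [write_library()]
#'
#' @param dir Directory containing `sl_star.smi`, `sl.smi`, `accounting.txt`.
#' @return A `fragment_library`.
#' @export
read_library <- function(dir) {
  acc <- read_keyvalue(file.path(dir, "accounting.txt"))
  hrec <- read_smiles_file(file.path(dir, "sl_star.smi"))
  brec <- read_smiles_file(file.path(dir, "sl.smi"))
  headers <- lapply(seq_len(nrow(hrec)), function(i) {
    new_fragment(hrec$smiles[i], parent_id = hrec$extra[i])
  })
  bodies <- lapply(seq_len(nrow(brec)), function(i) {
    structure(list(molecule = canonicalize(brec$smiles[i], id = brec$id[i]),
                   parent_id = brec$extra[i]),
              class = "fragment_body")
  })
  structure(
    list(headers = headers, bodies = bodies,
         n_kl = as.integer(acc[["nkl"]]), n_fl = as.integer(acc[["nfl"]]),
         n_df = as.integer(acc[["df"]]), n_sl = as.integer(acc[["nsl"]])),
    class = "fragment_library")
}
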