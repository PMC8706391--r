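# Internal molecular-graph layer.
#
# All structure I/O goes through OpenBabel (ChemmineOB); molblocks are parsed
# with ChemmineR.  The graph form (atom symbols, formal charges, bond table)
# is what fragmentation and coupling edit; OpenBabel re-canonicalizes every
# edited structure, so atom order downstream is always canonical order.

.fragrecon_cache <- new.env(parent = emptyenv())

cache_get <- function(kind, key) {
  k <- paste0(kind, "\r", key)
  if (exists(k, envir = .fragrecon_cache, inherits = FALSE)) {
    get(k, envir = .fragrecon_cache, inherits = FALSE)
  } else {
    NULL
  }
}

cache_set <- function(kind, key, value) {
  assign(paste0(kind, "\r", key), value, envir = .fragrecon_cache)
  value
}

# Canonical SMILES via OpenBabel.  OpenBabel reports parse failures on stderr
# and returns an empty string; that is turned into an R error here.
ob_canonical <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  hit <- cache_get("can", smiles)
  if (!is.null(hit)) return(hit)
  out <- ChemmineOB::convertFormat("SMI", "CAN", smiles)
  out <- sub("[ \t\r\n]+$", "", out)
  if (!nzchar(out)) {
    stop("SMILES parse error: cannot interpret input '", smiles, "'",
         call. = FALSE)
  }
  cache_set("can", smiles, out)
}

# Allowed valences by element; charge on N/O/P/S/C shifts the allowed set.
.allowed_valence <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
  P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = c(1, 3, 5)
)

atom_allowed_valence <- function(symbol, charge) {
  if (symbol == "*") return(1L)
  av <- .allowed_valence[[symbol]]
  if (is.null(av)) return(NA_integer_)
  if (charge != 0 && symbol %in% c("C", "N", "O", "P", "S")) av <- av + charge
  av
}

# Parse a V2000 molblock into the internal graph.
parse_molblock <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) stop("empty molblock", call. = FALSE)
  if (na < 2 || nb < 1) {
    # degenerate blocks (single atom / bond-free) trip ChemmineR's reader
    atoms <- lines[5:(4 + na)]
    sym <- trimws(substr(atoms, 32, 34))
    code <- suppressWarnings(as.integer(substr(atoms, 37, 39)))
    code[is.na(code)] <- 0L
    chg <- ifelse(code == 0 | code == 4, 0L, 4L - code)
    for (l in grep("^M  CHG", lines, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
      n <- f[1]
      for (k in seq_len(n)) chg[f[2 * k]] <- f[2 * k + 1]
    }
    bonds <- if (nb >= 1) {
      bl <- lines[(5 + na):(4 + na + nb)]
      data.frame(a1 = as.integer(substr(bl, 1, 3)),
                 a2 = as.integer(substr(bl, 4, 6)),
                 order = as.integer(substr(bl, 7, 9)))
    } else {
      data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
    }
    return(list(sym = sym, chg = chg, bonds = bonds))
  }
  sdfset <- methods::as(methods::as(lines, "SDFstr"), "SDFset")
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- sub("_\\d+$", "", rownames(ab))
  # old-style charge code in the atom line: 1..3 -> +3..+1, 5..7 -> -1..-3
  code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, length(sym))
  chg <- ifelse(code == 0 | code == 4, 0L, 4L - as.integer(code))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  list(sym = unname(sym), chg = unname(chg), bonds = bonds)
}

# SMILES -> graph, in canonical atom order (structure is canonicalized first).
mol_graph <- function(smiles) {
  can <- ob_canonical(smiles)
  hit <- cache_get("graph", can)
  if (!is.null(hit)) return(hit)
  mb <- ChemmineOB::convertFormat("SMI", "MOL", can)
  g <- parse_molblock(mb)
  g$smiles <- can
  cache_set("graph", can, g)
}

# Serialize a graph back to a V2000 molblock (0D coordinates) and ask
# OpenBabel for its canonical SMILES.
graph_to_smiles <- function(sym, chg, bonds) {
  key <- paste(c(sym, chg, bonds$a1, bonds$a2, bonds$order), collapse = ",")
  hit <- cache_get("g2s", key)
  if (!is.null(hit)) return(hit)
  n <- length(sym)
  head <- c("", " fragrecon", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)))
  atoms <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    sym)
  bl <- if (nrow(bonds)) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$order)
  } else {
    character(0)
  }
  chgl <- character(0)
  ch <- which(chg != 0)
  if (length(ch)) chgl <- sprintf("M  CHG  1 %3d %3d", ch, chg[ch])
  mb <- paste(c(head, atoms, bl, chgl, "M  END"), collapse = "\n")
  out <- ChemmineOB::convertFormat("MOL", "CAN", mb)
  out <- sub("[ \t\r\n]+$", "", out)
  if (!nzchar(out)) stop("internal: molblock serialization failed", call. = FALSE)
  cache_set("g2s", key, out)
}

# Sum of bond orders per atom.
bond_order_sum <- function(g) {
  bs <- numeric(length(g$sym))
  if (nrow(g$bonds)) {
    for (j in seq_len(nrow(g$bonds))) {
      bs[g$bonds$a1[j]] <- bs[g$bonds$a1[j]] + g$bonds$order[j]
      bs[g$bonds$a2[j]] <- bs[g$bonds$a2[j]] + g$bonds$order[j]
    }
  }
  bs
}

# Implicit hydrogen count per atom; errors on valence violations, which is
# how structurally invalid (e.g. pentavalent-carbon) SMILES are rejected.
implicit_hydrogens <- function(g) {
  bs <- bond_order_sum(g)
  h <- integer(length(g$sym))
  for (i in seq_along(g$sym)) {
    if (g$sym[i] == "*") { h[i] <- 0L; next }
    av <- atom_allowed_valence(g$sym[i], g$chg[i])
    if (length(av) == 1 && is.na(av)) { h[i] <- 0L; next }  # exotic element: trust input
    ok <- av[av >= bs[i]]
    if (!length(ok)) {
      stop("valence violation at atom ", i, " (", g$sym[i],
           if (g$chg[i] != 0) sprintf(" charge %+d", g$chg[i]) else "",
           ", bond order sum ", bs[i], ") in '", g$smiles %||% "<structure>",
           "'", call. = FALSE)
    }
    h[i] <- as.integer(min(ok) - bs[i])
  }
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_heavy_atoms <- function(g) sum(g$sym != "*" & g$sym != "H")

n_markers <- function(g) sum(g$sym == "*")

# A bond is acyclic iff it is a bridge of the molecular graph.
acyclic_bonds <- function(g) {
  if (!nrow(g$bonds)) return(logical(0))
  ig <- igraph::graph_from_data_frame(
    g$bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_along(g$sym)))
  res <- rep(FALSE, nrow(g$bonds))
  res[as.integer(igraph::bridges(ig))] <- TRUE
  res
}

ring_atoms <- function(g) {
  acyc <- acyclic_bonds(g)
  ring <- rep(FALSE, length(g$sym))
  for (j in which(!acyc)) {
    ring[g$bonds$a1[j]] <- TRUE
    ring[g$bonds$a2[j]] <- TRUE
  }
  ring
}

# Smallest-set-of-smallest-rings count for a connected structure.
ring_count <- function(g) {
  n_comp <- if (length(g$sym) == 0) 0L else {
    ig <- igraph::graph_from_data_frame(
      g$bonds[, c("a1", "a2")], directed = FALSE,
      vertices = data.frame(name = seq_along(g$sym)))
    igraph::count_components(ig)
  }
  nrow(g$bonds) - length(g$sym) + n_comp
}

# Split a graph into connected components, each re-serialized to SMILES.
graph_components <- function(sym, chg, bonds) {
  ig <- igraph::graph_from_data_frame(
    bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_along(sym)))
  memb <- igraph::components(ig)$membership
  lapply(unique(memb), function(k) {
    idx <- which(memb == k)
    remap <- match(seq_along(sym), idx)
    keep <- bonds$a1 %in% idx & bonds$a2 %in% idx
    bsub <- bonds[keep, , drop = FALSE]
    bsub$a1 <- remap[bsub$a1]
    bsub$a2 <- remap[bsub$a2]
    graph_to_smiles(sym[idx], chg[idx], bsub)
  })
}
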