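# Molecular substrate: canonical SMILES, descriptors, fingerprints, Tanimoto
# similarity and the rule-based drug-likeness filters.

ROT_BOND_SMARTS <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"
LIPINSKI_ACCEPTOR_SMARTS <- "[#7,#8]"
FINGERPRINT_NAME <- "ECFP4"   # circular, radius 2, 4096 bits (OpenBabel)

#' Canonicalize a SMILES string
#'
#' Parses a SMILES string with OpenBabel, audits atom valences, and returns a
#' `molecule` object keyed by its canonical SMILES.  Two spellings of the same
#' structure yield identical `smiles_canonical`; canonicalization is
#' idempotent.  Attachment markers (`*`) are permitted and excluded from the
#' heavy-atom count.
#'
#' @param smiles A single SMILES string.
#' @param id Optional identifier carried on the molecule.
#' @return A `molecule`: list with `smiles_canonical`, `heavy_atom_count`,
#'   `n_markers` and `id`.
#' @examples
#' canonicalize("C1=CC=CC=C1")$smiles_canonical  # same as for "c1ccccc1"
#' @export
canonicalize <- function(smiles, id = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles))) {
    stop("'smiles' must be a single non-empty string", call. = FALSE)
  }
  g <- mol_graph(smiles)
  implicit_hydrogens(g)   # valence audit; errors on violation
  structure(
    list(smiles_canonical = g$smiles,
         heavy_atom_count = n_heavy_atoms(g),
         n_markers = n_markers(g),
         id = id),
    class = "molecule")
}

is_molecule <- function(x) inherits(x, "molecule")

as_molecule <- function(x, id = NULL) {
  if (is_molecule(x)) x else canonicalize(x, id = id)
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", if (!is.null(x$id)) paste0(" ", x$id) else "", " ",
      x$smiles_canonical, " (", x$heavy_atom_count, " heavy atoms)\n",
      sep = "")
  invisible(x)
}

# OpenBabel property block + SMARTS counts for one marker-free structure.
ob_profile <- function(smiles_canonical) {
  hit <- cache_get("profile", smiles_canonical)
  if (!is.null(hit)) return(hit)
  res <- ChemmineOB::forEachMol("SMILES", smiles_canonical, function(m) {
    list(prop = ChemmineOB::prop_OB(list(m)),
         hba = ChemmineOB::smartsSearch_OB(list(m), LIPINSKI_ACCEPTOR_SMARTS),
         rot = ChemmineOB::smartsSearch_OB(list(m), ROT_BOND_SMARTS))
  })[[1]]
  cache_set("profile", smiles_canonical, res)
}

#' Compute physicochemical descriptors
#'
#' Molecular weight (average atomic masses, implicit hydrogens included),
#' OpenBabel's additive logP estimate, Lipinski donor count (N/O atoms bearing
#' at least one hydrogen), Lipinski acceptor count (N plus O atoms), rotatable
#' bonds (acyclic single bonds between non-terminal heavy atoms, triple-bond
#' neighbours excluded) and topological polar surface area.
#'
#' @param mol A `molecule` (or SMILES string) without attachment markers.
#' @return A `descriptor_set`: list with `mw`, `clogp`, `hbd`, `hba`,
#'   `rotatable_bonds`, `tpsa`.
#' @export
compute_descriptors <- function(mol) {
  mol <- as_molecule(mol)
  if (mol$n_markers > 0) {
    stop("descriptors are defined for marker-free structures; strip markers first",
         call. = FALSE)
  }
  p <- ob_profile(mol$smiles_canonical)
  structure(
    list(mw = as.numeric(p$prop$MW),
         clogp = as.numeric(p$prop$logP),
         hbd = as.integer(p$prop$HBD),
         hba = as.integer(p$hba),
         rotatable_bonds = as.integer(p$rot),
         tpsa = as.numeric(p$prop$TPSA)),
    class = "descriptor_set")
}

#' Construct a descriptor set from explicit values
#'
#' Useful for probing the rule filters directly.
#'
#' @param mw,clogp,hbd,hba,rotatable_bonds,tpsa Descriptor values.
#' @return A `descriptor_set`.
#' @export
descriptor_set <- function(mw, clogp, hbd, hba, rotatable_bonds, tpsa) {
  structure(list(mw = mw, clogp = clogp, hbd = hbd, hba = hba,
                 rotatable_bonds = rotatable_bonds, tpsa = tpsa),
            class = "descriptor_set")
}

#' Circular fingerprint of a molecule
#'
#' Deterministic ECFP-type circular fingerprint (radius 2, 4096 bits, via
#' OpenBabel).  Identical structures give bit-identical fingerprints.
#' Attachment markers are stripped before fingerprinting, so comparison is
#' constitutional.
#'
#' @param mol A `molecule` or SMILES string.
#' @return A `fingerprint`: list with logical `bits` and `n_bits`.
#' @export
fingerprint <- function(mol) {
  mol <- as_molecule(mol)
  smi <- if (mol$n_markers > 0) strip_marker_smiles(mol$smiles_canonical) else
    mol$smiles_canonical
  hit <- cache_get("fp", smi)
  if (!is.null(hit)) return(hit)
  bits <- ChemmineOB::forEachMol("SMILES", smi, function(m) {
    ChemmineOB::fingerprint_OB(list(m), FINGERPRINT_NAME)
  })[[1]]
  fp <- structure(list(bits = as.logical(as.vector(bits)),
                       n_bits = length(bits)),
                  class = "fingerprint")
  cache_set("fp", smi, fp)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`; symmetric, bounded in `[0, 1]`, and exactly 1 for
#' identical non-empty fingerprints.  Two all-zero fingerprints compare as 0
#' so that featureless stubs are never declared duplicates by vacuity.
#'
#' @param a,b `fingerprint` objects with equal `n_bits`.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$n_bits != b$n_bits) {
    stop("fingerprints have different lengths (", a$n_bits, " vs ", b$n_bits,
         ")", call. = FALSE)
  }
  union <- sum(a$bits | b$bits)
  if (union == 0) return(0)
  sum(a$bits & b$bits) / union
}

rule_check <- function(violations) {
  structure(list(pass = length(violations) == 0L, violations = violations),
            class = "rule_check")
}

#' @export
print.rule_check <- function(x, ...) {
  if (x$pass) cat("pass\n") else cat("fail:", paste(x$violations, collapse = ", "), "\n")
  invisible(x)
}

#' Rule-of-three fragment filter
#'
#' Fragment-likeness test: molecular weight strictly below 300, cLogP at most
#' 3, at most 3 hydrogen-bond donors and at most 3 acceptors.  All violated
#' clauses are reported, not only the first.
#'
#' @param d A `descriptor_set`.
#' @return A `rule_check`: list with `pass` and `violations`.
#' @export
check_ro3 <- function(d) {
  stopifnot(inherits(d, "descriptor_set"))
  v <- character(0)
  if (!(d$mw < 300)) v <- c(v, "mw")
  if (!(d$clogp <= 3)) v <- c(v, "clogp")
  if (!(d$hbd <= 3)) v <- c(v, "hbd")
  if (!(d$hba <= 3)) v <- c(v, "hba")
  rule_check(v)
}

#' Lipinski rule-of-five plus Veber filter
#'
#' Drug-likeness test used when accepting reconstructed ligands: MW <= 500,
#' cLogP <= 5, donors <= 5, acceptors <= 10 (Lipinski) and rotatable bonds
#' <= 10, TPSA <= 140 A^2 (Veber).  All bounds inclusive; every violated
#' clause is reported.
#'
#' @param d A `descriptor_set`.
#' @return A `rule_check`: list with `pass` and `violations`.
#' @export
check_lipinski_veber <- function(d) {
  stopifnot(inherits(d, "descriptor_set"))
  v <- character(0)
  if (!(d$mw <= 500)) v <- c(v, "mw")
  if (!(d$clogp <= 5)) v <- c(v, "clogp")
  if (!(d$hbd <= 5)) v <- c(v, "hbd")
  if (!(d$hba <= 10)) v <- c(v, "hba")
  if (!(d$rotatable_bonds <= 10)) v <- c(v, "rotatable_bonds")
  if (!(d$tpsa <= 140)) v <- c(v, "tpsa")
  rule_check(v)
}
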