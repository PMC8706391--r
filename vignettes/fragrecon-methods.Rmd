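---
title: "Deconstruction–reconstruction design of Hsp90 inhibitor candidates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fragrecon methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragrecon)
```

`fragrecon` generates candidate Hsp90 inhibitors by cutting known ligands
into small fragments and recombining them, either exhaustively over the
fragment cross product or with a simulated-annealing search. This vignette
explains the model, the parameters that matter, the numerical choices, and
what the package's tests do and do not establish.

## The pipeline

### Deconstruction and the cleavable-bond rule

A known ligand is cut **simultaneously** at every *acyclic single bond
between two heavy atoms of which at least one lies in a ring*. This covers
ring–chain bonds (e.g. an N-butyl attachment), ring–ring single bonds
(biaryl linkers), and ring–heteroatom bonds whose substituent continues
(aryl methyl ethers are cut at the aryl–O bond, keeping the methoxy group
whole). Bonds wholly inside acyclic chains are never cut, so an acyl side
chain such as `*C(=O)NCC` survives as one piece. Each broken bond leaves
one attachment marker (`*`) on both pieces, and the heavy-atom multiset is
conserved across the raw pieces (a tested invariant of `cleave_ligand()`).

Pieces are then filtered by the rule of three *evaluated on the
marker-stripped form* (markers become implicit hydrogens): MW < 300
(strict), cLogP ≤ 3, donors ≤ 3, acceptors ≤ 3. Pieces failing any clause
are discarded, not re-merged. Finally, duplicated pieces within the ligand
collapse to one, which is what makes the per-ligand sub-ligand count match
the worked PU3 example: PU3 cuts into 8 raw pieces; the purine core is
discarded (its Lipinski N+O acceptor count is 4) and the three methoxy
copies collapse, leaving exactly 5 sub-ligands:

```{r pu3}
vapply(fragment_ligand(load_pu3()), function(f) f$smiles_with_markers,
       character(1))
```

This rule was chosen as the simplest one consistent with the worked example
count of five; the pieces it yields for other library members (intact side
chains, whole methoxy groups, terminal amines/hydroxyls cut as one-atom
fragments when attached to rings) follow from the same single clause.

### Duplicate detection

Two structures are duplicates iff their fingerprints have Tanimoto
similarity exactly 1 **or** their canonical SMILES coincide. Fingerprints
are OpenBabel ECFP4 — circular, radius 2, 4096 bits, deterministic — and are
computed on marker-stripped forms, so marker placement never distinguishes
copies; the first occurrence in input order survives. Two all-zero
fingerprints compare as 0, not 0/0, so featureless stubs are never
vacuously merged. At this fingerprint density, Tanimoto 1 practically
implies constitutional identity, and the SMILES clause catches the
remainder.

### Reconstruction and the census

Headers are the marker-bearing deduplicated fragments; bodies are the
marker-stripped forms of *all* deduplicated fragments (marker-free
fragments are usable only as bodies). The semi-exhaustive pass couples
every header's **first** marker (canonical atom order) with every body,
fills any residual markers with uniformly drawn bodies (one draw sequence
per candidate, seeded), rejects candidates failing Lipinski + Veber, and
deduplicates survivors. The census

`n == generated − rnl − dnl`, with `generated = |headers| × |bodies|`,

is asserted after every run; when every fragment carries a marker the two
sets are equinumerous with the sub-ligand set and the census is the square
form `N = (NFL − DF)² − RNL − DNL`. Coupling-infeasible pairs (a body with
no free valence, e.g. a perfluorinated stub) are counted inside `rnl` so
the identity stays exact. The body-side attachment atom is the first
free-valence heavy atom in canonical order by default (a seeded `"random"`
policy is available); determinism was preferred because any other
convention is unrecoverable from the method description. Output is sorted
by canonical SMILES so runs diff cleanly.

### Simulated annealing

A solution is one header plus an ordered body list, one body per marker.
Per restart (`max_tries`, default 5), an initial solution is picked by a
size-`competition_size` tournament of random solutions (default 5), and the
inner loop runs while `T > final_temp` and fewer than `stuck_limit`
consecutive iterations (default 50) have passed without improving the best
energy. Each iteration proposes a *change* (accepted when not worse;
worsening accepted with probability exp(−Δf/T)); an accepted change is
followed by exactly one *swap* proposal, accepted only when not worse.
`T ← αT` once per iteration.

Numerical choices:

* **Metropolis sign.** The acceptance uses exp(−(f(new) − f(cur))/T); under
  minimization a positive exponent would accept every deterioration, which
  contradicts a cooling schedule, so the corrected sign is used.
* **Ties.** Equal-energy moves are accepted (`≤`), as in the source
  procedure's comparisons; this also makes a constant scorer accept every
  proposal.
* **Infeasibility.** Unrealizable or filter-violating solutions evaluate to
  +Inf, which loses every comparison; the empty incumbent starts at +Inf.
  If two tournament rounds produce only infeasible candidates the search
  starts from an infeasible solution (flagged `infeasible_start`) rather
  than aborting — any feasible move then improves on +Inf.
* **Neighbourhood fallback.** The change move draws from bodies with
  Tanimoto > 0 to the removed one; when that set is empty the whole pool is
  used, keeping the move total.
* **Defaults** (`initial_temp` 10, `final_temp` 0.01, α 0.95) give ~135
  cooling steps per restart — seconds on the packaged groups with the
  surrogate scorer; all are configurable. `pos` (docking poses) is carried
  in the config for docking scorers and ignored by the others.
* **Randomness.** One seed in `sa_config()` drives everything; the trace
  echoes it, and equal seeds give byte-identical traces.

A caveat worth stating: the heuristic is **not** dominated by the
semi-exhaustive pass in general. For multi-marker headers the
semi-exhaustive pass fills residual markers randomly (one fill sequence per
header × first-body pair), while the annealer optimizes the full body
assignment, so it can reach assemblies the semi-exhaustive enumeration
never sampled. The subset relation — heuristic best ≥ semi-exhaustive
best — holds exactly when every header carries one marker, and that is the
configuration in which the test suite asserts it.

## Scoring

Binding energies are on the docking scale (kcal/mol, lower is better).
The lookup scorer serves the 68 packaged reference energies keyed by
canonical SMILES and reports anything else unavailable. The surrogate
scorer is a fixed, documented descriptor formula,

`E = −(1.0·log(1+MW) + 0.3·HBA + 0.5·rings) + 0.05·cLogP²`,

chosen only to be deterministic, cheap, and monotone in size/polarity so
that search behaviour is testable; its weights are constants, not fitted.
Structures above a heavy-atom cap (default 60) score unavailable, mirroring
a ligand too large for a docking grid; selection logic treats unavailable
as worse than any finite energy. The docking adapter is a contract only:
it validates the engine and receptor paths at construction, serializes the
standard protocol parameters (45×45×45 grid points, 0.375 Å spacing, 100
runs, population 150, 1 Å RMS clustering), and parses the most negative
pose energy; no engine or receptor is shipped, and no printed docking
energy is reproduced by the package.

## Descriptors and their conventions

MW is the sum of average atomic masses including implicit hydrogens; cLogP
is OpenBabel's additive (Crippen-type) estimate; donors are N/O atoms
bearing hydrogen and acceptors are the N+O count (one consistent Lipinski
convention for both filters); rotatable bonds are acyclic single bonds
between non-terminal heavy atoms excluding triple-bond neighbours; TPSA is
the topological polar surface area in Å². The acceptor convention matters:
it is what excludes the purine core during PU3 deconstruction. Valences
are audited on parse (a pentavalent carbon is a parse error), with charge
adjustments for the protonated amines occurring in the reference tables.

## The packaged data

The reference library holds the 68 ligands with printed structures
(binding energies as published; families resorcinol, hydroxy-indazole,
"others"); the tables name 70 components, but M16, M57 and M70 have no
printed structure, so group definitions referencing M70 load with a warning
and skip it rather than inventing a structure. PU3 is packaged from its
literature structure. Stereochemistry survives canonicalization but is
dropped by the fragmentation/coupling path (0D molblock round trips) and
ignored by fingerprints — reconstruction is constitutional.

## What the tests show, and what they do not

Tests run the pipeline on the packaged library and on small synthetic
libraries built from ~10 one-ring ligands: large enough to exercise
multi-marker headers, duplicate collapse, filter rejections and
infeasibility, small enough that the whole suite (including 100 randomized
census checks and a five-seed annealing-versus-enumeration comparison on a
2-header × 3-body library) runs in a few minutes on one CPU. They establish
the structural invariants — census identity, atom conservation, dedup
idempotence, filter compliance of every emitted ligand, monotone best
energy, geometric cooling, seeded reproducibility — and the package's
agreement with the printed library statistics and worked examples. They do
not validate docking energies, synthesizability, or biological activity of
generated ligands, and the surrogate scorer's ranking has no pharmacological
meaning.
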