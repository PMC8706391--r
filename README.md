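# fragrecon

Fragment-based deconstruction–reconstruction of Hsp90 inhibitor candidates.

Heat-shock protein 90 (Hsp90) is a chaperone and a long-standing oncology
drug target. `fragrecon` implements, in R, a fragment-based drug-design
(FBDD) pipeline that generates candidate Hsp90 inhibitors from a library of
known ligands, for computational chemists who want a transparent, fully
scriptable deconstruction–reconstruction workflow that is testable without a
docking engine.

## The method

**Deconstruction.** Every known ligand is cut simultaneously at each acyclic
single bond incident to a ring atom. Each piece keeps one attachment marker
(`*`) per broken bond. Pieces whose marker-stripped form violates the
rule of three (MW < 300, cLogP ≤ 3, H-bond donors ≤ 3, acceptors ≤ 3) are
discarded; duplicated pieces collapse. Pooling over ligands and
deduplicating (fingerprint Tanimoto = 1 or identical canonical SMILES) gives
the sub-ligand library: headers (SL\*, markers kept) and bodies (SL, markers
hydrogenated), with the census NSL = NFL − DF.

**Semi-exhaustive reconstruction.** Every header is crossed with every body:
the body bonds into the header's first marker, residual markers are filled
with uniformly drawn bodies, and candidates failing Lipinski's rule of five
(MW ≤ 500, cLogP ≤ 5, donors ≤ 5, acceptors ≤ 10) or Veber's rules
(rotatable bonds ≤ 10, TPSA ≤ 140 Å²) are rejected. After a final
deduplication the census satisfies

> N = (NFL − DF)² − RNL − DNL

(generalized to N = generated − RNL − DNL when some fragments carry no
markers), and `verify_accounting()` checks it on every run.

**Heuristic search.** A simulated-annealing search over header-plus-bodies
assemblies: a *change* move replaces a random body within its Tanimoto
neighbourhood (similarity > 0), an accepted improving change is followed by
one *swap* of two body positions, worsening changes are accepted with
probability exp(−Δf/T) under a geometric cooling schedule (factor α), with
restarts and a stuck criterion.

**Scoring** is pluggable: a lookup scorer serving the packaged binding
energies, a deterministic descriptor surrogate for testing, and an adapter
contract for an external docking engine (grid 45×45×45 points, 0.375 Å
spacing, 100 runs, population 150, 1 Å RMS pose clustering as defaults).

The package ships the reference library of 68 Hsp90 ligands (resorcinol,
hydroxy-indazole and "others" families, with binding energies in kcal/mol)
and the eight experiment group definitions.

## Worked example

```r
library(fragrecon)

# the PU3 worked example: five sub-ligands
vapply(fragment_ligand(load_pu3()),
       function(f) f$smiles_with_markers, character(1))
#> [1] "*CCCC"  "*C*"  "*c1cc(*)c(c(c1)*)*"  "*OC"  "*N"

# library statistics of the packaged 68 ligands
unlist(library_stats(load_reference_library()))
#>     min_be     max_be    mean_be   n_at_min
#> -11.300000   9.200000  -8.566176   2.000000

# group-1 experiment end to end with the surrogate scorer
run_experiment(1, "semi_exhaustive", surrogate_scorer(), seed = 7)
#> <experiment_report> group 1 mode semi_exhaustive seed 7
#>   known ligands: 5  sub-ligands: 20  new ligands: 379
#>   best KL energy: -9.851671  best NL energy: -11.03215  improvement: 12%
#>   best new ligand: N1CCN(CC1)c1cc2c(cc1N1CCNCC1)[nH]nc2c1ccc2c(c1)[nH]nc2
```

The five PU3 sub-ligands are the butyl chain, the benzylic methylene, the
trimethoxyphenyl ring (as phenyl plus methoxy), and the exocyclic amine; the
purine core itself exceeds the rule-of-three acceptor cap and is discarded.
`min_be`/`max_be` are the best (−11.3) and worst (9.2) docking-derived
binding energies in the packaged library, attained by `n_at_min = 2` ligands
at the minimum. In the experiment report, energies are surrogate units
(lower is better) and "improvement" is the percent gain of the best new
ligand over the best known ligand under the same scorer.

A thin command-line front end wraps the same functions:

```sh
exec/fragrecon deconstruct --in ligands.smi --out libdir
exec/fragrecon reconstruct --library libdir --seed 3 --out recon
exec/fragrecon search --library libdir --scorer surrogate --seed 3 --out trace.tsv
```

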