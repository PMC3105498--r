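---
title: "Methods: RDF-backed molecular chemometrics in chemrdf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RDF-backed molecular chemometrics in chemrdf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemrdf)
```

chemrdf connects two representations of molecular knowledge: RDF graphs,
in which facts about molecules, assays, targets and spectra are
subject--predicate--object triples that can be merged across databases and
queried with SPARQL; and the numeric matrices on which chemometric models
operate. This vignette documents the models, the tunable parameters, the
numerical choices, and the design decisions that were genuinely open, plus
what the synthetic data can and cannot demonstrate.

## The RDF backbone

The in-memory `TripleStore` holds a duplicate-free triple set with a
prefix map. Terms use a canonical string encoding (IRIs in angle
brackets, `_:` blanks, escaped literals with optional datatype or
language tag), which makes joins plain character comparisons.

The Turtle/Notation3 reader and writer support the subset every document
in this package needs: prefix and base declarations, `a`, `;` and `,`
lists, anonymous `[]` nodes, and typed, plain, numeric and boolean
literals. RDF collections, N3 rules and paths are rejected with a parse
error naming the line. The SPARQL engine evaluates `SELECT` with an
explicit projection (no `SELECT *`), basic graph patterns, `DISTINCT`,
`FILTER` (comparisons, `regex`, `&&`/`||`/`!`), `OPTIONAL` and `LIMIT`.
Everything outside this subset --- `UNION`, `ORDER BY`, property paths,
aggregation --- raises an "unsupported SPARQL feature" error; the engine
never silently returns a wrong answer for syntax it does not implement.

Basic graph patterns are evaluated pattern-by-pattern with hash joins on
shared variables; `OPTIONAL` is a left join leaving unbound cells `NA`
(empty in CSV export). The tests check the join semantics against an
independent brute-force oracle that enumerates every assignment of store
triples to patterns.

Round-trip fidelity is defined up to blank-node renaming: two stores are
isomorphic when a bijection between their blank nodes equalizes the
triple sets. The search is exhaustive with a degree/predicate signature
for pruning and a safety cap (default 10 blanks) --- fixtures stay far
below it, and the cap fails loudly rather than degrading.

Namespaces: the published serializations name their classes and
properties (Molecule, Atom, Bond, `hasAtom`, `hasBond`, `symbol`,
`order`; descriptor provenance via `instanceOf`, parameters and software)
but no resolvable namespace IRIs, so the package fixes its own
`example.org` namespaces, documented in `inst/extdata/vocabulary.ttl`,
and keeps resource URIs in the `example.com`/`example.org` style of the
original examples. The InChI resolver base
(`http://rdf.openmolecules.net/`) is the one documented convention and is
kept, configurably, as the default for `owl:sameAs` identity links.

## Chemical graphs and SMILES

`Molecule` is an atom/bond graph with implicit hydrogens. The SMILES
grammar covers the organic subset (B, C, N, O, P, S, F, Cl, Br, I, the
aromatic lowercase forms), bracket atoms with explicit hydrogen counts
and charges, branches, dot disconnections, and ring closures `1`--`9` and
`%nn`. Stereochemistry, isotopes and atom maps are out of scope and
rejected with an error naming the offending token and position, as are
conflicting bond symbols on the two ends of a ring closure.

Implicit hydrogens on non-bracket atoms complete the standard valence
(B 3, C 4, N 3, O 2, P 3, S 2, halogens 1); bracket atoms take their
hydrogen count literally. An aromatic bond counts 1.5 toward the used
valence and the remainder is rounded down --- the convention that gives
each benzene carbon exactly one hydrogen and pyridine's nitrogen none.
The suite pins this behaviour to a frozen table of 200
generator-produced structures whose atom counts, bond counts, Hill
formulas, weights and TPSA values were computed once with RDKit
(`tests/testthat/fixtures/smiles_oracle.tsv`).

RDF serialization mints one resource per atom and bond. Because RDF
asserts no statement order, atom and bond indices are written explicitly
(`cdk:index`) so that deserialization is order-deterministic and the
round-trip preserves the graph exactly --- atom count, bond orders,
charges, implicit hydrogens, aromatic flags and name.

SD export writes V2000 molblocks with zero coordinates (no layout
engine in scope), charges on `M  CHG` lines, and per-molecule data
items; files are verified by re-reading them with ChemmineR.

## Descriptors with provenance

Five descriptors are registered: heavy atom count, bond count, ring
count (the cyclomatic number, bonds − atoms + connected components),
molecular weight, and topological polar surface area. TPSA is the sum of
fragment contributions over nitrogen/oxygen environments, matched on
element, aromaticity, charge, hydrogen count, bond-order profile and
3-ring membership. The table covers the classic N/O environments; an N
or O environment outside the table is an explicit "contribution
unavailable" error rather than a silent zero, because the point of the
module is trustworthy provenance, not descriptor completeness. Sulfur
and phosphorus contribute nothing, the classic N/O-only convention. The
`checkAromaticity` parameter (default `FALSE`, mirroring the published
example where "aromaticity was not detected") controls whether
lowercase-SMILES aromatic flags are revalidated against ring membership
before use; with `TRUE`, an aromatic-marked atom on no cycle is an
error.

Every result is a `DescriptorResult` carrying the parameter values as
used and the software name/version, and serializes to the Blue Obelisk
descriptor-ontology pattern: a result resource linked `instanceOf` its
dictionary entry, one resource per parameter, a software resource, and
the value as an `xsd:decimal` literal printed with 17 significant digits
so the parsed-back value is bit-identical.

## The synthetic ChEMBL-like store

No real database content ships with the package. `generateChemblStore()`
emulates the shape of a ChEMBL SPARQL endpoint: targets with a
seven-level classification, organism, type and a pre-aligned protein
sequence; assays with integer confidence scores; activities with type
(IC50, Ki, "Ki app", Inhibition, Activity), positive value and unit; and
molecules with SMILES from a conservative generator grammar (chains,
benzene/pyridine, saturated carbo- and heterocycles, polar substituents)
chosen so implicit-hydrogen and TPSA conventions are toolkit-standard.

Two signals are planted and returned as ground truth:

* **QSAR**: activities of the kinase-style target (id 10885, the running
  example id) are `pIC50 = 6 + x'beta + e`, where `x` is the
  standardized 5-descriptor vector and `e` has standard deviation
  `noiseBaseSd / sqrt(confidence)`. Confidence scores are drawn from
  {1, 3, 9} with base SD 0.6 --- about a half-log-unit of assay noise at
  middling confidence, a realistic figure for pooled literature IC50
  data. Values are rendered in nM or (30% of rows) uM to exercise unit
  conversion.
* **PCM**: 18 ion-channel targets (8 sodium-channel alpha subunits, 10
  calcium-channel alpha-1 subunits, mirroring the reference design, so
  that the protein block supports exactly 17 principal components)
  receive Ki/IC50 activities from a bilinear model: ligand descriptors,
  mean z-scale protein effects, and their products, scaled to unit signal
  variance plus Gaussian noise (SD 0.2).

The shipped extraction queries (`inst/extdata/queries/`) bind the
documented variable sets: seven for QSAR (`act, ass, mol, smiles, val,
unit, conf`) and nine for PCM (`target, type, pubmed, l4, l5, l6,
smiles, val, seq`). The nine-variable contract counts the molecule and
its SMILES as one property, so the query projects `?smiles` (which
identifies the molecule uniquely in the synthetic store) rather than a
tenth variable. PCM-branch activities are always recorded in nM for the
same reason: the nine fields leave no room for a unit column, and the
PCM assembly interprets `val` as nanomolar. Extraction runs through the
package's own SPARQL engine and is tested for full-table equality
against a direct scan of the generator's record tables.

`qsarMatrix()` follows the documented preprocessing: activities to molar,
negative decadic logarithm, response and descriptor columns centered and
scaled to unit variance, constant descriptor columns dropped with a
warning, and weights `w = confidence / mean(confidence)` so they average
one --- "proportionally higher weights" realized as the simplest
proportional map (alternatives can be injected by transforming `conf`
before the call).

## Bayesian weighted ridge regression

The model is

$$y \mid \beta, \sigma^2 \sim N(X\beta,\ \sigma^2 W^{-1}), \qquad
\beta \mid \tau^2 \sim N(0, \tau^2 I),$$

with $W = \mathrm{diag}(w)$ and inverse-gamma(0.001, 0.001) hyperpriors
on both variances --- weakly informative defaults, configurable, standing
in for the unpublished defaults of the original JAGS fit. The Gibbs
sampler cycles the standard full conditionals; the $\beta$ draw uses one
Cholesky factorization of the conditional precision
$X'WX/\sigma^2 + I/\tau^2$ per iteration. Defaults are 12,000 iterations
with 2,000 burn-in; the correctness tests use fixed-variance runs where
the exact Gaussian posterior is available in closed form and compare
means (within 3 Monte-Carlo standard errors) and covariances (10%
Frobenius). Chains are exactly reproducible from the seed.

Cross-validation draws folds by a seeded permutation cut into contiguous
blocks, with earlier folds taking the remainder rows. Each fold is
refitted with a fold-derived seed and its held-out rows predicted per
posterior draw; PRESS draw $s$ sums squared deviations from draw $s$'s
predictions over all rows, and the summary is the posterior mean with a
central 95% interval --- the "9.3 (7.6; 12.8)" reporting format. Whether
such an interval should be over posterior draws or CV replicates is not
fixed by the reference description; the posterior-draw convention is
chosen and used consistently. `compareWeightedUnweighted()` reruns the
same folds with unit weights, the published check of whether assay
confidence helps. A fold smaller than the descriptor count falls back to
fixed unit variances with a warning rather than failing.

## The proteochemometric pipeline

Aligned sequences (alignment is an upstream input; no aligner is
provided) are encoded position-wise with the classic three-component
amino-acid z-scales shipped in `inst/extdata/zscales.tsv`. A gap takes
the position mean of the non-gap residues --- the reference description is
silent on gaps, and mean imputation keeps the encoding linear and
rank-stable; all-gap positions are flagged and dropped. The encoding of
the distinct sequences is autoscaled (the centered-only alternative is
defensible; autoscaling was chosen so no alignment position dominates by
variance) and reduced by centered PCA to 17 components by default,
clamped to the available rank with a warning.

The design matrix is [autoscaled ligand descriptors | protein PC scores
| autoscaled ligand-by-protein cross-terms], with all ligand descriptors
crossed with all protein components (the subset used originally is
unstated; the full product is taken). PLS1 is fitted by NIPALS with
deflation, stopping early with a warning when the residual covariance
vanishes; predictions agree with mixOmics to 1e-6 in the tests and with
ordinary least squares for a single predictor. The component count
defaults to the 1..10 grid value minimizing 5-fold PRESS, selected once
on the full data, since no count is published. Predictive ability is the
Pearson correlation between 7-fold held-out predictions and observations;
VIP scores (mean square one over columns) rank descriptor importance
with ties broken by column order.

## NMR dereplication

Spectra serialize to RDF as one resource per peak with the shift as an
`xsd:decimal` in ppm. "Near" is an explicit tolerance, default 0.5 ppm
(a 13C-scale figure); the published behaviour is described but no
formula is given, so the package defines the similarity score as the
fraction of query peaks that find a one-to-one partner by greedy
nearest-neighbour assignment within tolerance. Results are ranked by
score, then mean absolute deviation, then spectrum id. The fractional
score subsumes both all-peaks-must-match and any-subset semantics
(threshold at 1 for the former). The synthetic reference generator
enforces a minimum separation between any two database peaks (default
1.2 ppm, i.e. more than twice the default tolerance), which makes
self-dereplication provably unambiguous --- the property the acceptance
checks exercise on 50 seeded databases.

## Problem sizes, determinism, and limits

The test suite and `scripts/acceptance.R` use desk-scale problem sizes
chosen as the smallest at which each property is statistically sharp:
closed-form sampler agreement on a 100 x 5 problem with 20,000 draws;
95% predictive coverage on 500 simulated points; the weighted-beats-
unweighted comparison at n = 300, p = 10 over 20 seeded replicates;
PCM recovery at ~300 compound--protein pairs over 18 proteins; 100
random-store round-trips; 50 dereplication databases. Every stochastic
step is seeded, and identical seeds give bit-identical chains, folds,
stores and files.

What passing does and does not show: the synthetic generator plants
linear and bilinear signals in exactly the descriptor spaces the models
search, with Gaussian noise and a clean confidence-to-variance map. Real
assay data have correlated descriptors, non-Gaussian errors, censored
values ("> 10000 nM"), inter-laboratory shifts and activity cliffs, none
of which are emulated. The published headline numbers (PRESS 9.3 vs
11.2 on 449 compounds; PCM r = 0.79 on 1149 pairs) depend on the real
ChEMBL content and a commercial descriptor set and are deliberately not
reproduction targets; the package demonstrates the methods' correctness
and the qualitative phenomena (weighting helps under heteroscedastic
confidence; the bilinear ligand--protein signal is recoverable) on data
whose ground truth it controls.

Known limitations: the SPARQL subset has no `UNION`/paths/aggregates;
molecules are limited to the 11-element organic subset without
stereochemistry; TPSA fails (by design) outside its N/O table; the
isomorphism check is exponential in blank-node count and capped;
`molecularWeight` uses abridged standard atomic weights (two to three
decimals), so weights match full-precision toolkits to about 0.02 Da.
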