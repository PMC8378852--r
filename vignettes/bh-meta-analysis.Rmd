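---
title: "Curation and meta-analysis of Buchwald-Hartwig coupling corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and meta-analysis of Buchwald-Hartwig coupling corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pd-catalysed C-N cross-coupling (Buchwald-Hartwig amination) couples an
amine nucleophile with an aryl or heteroaryl (pseudo)halide electrophile.
Reaction databases hold tens of thousands of such records, but the raw
entries are messy: ligands and bases sit in a generic "reagents" field,
solvents are inconsistently declared, the Pd source may be a salt, a
mixture, or a defined complex, the same reaction appears in several
sources, and tautomeric groups are drawn inconsistently between reactant
and product records. **bhmeta** implements a curation pipeline that turns
such records into analysable reactions, plus the analyses a practitioner
wants on top: per-class condition cheatsheets, a Pareto-front ligand
recommender, and corpus-level bias statistics. Because the real corpora
are licensed, the package ships a synthetic-corpus generator that emulates
their statistical structure with known ground truth, and all quantitative
claims in the package are ground-truth-recovery results on that generator.

## The curation model

The pipeline is a fixed sequence of total, tibble-to-tibble stages. Every
record removed at any stage carries exactly one discard reason, so
kept + discarded equals the input size throughout.

1. **Template filter** (`filter_template`). A record must have exactly two
   parseable reactant structures and one parseable product
   (`not_single_step` / `missing_structure` otherwise). Records whose
   product structure is absent are treated as `missing_structure`; the
   strict two-to-one template also rejects multi-product entries.
2. **Pd filter** (`filter_pd_catalyzed`). A palladium atom must occur in
   at least one declared species, regardless of which field it was
   declared in -- the declared fields are exactly what we do not trust.
3. **Raw deduplication** (`basic_dedup`). Byte-identical raw rows
   collapse before any normalisation.
4. **Role resolution** (`resolve_roles`), described below.
5. **Reactant classification** (`classify_reactants`), described below.
6. **Reaction-key deduplication** (`reaction_key`,
   `dedup_keep_earliest`): cross-source duplicates collapse onto the
   earliest publication.

### Structure normalisation

Canonical SMILES and standard InChI come from Open Babel (via ChemmineOB);
the molecular graph used for substructure work is parsed from the
canonical SMILES by a small reader covering that dialect. Substructure
tests are coloured subgraph monomorphisms (igraph's VF2) over element,
aromaticity, charge and bond order; hydrogen counts are deliberately not
matched, which is what severed or newly created attachment points require.
Two normalisation modes exist: *substrate* mode keeps the largest organic
fragment and neutralises trivially ionised centres; *reagent* mode keeps
multi-fragment salts intact so that ionic bases remain identifiable by
table lookup. The canonical key is the standard InChI; note that standard
InChI treats mobile hydrogens as equivalent, so tautomeric drawings of the
same compound share a key -- a property that makes the final
deduplication robust to drawing style.

### Reagent roles

Roles are assigned per species with a fixed precedence: solvent lookup,
base lookup, phosphine rule, NHC rule, metal source, generic. The
phosphine rule declares any species with phosphorus but no
phosphorus-halogen bond a ligand; testing the base table first keeps
phosphazene superbases out of the ligand pool, and P-N / P-O bonds are
allowed so that phosphites and proazaphosphatranes are ligands. NHC
ligands and their azolium precursors are found by substructure patterns
shipped as a plain-text file. Defined complexes are handled by severing
all P-metal bonds -- and carbene-C-metal bonds, a documented extension so
NHC complexes are extracted too -- and collecting metal-free fragments
that qualify as ligands. Exactly one distinct ligand must emerge per
reaction (free species and complex extractions pooled): none discards the
record as `ligand_undetected`, several as `ligand_ambiguous`. One further
design choice: a species containing a catalytic metal (Pd, Ni, Pt, Cu,
Rh, Ru, Ir, Au, Ag) is never itself a ligand, while iron is deliberately
not on that list so ferrocene-backbone phosphines remain ligands when
declared free. When several distinct bases or solvents are declared we
keep the first-declared one and flag the record (`multi_base`,
`multi_solvent`); a `strict_roles` switch discards instead. The Pd source
is recorded but collapsed out of all downstream keys, i.e. pre-catalysts
are subsumed under their ligands.

### Reactive sites and substrate classes

Which reactant is the electrophile is decided by leaving-group
bookkeeping over Br, Cl, I, F, triflate and tosylate: if exactly one
leaving-group type changes, its reactant-minus-product count is exactly
one, and exactly one reactant carries it, that reactant is the
electrophile. Halide instances only count when bonded to an aromatic
carbon, which also prevents triflate fluorines from counting as fluoride.
When the rule fails (both reactants carry the group, several types
change), the single reactant bearing N-H nitrogens is the nucleophile;
if that also fails the record is discarded (`roles_unresolved`).

The reactive carbon is located by severing each candidate C-LG bond and
testing the remaining skeleton as a substructure of the product; the
reactive nitrogen by replacing one N-H hydrogen with a carbon and testing
likewise. Two refinements make this robust: candidates that pass are
collapsed under graph symmetry (otherwise piperazine or
1,4-dibromobenzene would always be ambiguous), and when a direct test
fails the product's tautomers are enumerated and retested, setting a
`tautomer_used` flag. The tautomer enumerator applies 1,3-hydrogen shifts
(X1=X2-X3H with X1, X3 in {N, O}, X2 carbon) on the Kekulé structure,
re-canonicalises, and iterates breadth-first up to a cap of 64 distinct
forms and 4 successive shifts; exceeding the cap simply means the record
fails as `reactive_atom_fail` rather than guessing. The scenario that
actually requires this branch is a *remote* mobile-hydrogen group drawn
in different tautomeric forms in reactant and product records (the
N-arylated nitrogen itself has no mobile hydrogen left), and that is how
the generator plants its stress case.

Electrophiles are classed by leaving group and ring kind: `HAR` when the
fused aromatic ring *system* holding the reactive carbon contains a
non-carbon ring atom, else `ARY`. The system-level reading makes a
bromide on the carbocyclic ring of quinoline heteroaryl, which matches
chemical usage; a `system_level = FALSE` switch gives the smallest-ring
reading. Nucleophiles are classed by the nitrogen's environment with the
precedence amide > aromatic-ring nitrogen > ketimine > neighbour counts
(Aryl, DiAryl, Alkyl, DiAlkyl, AlkylAryl) > Other. Amide must precede the
neighbour counts or acetanilide would land in AlkylAryl.

### Deduplication key

A reaction is identified by the SHA-256 digest of the `|`-joined InChI
keys of (electrophile, nucleophile, product, solvent, base, ligand) in
that fixed order, with a placeholder for absent slots. Temperature, time,
yield and the Pd source are deliberately excluded. Within a key group the
earliest publication year wins; ties break nonpatent-first, then source
name, then record id -- the tie-break is a documented convention, not a
claim about the literature. Yield spread within collapsed groups is
reported but never blocks deduplication.

## The analysis layer

* `median_yield_matrix` reports, per cell, the count of all records and
  the median/quartiles of the *reported* yields only -- count and colour
  are separate channels. Medians of even-sized groups interpolate
  linearly; cheatsheet ranks are sensitive to this, so it is fixed here.
* `build_cheatsheet` ranks (ligand, base) combinations per
  (electrophile class x nucleophile class) cell by median yield and keeps
  the top 3, but only combinations with at least 20 reactions are
  eligible. Both thresholds are arguments with those defaults. Median
  ties rank the better-supported combination first, then alphabetically.
* `build_profiles` + `pareto_rank` implement the ligand recommender:
  per-ligand medians and population standard deviations of molecular
  weight, heteroatom count, ring count, heteroatom-H count,
  ortho-substituent count and per-reaction Tanimoto distance, per scope
  (electrophile, nucleophile, product), plus yield. Ranking is standard
  iterated non-dominated sorting, maximising every selected statistic
  (an `invert` flag minimises); the published phrasing of
  Pareto-optimality is looser than the standard definition, and we
  implement the standard one. The yield threshold filters *after*
  ranking, mirroring the two-step flow of the interactive tool; yield can
  instead be included as a ranking objective. Single-use ligands are kept
  (standard deviation 0, `low_support` flag) rather than excluded --
  surfacing rarely used ligands is the point of the tool.
* Fingerprints are circular (Morgan-type) of radius 4 folded to 2048
  bits; the radius matches the recommender's design, the fold length is a
  documented package choice. No installed R package provides this
  fingerprint, so it is implemented here with a deterministic integer
  hash.
* `trend` functions: yearly counts, percentile-bootstrap confidence
  bands for median yield (default 2000 resamples, always seeded), an
  integer-binned yield histogram with a *spike index* -- mean count at
  bins 40..90 over mean count at their immediate neighbours, our
  quantification of round-number reporting -- cumulative reagent
  coverage, log-log least-squares Zipf fits over items with at least 5
  occurrences (the low-count tail biases the slope; maximum-likelihood
  fitting would be an alternative, not implemented as default), and
  per-year class shares.

## The synthetic generator

`generate_corpus(bh_config(...))` emulates the structure the analysis
assumes, with every parameter explicit and seeded:

* substrates drawn per class from a curated library (3+ labelled members
  per electrophile and nucleophile class); products built by joining the
  labelled reactive sites directly -- chemically simplistic by design,
  since the fidelity target is the pipeline's logic, not synthesis;
* Zipf(s = 1) ligand usage over a 12-ligand vocabulary, two dominant
  bases (planted shares 0.50/0.29) and solvents, mirroring the
  concentration phenomenon of the real literature without claiming its
  exact percentages;
* planted condition effects: median yield = 55 + ligand-by-nucleophile
  affinity + base-by-electrophile affinity, additive noise with sd 12,
  clipped to [1, 99]; yields rounded to the nearest ten with probability
  0.15 and missing with probability 0.25 (roughly the reported-yield
  availability of real corpora);
* a patent/nonpatent split whose patent share rises after 2014, a -25
  point patent yield shift before 2014, and a post-2014 surge of
  aromatic-nitrogen and diarylamine nucleophiles -- the planted analogues
  of the trends the statistics layer is meant to detect;
* cross-source duplicates (default rate 0.1) that preserve the six key
  fields exactly while changing source, year, spelling (an equivalent
  SMILES respelling), declaration order and temperature;
* declaration mess: bases always in the generic reagent field, solvents
  moved there with probability 0.3, Pd declared as a defined complex of
  the chosen ligand with probability 0.1, occasional generic additives;
* a rare "specialist" ligand (a proazaphosphatrane) boosted inside its
  niche (dialkylamine nucleophiles on heteroaryl electrophiles) with a
  high planted affinity and low overall usage -- the planted analogue of
  a rare-but-optimal ligand the recommender should surface;
* at least one planted tautomer stress case whose product is recorded in
  the pyridone drawing while the reactant uses the hydroxypyridine form.

What the generator does **not** emulate: real substrate complexity and
functional-group diversity (products are direct couplings of small
library members), name-only reagent entries beyond the alias table,
atom-mapping errors, non-single-step entries, partial structure records,
and near-duplicates that differ in salt form (a documented limitation of
canonical-key equality; a near-duplicate mode exists only as a test of
that limitation). Passing recovery tests therefore demonstrates the
correctness of the pipeline's logic under the stated statistical
conditions, not performance on licensed data.

## Numerical and design choices

* Standard deviations in profiles are population (divide by n), so a
  two-reaction ligand has a defined, finite sd; single observations give 0.
* Bootstrap CIs use the percentile method with `quantile` type 7.
* The tautomer cap (64 forms, depth 4) bounds a worst-case exponential
  enumeration; hitting the cap is a failure signal, never silent truncation.
* Pairwise Tanimoto means subsample deterministically (evenly spaced,
  cap 60) so results are reproducible without consuming RNG state.
* All randomness flows through explicit seeds (`withr::with_seed`);
  generation is a pure function of its config.
* Problem sizes used by the shipped tests and the acceptance script:
  the curated fixtures (40 reagents, 25 substrates), corpora of 250-1,200
  records for unit-level recovery, 10,000 records for the deduplication
  study, 20 corpora of 600 records for cheatsheet recovery, 5,000 records
  for the end-to-end determinism run, 500 replications for bootstrap
  coverage. These sizes give stable statistics for every planted effect
  while keeping a full run on a single CPU comfortable.

## Known limitations

* The SMILES reader covers the dialect Open Babel's canonical writer
  emits (plus the package's own bracket-rich writer); it is not a general
  SMILES parser and ignores stereochemistry throughout.
* Leaving-group and NHC patterns are the package's own graph predicates;
  exotic leaving groups (nonaflates, phosphates) and carbene classes
  (triazolylidenes, CAACs) are out of scope of the shipped tables, which
  are user-extensible CSVs.
* Solvent mixtures are reduced to the first-declared solvent rather than
  serialised as a set; records declaring several distinct bases are kept
  on the first-declared base unless `strict_roles` is set.
* The Pd filter is element presence, so a stoichiometric Pd reagent would
  pass it; in curated corpora this is the intended behaviour (declared
  fields are unreliable), but it is a filter, not a mechanism claim.
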