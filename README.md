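# bhmeta

Curation and meta-analysis of Buchwald–Hartwig (Pd-catalysed C–N
cross-coupling) reaction corpora, for chemists and cheminformaticians who
want data-driven condition recommendations and honest corpus statistics
out of messy literature reaction records.

Reaction databases report these couplings with ligands and bases buried in
a generic reagents field, solvents declared inconsistently, Pd sources
given as salts, mixtures or defined complexes, duplicates across sources,
and tautomers drawn differently in reactants and products. `bhmeta`
implements the full curation pipeline and the analyses on top of it:

* **Curation**: single-step template and missing-structure filters, a Pd
  filter, reagent role assignment (solvent/base lookup; a phosphine rule —
  phosphorus but no P–halogen bond; NHC substructure patterns; ligand
  extraction from defined complexes by severing P–metal bonds), reactive
  site detection by severing C–LG bonds / substituting N–H hydrogens and
  substructure-testing against the product (with a tautomer-enumeration
  fallback), substrate classification (leaving group × aryl/heteroaryl;
  nine nitrogen environment classes), and cross-source deduplication by a
  SHA-256 key over the InChIs of (electrophile, nucleophile, product,
  solvent, base, ligand), keeping the earliest publication.
* **Recommendation**: per-class condition *cheatsheets* — the top-3
  (ligand, base) combinations by median yield, reported only when backed
  by ≥ 20 reactions — and a *Pareto ligand recommender* that ranks ligands
  by iterated non-dominated sorting over user-selected property medians or
  standard deviations (molecular weight, heteroatom/ring/heteroatom-H/
  ortho-substituent counts, Tanimoto distance on radius-4 circular
  fingerprints, yield), with a post-ranking yield slider.
* **Corpus statistics**: reactions per year, bootstrap confidence bands
  for median yield, yield histograms with a multiples-of-ten *spike
  index*, cumulative reagent coverage, Zipf frequency–rank fits of ligand
  usage, and class share time series.

The licensed corpora (CAS, Reaxys, USPTO) are not required: a seeded
synthetic-corpus generator (`generate_corpus`) emulates their statistical
structure — Zipf-distributed reagent usage, planted condition effects,
right-skewed spiked yields, cross-source duplicates, messy reagent
declarations — together with the ground truth needed to *prove* recovery.

## Worked example

```r
library(bhmeta)

sim    <- generate_corpus(bh_config(n_reactions = 500, seed = 7))
result <- run_pipeline(read_reactions(sim$records))
pipeline_tally(result)
#>   discard_reason     n
#> 1 <NA>             494
#> 2 duplicate         56
```

550 raw records (500 plus a 10 % duplicate rate) collapse to 494 unique
reactions; the 56 removed records are cross-source duplicates (this clean
synthetic corpus triggers no other discard reason).

```r
build_cheatsheet(result, min_count = 10)
#>   ephile_class nphile_class  rank ligand   base   median_yield     n
#> 1 Br_ARY       Aryl             1 Xantphos NaOtBu           57    10
```

With only 500 records a single (electrophile × nucleophile) cell reaches
the support threshold: for coupling anilines with aryl bromides the
best-supported combination is Xantphos/NaOtBu at a median reported yield
of 57 %. (On full-size corpora the sheet fills in; the default support
rule is `min_count = 20`.)

```r
pf <- build_profiles(result)
pr <- pareto_rank(pf, c("median_heteroatoms_nphile", "median_yield"))
head(tidy(pr), 3)
#>   ligand                  front n_reactions median_yield median_heteroatoms_nphile
#> 1 XPhos                       1          32           61                       1
#> 2 Triisobutylphosphatrane     1          20           60                       1.5
#> 3 IPr-HCl                     2          15           60                       1
```

Asking for ligands whose nucleophiles are heteroatom-rich *and* whose
yields are high puts the rarely used proazaphosphatrane on front 1 next
to the workhorse XPhos — exactly the "rare but optimal" ligand the
recommender is designed to surface. `filter_by_yield(pr, 80)` then applies
the yield slider without recomputing ranks.

```r
zipf_fit(frequency_rank_table(result, "ligand_name"))
#> Zipf exponent: 0.99 (r^2 = 0.978)
yield_histogram(result)$spike_index
#> 2.22
```

Ligand usage follows the planted Zipf law (exponent ≈ 1), and the yield
histogram shows the round-number reporting artefact: bins at 40, 50, …,
90 % hold about twice the counts of their neighbours.

A thin command-line wrapper over these functions ships in
`inst/scripts/bhmeta.R` (`simulate`, `pipeline`, `cheatsheet`,
`recommend`, `trends` subcommands). The methods vignette
(`vignettes/bh-meta-analysis.Rmd`) documents the model, rules, parameter
defaults and the generator's scope.

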