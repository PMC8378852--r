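# Shared fixtures, built in code and memoised across test files.

.bh_test_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.bh_test_env[[key]])) .bh_test_env[[key]] <- force(expr)
  .bh_test_env[[key]]
}

# a small default-condition corpus, generated + fully processed once
small_processed <- function() {
  memo("small", {
    sim <- generate_corpus(bh_config(n_reactions = 250, seed = 7,
                                     duplicate_rate = 0.15))
    list(sim = sim, out = run_pipeline(read_reactions(sim$records)))
  })
}

mol <- function(s, mode = "substrate") normalize_molecule(s, mode)

# truth-level reaction identity: two records are the same reaction iff
# they share substrates, product and resolved conditions
truth_group_key <- function(truth_per_record) {
  paste(truth_per_record$ephile_name, truth_per_record$nphile_name,
        truth_per_record$ligand, truth_per_record$base,
        truth_per_record$solvent, truth_per_record$tautomer_case,
        sep = "|")
}

# raw-schema record builder for hand-written ingestion fixtures
raw_record <- function(record_id = "X1", source = "CAS",
                       doc_type = "nonpatent", pub_year = 2015L,
                       reactant_smiles = "Brc1ccccc1;Nc1ccccc1",
                       product_smiles = "c1ccc(Nc2ccccc2)cc1",
                       reagents = paste0(
                         "CC(=O)O[Pd]OC(C)=O|catalyst;",
                         "c1ccc(P(c2ccccc2)c2ccccc2)cc1|reagent;",
                         "[Na+].CC(C)(C)[O-]|reagent;Cc1ccccc1|solvent"),
                       yield_percent = 80, temperature_C = 100, time_h = 12) {
  tibble::tibble(record_id = record_id, source = source, doc_type = doc_type,
                 pub_year = pub_year, reactant_smiles = reactant_smiles,
                 product_smiles = product_smiles, reagents = reagents,
                 yield_percent = yield_percent, temperature_C = temperature_C,
                 time_h = time_h)
}
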