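# Structure normalisation, canonical keys, substructure matching and
# molecular properties.

test_that("canonicalization is spelling-invariant and idempotent", {
  a <- mol("c1ccccc1N")
  b <- mol("Nc1ccccc1")
  expect_identical(a$canonical_key, b$canonical_key)
  expect_identical(a$canonical_smiles, b$canonical_smiles)
  # idempotence: normalizing the canonical form is a fixed point
  c2 <- mol(a$canonical_smiles)
  expect_identical(c2$canonical_key, a$canonical_key)
})

test_that("reagent mode keeps salts intact, substrate mode strips them", {
  salt <- mol("CC(C)(C)[O-].[Na+]", "reagent")
  expect_length(mgraph_fragments(salt$graph), 2)
  sub <- mol("CC(C)(C)[O-].[Na+]", "substrate")
  expect_length(mgraph_fragments(sub$graph), 1)
  expect_false("Na" %in% sub$graph$elem)
  # trivially ionised centre is neutralised in substrate mode
  expect_identical(sub$canonical_key, mol("CC(C)(C)O")$canonical_key)
  # the two modes give different keys for the salt
  expect_false(identical(salt$canonical_key, sub$canonical_key))
})

test_that("unparsable and empty structures raise typed errors", {
  expect_error(normalize_molecule("C1CC"), class = "bhmeta_parse_error")
  expect_error(normalize_molecule("xyz!"), class = "bhmeta_parse_error")
  expect_error(normalize_molecule(""), class = "bhmeta_missing_structure")
  expect_error(normalize_molecule(NA_character_),
               class = "bhmeta_missing_structure")
})

test_that("aromatic perception and implicit hydrogens follow the dialect", {
  g <- smiles_graph("O=c1cccc[nH]1") # aromatic 2-pyridone
  expect_true(all(g$arom[g$elem != "O"]))
  expect_equal(sum(g$hcount[g$elem == "N"]), 1)
  bip <- smiles_graph("c1ccccc1c1ccccc1") # unmarked biaryl bond is single
  expect_equal(sum(bip$bonds$order == 1), 1)
  expect_equal(sum(bip$bonds$order == 1.5), 12)
})

test_that("the SMILES writer round-trips through canonicalization", {
  for (s in c("Nc1ccccc1", "O=c1cccc[nH]1", "CC(C)(C)P(C(C)(C)C)C(C)(C)C",
              "O=S(=O)(Oc1ccccc1)C(F)(F)F", "c1ccc2c(c1)[nH]c1ccccc21",
              "[Na+].CC(C)(C)[O-]")) {
    can <- mol(s, "reagent")$canonical_smiles
    rewritten <- mgraph_smiles(smiles_graph(can))
    expect_identical(mol(rewritten, "reagent")$canonical_smiles, can)
  }
})

test_that("substructure matching is chemistry-aware monomorphism", {
  bz <- smiles_graph("c1ccccc1")
  expect_true(mol_subiso(bz, mol("Nc1ccccc1")$graph))
  expect_false(mol_subiso(bz, smiles_graph("C1CCCCC1"))) # not cyclohexane
  # monomorphism (not induced): a 3-chain matches inside a ring
  expect_true(mol_subiso(smiles_graph("CCC"), smiles_graph("C1CC1")))
  # bond orders are respected
  expect_false(mol_subiso(smiles_graph("C=C"), smiles_graph("CC")))
})

test_that("symmetry equivalence detects interchangeable atoms", {
  pip <- mol("C1CNCCN1")$graph
  ns <- which(pip$elem == "N")
  expect_true(atoms_equivalent(pip, ns[1], ns[2]))
  an <- mol("Nc1ccccc1")$graph
  expect_false(atoms_equivalent(an, which(an$elem == "N"),
                                which(an$elem == "C")[1]))
})

test_that("molecular properties are computed correctly", {
  an <- mol("Nc1ccccc1")
  expect_equal(mol_weight(an), 93.13, tolerance = 1e-3)
  expect_equal(mol_heteroatoms(an), 1)
  expect_equal(mol_rings(an), 1)
  expect_equal(mol_heteroatom_h(an), 1)
  # fused bicyclic counts 2 rings
  expect_equal(mol_rings(mol("c1ccc2ccccc2c1")), 2)
  # heteroatom-H: morpholine has N-H, not O-H
  expect_equal(mol_heteroatom_h(mol("C1COCCN1")), 1)
})

test_that("fingerprint distances separate dissimilar structures", {
  f_an <- morgan_fp(mol("Nc1ccccc1"))
  f_an2 <- morgan_fp(mol("c1ccccc1N"))
  expect_equal(tanimoto_distance(f_an, f_an2), 0)
  f_far <- morgan_fp(mol("CC(C)(C)P(C(C)(C)C)C(C)(C)C"))
  expect_gt(tanimoto_distance(f_an, f_far), 0.8)
  # near misses sit in between
  f_tol <- morgan_fp(mol("Cc1ccc(N)cc1"))
  d <- tanimoto_distance(f_an, f_tol)
  expect_gt(d, 0); expect_lt(d, 0.9)
})

test_that("tautomer enumeration finds the pyridone/hydroxypyridine pair", {
  tt <- enumerate_tautomers("O=c1cccc[nH]1")
  hydroxy <- mol("Oc1ccccn1")$canonical_smiles
  expect_true(hydroxy %in% tt)
  tt2 <- enumerate_tautomers("Oc1ccccn1")
  pyridone <- mol("O=c1cccc[nH]1")$canonical_smiles
  expect_true(pyridone %in% tt2)
  # benzene has no mobile hydrogens
  expect_length(enumerate_tautomers("c1ccccc1"), 1)
})
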