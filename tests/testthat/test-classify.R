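# Leaving groups, electrophile/nucleophile identification, reactive-site
# detection and substrate classification.

test_that("leaving-group counting respects aryl attachment and priority", {
  expect_equal(count_leaving_groups(mol("Brc1ccccc1"), "Br"), 1)
  bcb <- mol("Brc1ccc(Cl)cc1")
  expect_equal(count_leaving_groups(bcb, "Br"), 1)
  expect_equal(count_leaving_groups(bcb, "Cl"), 1)
  otf <- mol("O=S(=O)(Oc1ccccc1)C(F)(F)F")
  expect_equal(count_leaving_groups(otf, "OTf"), 1)
  # triflate fluorines are aliphatic-bound: not fluoride leaving groups
  expect_equal(count_leaving_groups(otf, "F"), 0)
  # alkyl bromide does not count (aryl attachment required)
  expect_equal(count_leaving_groups(mol("BrCCc1ccccc1"), "Br"), 0)
  ots <- mol("Cc1ccc(cc1)S(=O)(=O)Oc1ccccc1")
  expect_equal(count_leaving_groups(ots, "OTs"), 1)
})

test_that("role identification uses the leaving-group rule, then N-H fallback", {
  bb <- mol("Brc1ccccc1"); an <- mol("Nc1ccccc1")
  dpa <- mol(build_product("Brc1ccccc1", "Nc1ccccc1", "Br"))
  r <- identify_roles(bb, an, dpa)
  expect_equal(r$status, "ok"); expect_equal(r$electrophile, 1L)
  expect_equal(r$rule, "leaving_group")
  # swapping the reactants swaps the answer
  r2 <- identify_roles(an, bb, dpa)
  expect_equal(r2$electrophile, 2L)

  # both reactants brominated: the rule fails, the N-H fallback resolves
  bra <- mol("Nc1ccc(Br)cc1")
  prod <- mol(build_product("Brc1ccccc1", "Nc1ccc(Br)cc1", "Br"))
  r3 <- identify_roles(bb, bra, prod)
  expect_equal(r3$status, "ok")
  expect_equal(r3$rule, "nh_fallback")
  expect_equal(r3$electrophile, 1L)

  # two leaving-group types changing and no N-H anywhere: unresolved
  weird_prod <- mol("c1ccc(Nc2ccccc2)cc1")
  r4 <- identify_roles(mol("Brc1ccc(Cl)cc1"), mol("Cc1ccccc1"), weird_prod)
  expect_equal(r4$status, "unresolved")
})

test_that("reactive carbon: severing discriminates among leaving groups", {
  # Br/Cl electrophile, product keeps Cl: Br carbon is the reactive one
  e <- mol("Brc1ccc(Cl)cc1")
  prod <- mol(build_product("Brc1ccc(Cl)cc1", "Nc1ccccc1", "Br"))
  rc <- find_reactive_carbon(e, prod, codes = c("Br", "Cl"))
  expect_equal(rc$status, "ok")
  expect_equal(rc$lg_code, "Br")
  expect_equal(e$graph$elem[rc$c_atom], "C")
  # bromobenzene: single candidate
  rc2 <- find_reactive_carbon(mol("Brc1ccccc1"),
                              mol(build_product("Brc1ccccc1", "Nc1ccccc1", "Br")))
  expect_equal(rc2$status, "ok")
  # 1,4-dibromobenzene mono-coupled: two severings, symmetry-equivalent
  e3 <- mol("Brc1ccc(Br)cc1")
  prod3 <- mol(build_product("Brc1ccc(Br)cc1", "Nc1ccccc1", "Br"))
  rc3 <- find_reactive_carbon(e3, prod3, codes = "Br")
  expect_equal(rc3$status, "ok")
})

test_that("reactive nitrogen: direct probe, symmetric collapse, tautomers", {
  an <- mol("Nc1ccccc1")
  prod <- mol(build_product("Brc1ccccc1", "Nc1ccccc1", "Br"))
  rn <- find_reactive_nitrogen(an, prod)
  expect_equal(rn$status, "ok")
  expect_equal(an$graph$elem[rn$n_atom], "N")
  expect_false(rn$tautomer_used)

  # piperazine: two equivalent N-H sites collapse to one
  pip <- mol("C1CNCCN1")
  prod2 <- mol(build_product("Brc1ccccc1", "C1CNCCN1", "Br"))
  rn2 <- find_reactive_nitrogen(pip, prod2)
  expect_equal(rn2$status, "ok")

  # remote hydroxypyridine/pyridone drawing mismatch needs the tautomer branch
  nuc <- mol("Nc1ccc(-c2ccc(O)nc2)cc1")
  prod3 <- mol(build_product("Brc1ccccc1", "Nc1ccc(-c2ccc(=O)[nH]c2)cc1", "Br"))
  rn3 <- find_reactive_nitrogen(nuc, prod3)
  expect_equal(rn3$status, "ok")
  expect_true(rn3$tautomer_used)

  # a wrong product fails rather than guessing
  rn4 <- find_reactive_nitrogen(an, mol("Cc1ccccc1"))
  expect_equal(rn4$status, "fail")
})

test_that("electrophile classes: ARY vs HAR on the fused ring system", {
  bb <- mol("Brc1ccccc1")
  rc <- find_reactive_carbon(bb, mol(build_product("Brc1ccccc1", "Nc1ccccc1", "Br")))
  expect_equal(classify_electrophile(bb, rc$c_atom, rc$lg_code), "Br_ARY")

  cp <- mol("Clc1ccccn1")
  rcc <- find_reactive_carbon(cp, mol(build_product("Clc1ccccn1", "Nc1ccccc1", "Cl")))
  expect_equal(classify_electrophile(cp, rcc$c_atom, rcc$lg_code), "Cl_HAR")

  # bromide on the carbocyclic ring of quinoline: HAR at system level,
  # ARY when restricted to the smallest ring
  bq <- mol("Brc1cccc2ncccc12")
  rcq <- find_reactive_carbon(bq, mol(build_product("Brc1cccc2ncccc12",
                                                    "Nc1ccccc1", "Br")))
  expect_equal(classify_electrophile(bq, rcq$c_atom, rcq$lg_code), "Br_HAR")
  expect_equal(classify_electrophile(bq, rcq$c_atom, rcq$lg_code,
                                     system_level = FALSE), "Br_ARY")
})

test_that("nucleophile classes follow the documented precedence", {
  cls <- function(s) {
    m <- mol(s)
    n_at <- which(m$graph$elem == "N" & m$graph$hcount >= 1)[1]
    classify_nucleophile(m, n_at)
  }
  expect_equal(cls("Nc1ccccc1"), "Aryl")
  expect_equal(cls("c1ccc(Nc2ccccc2)cc1"), "DiAryl")
  expect_equal(cls("NCc1ccccc1"), "Alkyl")
  expect_equal(cls("C1COCCN1"), "DiAlkyl")
  expect_equal(cls("CNc1ccccc1"), "AlkylAryl")
  expect_equal(cls("N=C(c1ccccc1)c1ccccc1"), "Ketimine")
  expect_equal(cls("NC(=O)c1ccccc1"), "Amide")
  # amide precedence beats the AlkylAryl neighbour count
  expect_equal(cls("CC(=O)Nc1ccccc1"), "Amide")
  expect_equal(cls("N"), "Other")
  expect_equal(cls("NN"), "Other")
  # aromatic ring nitrogen
  cz <- mol("c1ccc2c(c1)[nH]c1ccccc21")
  nh <- which(cz$graph$elem == "N")
  expect_equal(classify_nucleophile(cz, nh), "aromN")
})

test_that("classification agrees with every label in the curated library", {
  lib <- substrate_library()
  for (i in seq_len(nrow(lib))) {
    row <- lib[i, ]
    if (row$role == "electrophile") {
      e_s <- row$smiles; n_s <- "Nc1ccccc1"
      lg <- sub("_.*$", "", row$class)
    } else {
      e_s <- "Brc1ccccc1"; n_s <- row$smiles; lg <- "Br"
    }
    n_build <- if (row$tautomer_case) "Nc1ccc(-c2ccc(=O)[nH]c2)cc1" else n_s
    prod <- build_product(e_s, n_build, lg)
    cl <- bhmeta:::classify_triple(normalize_molecule(e_s)$canonical_smiles,
                                   normalize_molecule(n_s)$canonical_smiles,
                                   prod)
    expect_equal(cl$status, "ok", info = row$name)
    got <- if (row$role == "electrophile") cl$ephile_class else cl$nphile_class
    expect_equal(got, row$class, info = row$name)
    if (row$tautomer_case) expect_true(cl$tautomer_used, info = row$name)
  }
})
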