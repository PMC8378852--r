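# Reagent role assignment, the ligand rules and complex extraction.

test_that("role assignment matches the curated 40-reagent fixture", {
  tb <- role_tables()
  fx <- readr::read_csv(system.file("extdata", "reagent_fixture.csv",
                                    package = "bhmeta"),
                        show_col_types = FALSE)
  expect_equal(nrow(fx), 40)
  got_role <- character(nrow(fx)); got_kind <- rep(NA_character_, nrow(fx))
  for (i in seq_len(nrow(fx))) {
    m <- resolve_reagent_species(fx$species[i], tb)
    expect_false(is.null(m), info = fx$name[i])
    ra <- assign_role(m, tb)
    got_role[i] <- ra$role; got_kind[i] <- ra$ligand_kind
  }
  expect_identical(got_role, fx$expected_role)
  lig <- !is.na(fx$expected_kind)
  expect_identical(got_kind[lig], fx$expected_kind[lig])
  # ligand_kind present iff role is ligand
  expect_identical(!is.na(got_kind), got_role == "ligand")
})

test_that("the phosphine rule needs P, forbids P-halogen, allows P-N and P-O", {
  expect_true(is_phosphine_ligand(mol("CC(C)(C)P(C(C)(C)C)C(C)(C)C", "reagent")))
  expect_false(is_phosphine_ligand(mol("ClP(Cl)Cl", "reagent")))
  expect_true(is_phosphine_ligand(
    mol("P12N(CC(C)C)CCN(CCN1CC(C)C)CCN2CC(C)C", "reagent"))) # phosphatrane
  expect_true(is_phosphine_ligand(mol("CCOP(OCC)OCC", "reagent")))
  expect_false(is_phosphine_ligand(mol("CCN(CC)CC", "reagent"))) # no P at all
})

test_that("a P-containing superbase is a base, not a ligand", {
  tb <- role_tables()
  m <- mol("CC(C)(C)N=P(N(C)C)(N(C)C)N(C)C", "reagent")
  expect_true(is_phosphine_ligand(m)) # the raw rule alone would say ligand
  expect_equal(assign_role(m, tb)$role, "base") # precedence protects it
})

test_that("NHC detection hits carbenes and azolium salts but not imidazole", {
  tb <- role_tables()
  ipr_salt <- mol(paste0("CC(C)c1cccc(C(C)C)c1[n+]1ccn",
                         "(-c2c(C(C)C)cccc2C(C)C)c1.[Cl-]"), "reagent")
  expect_true(is_nhc_ligand(ipr_salt, tb))
  expect_false(is_nhc_ligand(mol("c1c[nH]cn1", "reagent"), tb))
  expect_false(is_nhc_ligand(mol("c1ccc(P(c2ccccc2)c2ccccc2)cc1", "reagent"), tb))
})

test_that("ligand extraction: unique, ambiguous and undetected complexes", {
  tb <- role_tables()
  pph3 <- "c1ccc(P(c2ccccc2)c2ccccc2)cc1"
  pd4 <- mol(paste0("[Pd](", paste(rep("[P](c1ccccc1)(c1ccccc1)c1ccccc1",
                                       3), collapse = ")("),
                    ")[P](c1ccccc1)(c1ccccc1)c1ccccc1"), "reagent")
  ex <- extract_ligands_from_complex(pd4, tb)
  expect_length(ex, 1) # four copies, one distinct ligand
  expect_identical(ex[[1]]$canonical_key, mol(pph3, "reagent")$canonical_key)
  expect_false(any(vapply(ex, function(m) "Pd" %in% m$graph$elem, logical(1))))

  mixed <- mol(paste0("[Pd]([P](c1ccccc1)(c1ccccc1)c1ccccc1)",
                      "[P](C(C)(C)C)(C(C)(C)C)C(C)(C)C"), "reagent")
  expect_length(extract_ligands_from_complex(mixed, tb), 2)

  expect_length(extract_ligands_from_complex(
    mol("CC(=O)O[Pd]OC(C)=O", "reagent"), tb), 0)
})

test_that("reagent sets resolve to one ligand/base/solvent with discards", {
  tb <- dplyr::bind_rows(
    raw_record("R1"), # Pd(OAc)2 + PPh3 + NaOtBu + toluene
    raw_record("R2", reagents = paste0("CC(=O)O[Pd]OC(C)=O|catalyst;",
                                       "[Na+].CC(C)(C)[O-]|reagent;",
                                       "Cc1ccccc1|solvent")), # no ligand
    raw_record("R3", reagents = paste0(
      "CC(=O)O[Pd]OC(C)=O|catalyst;",
      "c1ccc(P(c2ccccc2)c2ccccc2)cc1|reagent;",
      "CC(C)(C)P(C(C)(C)C)C(C)(C)C|reagent;",
      "[Cs+].[Cs+].[O-]C([O-])=O|reagent;C1COCCO1|solvent"))) # two ligands
  out <- read_reactions(tb) |> filter_template() |> resolve_roles()
  expect_equal(out$discard_reason,
               c(NA, "ligand_undetected", "ligand_ambiguous"))
  expect_equal(out$ligand_name[1], "PPh3")
  expect_equal(out$base_name[1], "NaOtBu")
  expect_equal(out$solvent_name[1], "toluene")
  expect_false(is.na(out$pd_source_key[1]))
})

test_that("a complex-declared Pd source yields the extracted ligand", {
  cplx <- paste0("[Pd]([P](c1ccccc1)(c1ccccc1)c1ccccc1)",
                 "[P](c1ccccc1)(c1ccccc1)c1ccccc1")
  tb <- raw_record("K1", reagents = paste0(
    cplx, "|catalyst;[Na+].CC(C)(C)[O-]|reagent;Cc1ccccc1|solvent"))
  out <- read_reactions(tb) |> filter_template() |> resolve_roles()
  expect_true(is.na(out$discard_reason[1]))
  expect_equal(out$ligand_name[1], "PPh3")
})

test_that("multiple distinct bases keep the first unless strict", {
  rg <- paste0("CC(=O)O[Pd]OC(C)=O|catalyst;",
               "c1ccc(P(c2ccccc2)c2ccccc2)cc1|reagent;",
               "[Na+].CC(C)(C)[O-]|reagent;",
               "[Cs+].[Cs+].[O-]C([O-])=O|reagent;Cc1ccccc1|solvent")
  tb <- raw_record("M1", reagents = rg)
  out <- read_reactions(tb) |> filter_template() |> resolve_roles()
  expect_equal(out$base_name[1], "NaOtBu")
  expect_true(out$multi_base[1])
  strict <- read_reactions(tb) |> filter_template() |>
    resolve_roles(strict_roles = TRUE)
  expect_equal(strict$discard_reason[1], "roles_unresolved")
})
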