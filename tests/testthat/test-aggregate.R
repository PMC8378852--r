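# Yield matrices, the cheatsheet rule and diversity proxies.

test_that("median-yield matrix equals a brute-force group oracle", {
  sp <- small_processed()
  kk <- kept(sp$out)
  m <- median_yield_matrix(sp$out, "ligand_name", "nphile_class")
  # independent oracle: split + sort-based median
  for (i in sample.int(nrow(m), min(25, nrow(m)))) {
    ix <- kk$ligand_name == m$row[i] & kk$nphile_class == m$col[i]
    expect_equal(m$n[i], sum(ix))
    ys <- sort(kk$yield_percent[ix])
    if (length(ys) == 0) {
      expect_true(is.na(m$median_yield[i]))
    } else {
      k <- length(ys)
      med <- if (k %% 2 == 1) ys[(k + 1) / 2] else (ys[k / 2] + ys[k / 2 + 1]) / 2
      expect_equal(m$median_yield[i], med)
    }
  }
  # partition conservation
  expect_equal(sum(m$n), nrow(kk))
  expect_true(all(is.na(m$q1) | (m$q1 <= m$median_yield &
                                 m$median_yield <= m$q3)))
})

test_that("cells without yields report counts but no median", {
  tb <- dplyr::bind_rows(
    raw_record("N1", yield_percent = NA), raw_record("N2", yield_percent = NA),
    raw_record("N3", yield_percent = NA), raw_record("N4", yield_percent = NA))
  out <- read_reactions(tb) |> filter_template() |> resolve_roles() |>
    classify_reactants()
  m <- median_yield_matrix(out, "ligand_name", "nphile_class")
  expect_equal(m$n, 4)
  expect_equal(m$n_yield, 0)
  expect_true(is.na(m$median_yield))
})

test_that("the cheatsheet enforces minimum support and ranks by median", {
  # planted combos, one cell: A 85 > B 60 > C 40, and an n=19 high-yield
  # combo that must be excluded by the support rule
  mk <- function(lig, base, n, med, id0) {
    dplyr::bind_rows(lapply(seq_len(n), function(j) {
      raw_record(sprintf("%s%03d", id0, j),
                 reagents = paste0("CC(=O)O[Pd]OC(C)=O|catalyst;", lig,
                                   "|reagent;", base, "|reagent;Cc1ccccc1|solvent"),
                 yield_percent = med + (j %% 5) - 2)
    }))
  }
  pph3 <- "c1ccc(P(c2ccccc2)c2ccccc2)cc1"
  ptbu <- "CC(C)(C)P(C(C)(C)C)C(C)(C)C"
  pcy <- "C1CCC(CC1)P(C2CCCCC2)C3CCCCC3"
  xph <- "CC(C)c1cc(C(C)C)c(-c2ccccc2P(C2CCCCC2)C2CCCCC2)c(C(C)C)c1"
  naotbu <- "[Na+].CC(C)(C)[O-]"; cs <- "[Cs+].[Cs+].[O-]C([O-])=O"
  tb <- dplyr::bind_rows(
    mk(pph3, naotbu, 22, 85, "A"),
    mk(ptbu, cs, 25, 60, "B"),
    mk(pcy, naotbu, 21, 40, "C"),
    mk(xph, cs, 19, 99, "X"))   # high yield but under-supported
  out <- read_reactions(tb) |> filter_template() |> resolve_roles() |>
    classify_reactants()
  cs_tb <- build_cheatsheet(out, min_count = 20, top_k = 3)
  expect_equal(nrow(cs_tb), 3)
  expect_equal(cs_tb$ligand, c("PPh3", "P(t-Bu)3", "PCy3"))
  expect_false("XPhos" %in% cs_tb$ligand)
  expect_true(all(cs_tb$n >= 20))
  expect_equal(cs_tb$rank, 1:3)
  expect_true(all(diff(cs_tb$median_yield) <= 0))
})

test_that("cheatsheet never emits a combo below min_count (property)", {
  sp <- small_processed()
  for (mc in c(3, 10, 20)) {
    cs_tb <- build_cheatsheet(sp$out, min_count = mc)
    if (nrow(cs_tb) > 0) expect_true(all(cs_tb$n >= mc))
  }
})

test_that("median ties rank the better-supported combo first", {
  combos <- tibble::tibble(
    discard_reason = NA_character_,
    ephile_class = "Br_ARY", nphile_class = "Aryl",
    ligand_key = "L", base_key = "B",
    ligand_name = rep(c("Lig1", "Lig2"), times = c(4, 8)),
    base_name = "NaOtBu",
    yield_percent = rep(70, 12))
  cs_tb <- build_cheatsheet(combos, min_count = 2, top_k = 2)
  expect_equal(cs_tb$ligand[1], "Lig2") # same median, larger n first
})

test_that("diversity proxies behave on constructed groups", {
  tb <- dplyr::bind_rows(raw_record("D1"), raw_record("D2"))
  out <- read_reactions(tb) |> filter_template() |> resolve_roles() |>
    classify_reactants()
  dv <- diversity_table(out, "nphile_class")
  expect_equal(dv$n, 2)
  expect_equal(dv$mean_tanimoto_distance, 0) # identical products
  expect_gt(dv$mean_product_mw, 160) # diphenylamine ~169 g/mol
  expect_equal(dv$mean_product_heteroatoms, 1)
  # dissimilar products give distance near 1 (direct pairwise oracle)
  f1 <- morgan_fp(mol("c1ccc(Nc2ccccc2)cc1"))
  f2 <- morgan_fp(mol("CCCCCCCCCCCCCCCC(=O)NCCCC(=O)O"))
  expect_gt(tanimoto_distance(f1, f2), 0.9)
})
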