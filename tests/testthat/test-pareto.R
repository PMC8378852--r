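# Ligand profiles, ortho-substituent counting and Pareto-front ranking.

fake_profiles <- function(vals) {
  tibble::tibble(ligand = paste0("L", seq_len(nrow(vals))),
                 n_reactions = 5L, median_yield = 50,
                 p1 = vals[, 1],
                 p2 = if (ncol(vals) > 1) vals[, 2] else vals[, 1],
                 p3 = if (ncol(vals) > 2) vals[, 3] else vals[, 1])
}

# independent O(n^2) double-loop oracle for iterated non-dominated sorting
pareto_oracle <- function(vals) {
  n <- nrow(vals)
  front <- rep(NA_integer_, n)
  left <- seq_len(n)
  f <- 0L
  while (length(left) > 0) {
    f <- f + 1L
    nd <- c()
    for (i in left) {
      dominated <- FALSE
      for (j in left) {
        if (i == j) next
        if (all(vals[j, ] >= vals[i, ]) && any(vals[j, ] > vals[i, ])) {
          dominated <- TRUE; break
        }
      }
      if (!dominated) nd <- c(nd, i)
    }
    front[nd] <- f
    left <- setdiff(left, nd)
  }
  front
}

test_that("a single property reduces to sorting with ties sharing fronts", {
  vals <- cbind(c(3, 1, 2, 3, 0))
  pr <- pareto_rank(fake_profiles(vals), "p1")
  got <- pr$front[match(paste0("L", 1:5), pr$ligand)]
  expect_equal(got, c(1L, 3L, 2L, 1L, 4L))
})

test_that("the textbook example ranks as expected", {
  vals <- cbind(c(3, 1, 2), c(1, 3, 2))
  pr <- pareto_rank(fake_profiles(vals), c("p1", "p2"))
  expect_true(all(pr$front == 1))
  vals2 <- rbind(vals, c(1, 1))
  pr2 <- pareto_rank(fake_profiles(vals2), c("p1", "p2"))
  expect_equal(pr2$front[pr2$ligand == "L4"], 2L)
  expect_true(all(pr2$front[pr2$ligand != "L4"] == 1L))
})

test_that("fronts equal the brute-force oracle on random tables", {
  withr::with_seed(11, {
    for (rep in 1:30) {
      n <- sample(5:60, 1)
      p <- sample(1:3, 1)
      vals <- matrix(sample(0:6, n * p, replace = TRUE), n, p)
      pr <- pareto_rank(fake_profiles(vals), c("p1", "p2", "p3")[seq_len(p)])
      want <- pareto_oracle(vals[, seq_len(p), drop = FALSE])
      got <- pr$front[match(paste0("L", seq_len(n)), pr$ligand)]
      expect_identical(got, want)
    }
  })
})

test_that("ranking is invariant to input order and monotone transforms", {
  withr::with_seed(5, {
    vals <- matrix(runif(40), 20, 2)
    pf <- fake_profiles(vals)
    pr <- pareto_rank(pf, c("p1", "p2"))
    perm <- sample.int(20)
    pr2 <- pareto_rank(pf[perm, ], c("p1", "p2"))
    expect_equal(pr2$front[match(pf$ligand, pr2$ligand)],
                 pr$front[match(pf$ligand, pr$ligand)])
    pf3 <- pf; pf3$p1 <- exp(3 * pf3$p1); pf3$p2 <- pf3$p2^3
    pr3 <- pareto_rank(pf3, c("p1", "p2"))
    expect_equal(pr3$front[match(pf$ligand, pr3$ligand)],
                 pr$front[match(pf$ligand, pr$ligand)])
  })
})

test_that("removing front 1 shifts the remaining fronts by one", {
  withr::with_seed(9, {
    vals <- matrix(sample(0:9, 60, replace = TRUE), 30, 2)
    pf <- fake_profiles(vals)
    pr <- pareto_rank(pf, c("p1", "p2"))
    keep <- pr$ligand[pr$front > 1]
    pr2 <- pareto_rank(pf[pf$ligand %in% keep, ], c("p1", "p2"))
    m <- match(pr2$ligand, pr$ligand)
    expect_equal(pr2$front, pr$front[m] - 1L)
  })
})

test_that("the yield filter removes after ranking without recomputing", {
  pf <- fake_profiles(cbind(c(3, 2, 1)))
  pf$median_yield <- c(84, 90, 95)
  pr <- pareto_rank(pf, "p1")
  out <- filter_by_yield(pr, 85)
  expect_false("L1" %in% out$ligand) # front 1 but below the slider
  expect_equal(out$front[out$ligand == "L2"], 2L) # rank kept, not recomputed
  expect_equal(nrow(filter_by_yield(pr, 0)), 3)
  expect_equal(nrow(filter_by_yield(pr, 101)), 0)
})

test_that("ortho-substituent counting enumerates flanking groups", {
  rc <- function(s, lg = "Br") {
    m <- mol(s)
    leaving_group_instances(m, lg)[[1]]$c_atom
  }
  m1 <- mol("Brc1ccccc1")
  expect_equal(count_ortho_substituents(m1, rc("Brc1ccccc1")), 0)
  m2 <- mol("Cc1ccccc1Br")
  expect_equal(count_ortho_substituents(m2, leaving_group_instances(m2, "Br")[[1]]$c_atom), 1)
  m3 <- mol("Cc1cccc(C)c1Br")
  expect_equal(count_ortho_substituents(m3, leaving_group_instances(m3, "Br")[[1]]$c_atom), 2)
  # amine nucleophile: ortho positions of the aromatic neighbour
  m4 <- mol("Cc1cccc(C)c1N")
  expect_equal(count_ortho_substituents(m4, which(m4$graph$elem == "N")), 2)
  # non-ring atom with no aromatic neighbour counts zero
  m5 <- mol("CCCCN")
  expect_equal(count_ortho_substituents(m5, which(m5$graph$elem == "N")), 0)
})

test_that("profiles compute medians and population sd per ligand", {
  tb <- dplyr::bind_rows(
    raw_record("F1", yield_percent = 60),
    raw_record("F2", yield_percent = 80, pub_year = 2016L))
  out <- read_reactions(tb) |> filter_template() |> resolve_roles() |>
    classify_reactants()
  pf <- build_profiles(out)
  expect_equal(nrow(pf), 1)
  expect_equal(pf$n_reactions, 2)
  expect_equal(pf$median_yield, 70)
  expect_equal(pf$sd_yield, 10) # population sd of {60, 80}
  expect_false(pf$low_support)
  expect_equal(pf$median_tanimoto_ephile, 0) # identical electrophiles
  # single-use ligand: sd 0 and low-support flag
  one <- build_profiles(read_reactions(raw_record("G1")) |>
                          filter_template() |> resolve_roles() |>
                          classify_reactants())
  expect_true(one$low_support)
  expect_equal(one$sd_yield, 0)
  expect_equal(one$median_tanimoto_product, 0)
})

test_that("profile medians match a per-ligand brute-force recomputation", {
  sp <- small_processed()
  pf <- build_profiles(sp$out)
  kk <- kept(sp$out)
  for (lig in pf$ligand[seq_len(min(4, nrow(pf)))]) {
    ix <- kk$ligand_name == lig
    mws <- vapply(kk$ephile_smiles[ix],
                  function(s) mol_weight(normalize_molecule(s)), numeric(1))
    expect_equal(pf$median_mw_ephile[pf$ligand == lig],
                 stats::median(mws))
    expect_equal(pf$n_reactions[pf$ligand == lig], sum(ix))
  }
})

test_that("tidy and glance summarise a ranking", {
  pr <- pareto_rank(fake_profiles(cbind(1:4)), "p1")
  expect_s3_class(tidy(pr), "tbl_df")
  g <- glance(pr)
  expect_equal(g$n_ligands, 4L)
  expect_equal(g$n_fronts, 4L)
})
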