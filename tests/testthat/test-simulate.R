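# The synthetic corpus generator and its ground truth.

test_that("generation is a deterministic function of config and seed", {
  cfg <- bh_config(n_reactions = 40, seed = 123)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$per_record, b$truth$per_record)
  c2 <- generate_corpus(bh_config(n_reactions = 40, seed = 124))
  expect_false(identical(a$records, c2$records))
})

test_that("every generated record passes the template filter", {
  sim <- generate_corpus(bh_config(n_reactions = 60, seed = 3,
                                   duplicate_rate = 0))
  out <- filter_template(read_reactions(sim$records))
  expect_true(all(is.na(out$discard_reason)))
})

test_that("zero duplicate rate leaves final dedup with planted groups only", {
  sim <- generate_corpus(bh_config(n_reactions = 80, seed = 5,
                                   duplicate_rate = 0, n_tautomer_cases = 0))
  out <- run_pipeline(read_reactions(sim$records))
  tr <- sim$truth$per_record[match(out$record_id,
                                   sim$truth$per_record$record_id), ]
  # the only permissible collapses are records identical in planted identity
  flagged <- out$discard_reason %in% "duplicate"
  tg <- truth_group_key(tr)
  for (i in which(flagged)) {
    expect_gt(sum(tg == tg[i]), 1)
  }
})

test_that("pipeline recovers planted roles, classes and conditions exactly", {
  sp <- small_processed()
  out <- sp$out; tr <- sp$sim$truth$per_record
  m <- dplyr::inner_join(kept(out), tr, by = "record_id",
                         suffix = c("", ".truth"))
  expect_gt(nrow(m), 0)
  expect_true(all(m$ephile_class == m$ephile_class.truth))
  expect_true(all(m$nphile_class == m$nphile_class.truth))
  expect_true(all(m$ligand_name == m$ligand))
  expect_true(all(m$base_name == m$base))
  expect_true(all(m$solvent_name == m$solvent))
  expect_true(all(m$electrophile_idx == m$electrophile_slot))
  # the planted tautomer case exercises the tautomer branch
  expect_true(any(m$tautomer_used[m$tautomer_case]))
})

test_that("planted yield skew and trend shifts are visible in the corpus", {
  sim <- memo("trend_corpus", generate_corpus(
    bh_config(n_reactions = 1200, seed = 31, duplicate_rate = 0,
              yield_missing_rate = 0.1)))
  rec <- sim$records
  y <- rec$yield_percent[!is.na(rec$yield_percent)]
  expect_gt(stats::median(y), 50) # right-skewed towards higher yields
  # patent yields lower before 2014, gap mostly gone after
  pre <- rec$pub_year < 2014
  gap_pre <- stats::median(rec$yield_percent[pre & rec$doc_type == "nonpatent"], na.rm = TRUE) -
    stats::median(rec$yield_percent[pre & rec$doc_type == "patent"], na.rm = TRUE)
  gap_post <- stats::median(rec$yield_percent[!pre & rec$doc_type == "nonpatent"], na.rm = TRUE) -
    stats::median(rec$yield_percent[!pre & rec$doc_type == "patent"], na.rm = TRUE)
  expect_gt(gap_pre, 10)
  expect_lt(abs(gap_post), 10)
  # patent literature outpaces nonpatent after 2014
  post_counts <- table(rec$doc_type[rec$pub_year >= 2014])
  expect_gt(post_counts[["patent"]], post_counts[["nonpatent"]])
  # aromatic-N nucleophiles surge after 2014 (planted mixture shift)
  tr <- sim$truth$per_record
  sh_pre <- mean(tr$nphile_class[rec$pub_year < 2014] == "aromN")
  sh_post <- mean(tr$nphile_class[rec$pub_year >= 2014] == "aromN")
  expect_gt(sh_post, sh_pre)
})

test_that("empirical ligand usage follows the planted Zipf law", {
  sim <- memo("trend_corpus", generate_corpus(
    bh_config(n_reactions = 1200, seed = 31, duplicate_rate = 0,
              yield_missing_rate = 0.1)))
  counts <- table(sim$truth$per_record$ligand)
  fit <- zipf_fit(as.integer(counts), min_count = 5)
  expect_equal(fit$exponent, sim$truth$zipf_s, tolerance = 0.15)
})

test_that("spike index increases with the round-to-ten probability", {
  spikes <- vapply(c(0, 0.1, 0.3), function(p) {
    sim <- generate_corpus(bh_config(n_reactions = 700, seed = 41,
                                     duplicate_rate = 0,
                                     yield_missing_rate = 0,
                                     round_to_ten_prob = p))
    recs <- read_reactions(sim$records)
    yield_histogram(recs)$spike_index
  }, numeric(1))
  expect_equal(spikes[1], 1, tolerance = 0.35)
  expect_true(all(diff(spikes) > 0))
  expect_gt(spikes[3], 2)
})

test_that("the substrate library covers every class with valid labels", {
  lib <- substrate_library()
  expect_true(all(table(lib$class[lib$role == "electrophile"]) >= 3))
  n_classes <- c("Aryl", "DiAryl", "Alkyl", "DiAlkyl", "AlkylAryl", "aromN",
                 "Ketimine", "Amide", "Other")
  expect_true(all(n_classes %in% lib$class[lib$role == "nucleophile"]))
  expect_true(all(table(lib$class[lib$role == "nucleophile"]) >= 3))
  expect_equal(sum(lib$tautomer_case), 1)
  # every SMILES parses
  for (s in lib$smiles) expect_s3_class(normalize_molecule(s), "bhmol")
})

test_that("the specialist ligand surfaces on front 1 for its niche", {
  sim <- memo("trend_corpus", generate_corpus(
    bh_config(n_reactions = 1200, seed = 31, duplicate_rate = 0,
              yield_missing_rate = 0.1)))
  out <- memo("trend_processed", run_pipeline(read_reactions(sim$records)))
  pf <- build_profiles(out)
  pr <- pareto_rank(pf, c("median_heteroatoms_nphile", "median_yield"))
  spec <- pr[pr$ligand == "Triisobutylphosphatrane", ]
  expect_equal(nrow(spec), 1)
  expect_equal(spec$front, 1L)
  # and it is a rare ligand: used less than the top ligand
  expect_lt(spec$n_reactions, max(pr$n_reactions) / 2)
})
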