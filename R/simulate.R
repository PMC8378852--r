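# Synthetic reaction-corpus generator with ground truth.
#
# Emulates the statistical structure of literature C-N coupling corpora:
# substrate classes drawn from a configurable mixture (with a post-2014
# shift towards aromatic-nitrogen nucleophiles), Zipf-distributed ligand
# usage, two dominant bases and solvents, planted condition effects on the
# median yield, right-skewed yields with spikes at multiples of ten,
# cross-source duplicates that preserve the six key fields, and messy
# reagent declarations (solvents in the generic reagent field, Pd declared
# as a defined complex). Chemistry is deliberately simple: the product is
# a direct C-N coupling of the labelled reactive sites.

#' Generator configuration
#'
#' Defaults define the reference synthetic study conditions; every rate is
#' a fraction in [0, 1]. `ligand_zipf_s` is the exponent of the Zipf usage
#' distribution over the ligand vocabulary (rank order as listed).
#'
#' @param n_reactions corpus size before duplication.
#' @param seed integer seed; the corpus is a deterministic function of the
#'   config including the seed.
#' @param year_range inclusive publication-year span.
#' @param ligand_zipf_s Zipf exponent for ligand usage.
#' @param duplicate_rate fraction of records re-emitted under another
#'   source with identical key fields.
#' @param near_duplicate_rate fraction of records re-emitted with the base
#'   swapped for a different salt form of the same anion (NaOtBu/KOtBu,
#'   Cs2CO3/K2CO3). Canonical-key deduplication deliberately does NOT
#'   collapse these; the mode exists to document that limitation.
#' @param field_mess_rate fraction of solvents declared in the generic
#'   reagent field.
#' @param complex_rate fraction of records declaring Pd as a defined
#'   complex of the chosen ligand (monodentate ligands only).
#' @param round_to_ten_prob probability that a reported yield is rounded
#'   to the nearest multiple of ten.
#' @param yield_sd standard deviation of the additive yield noise (percent
#'   points).
#' @param yield_missing_rate fraction of records without a reported yield.
#' @param base_yield intercept of the planted yield model (percent).
#' @param patent_pre2014_shift additive shift (percent points) applied to
#'   patent yields before 2014 (negative: the historical patent yield gap).
#' @param specialist_boost usage multiplier for the specialist ligand
#'   (triisobutylphosphatrane) inside its niche cells (heteroaryl
#'   electrophile x dialkylamine nucleophile).
#' @param n_tautomer_cases number of planted records exercising the
#'   tautomer fallback.
#' @param effect_table optional tibble (`ligand`, `base`, `ephile_class`,
#'   `nphile_class`, `median`) overriding the planted yield model for the
#'   listed combinations.
#' @param ligands,bases,solvents optional named weight vectors restricting
#'   the condition vocabularies (names must exist in the shipped tables;
#'   defaults: Zipf weights over the full ligand vocabulary, the planted
#'   base/solvent shares).
#' @param ephile_mix,nphile_mix,nphile_mix_post2014 named weight vectors
#'   over classes.
#' @return a `bh_config` list.
#' @export
bh_config <- function(n_reactions = 2000,
                      seed = 1L,
                      year_range = c(2000L, 2020L),
                      ligand_zipf_s = 1,
                      duplicate_rate = 0.1,
                      near_duplicate_rate = 0,
                      field_mess_rate = 0.3,
                      complex_rate = 0.1,
                      round_to_ten_prob = 0.15,
                      yield_sd = 12,
                      yield_missing_rate = 0.25,
                      base_yield = 55,
                      patent_pre2014_shift = -25,
                      specialist_boost = 8,
                      n_tautomer_cases = max(1L, round(0.002 * n_reactions)),
                      effect_table = NULL,
                      ligands = NULL, bases = NULL, solvents = NULL,
                      ephile_mix = c(Br_ARY = 0.30, Cl_HAR = 0.20,
                                     Br_HAR = 0.16, Cl_ARY = 0.14,
                                     I_ARY = 0.08, OTf_ARY = 0.06,
                                     OTs_ARY = 0.03, F_HAR = 0.03),
                      nphile_mix = c(Aryl = 0.26, Alkyl = 0.22,
                                     DiAlkyl = 0.18, AlkylAryl = 0.10,
                                     aromN = 0.08, DiAryl = 0.08,
                                     Amide = 0.06, Ketimine = 0.02),
                      nphile_mix_post2014 = c(Aryl = 0.24, Alkyl = 0.12,
                                              DiAlkyl = 0.12,
                                              AlkylAryl = 0.06, aromN = 0.20,
                                              DiAryl = 0.18, Amide = 0.06,
                                              Ketimine = 0.02)) {
  rates <- c(duplicate_rate, near_duplicate_rate, field_mess_rate,
             complex_rate, round_to_ten_prob, yield_missing_rate)
  stopifnot(n_reactions >= 1, all(rates >= 0), all(rates <= 1),
            abs(sum(ephile_mix) - 1) < 1e-6,
            abs(sum(nphile_mix) - 1) < 1e-6,
            abs(sum(nphile_mix_post2014) - 1) < 1e-6)
  cfg <- list(
    n_reactions = as.integer(n_reactions), seed = as.integer(seed),
    year_range = as.integer(year_range), ligand_zipf_s = ligand_zipf_s,
    duplicate_rate = duplicate_rate,
    near_duplicate_rate = near_duplicate_rate,
    field_mess_rate = field_mess_rate,
    complex_rate = complex_rate, round_to_ten_prob = round_to_ten_prob,
    yield_sd = yield_sd, yield_missing_rate = yield_missing_rate,
    base_yield = base_yield, patent_pre2014_shift = patent_pre2014_shift,
    specialist_boost = specialist_boost,
    n_tautomer_cases = as.integer(n_tautomer_cases),
    effect_table = effect_table,
    ligands = ligands, bases = bases, solvents = solvents,
    ephile_mix = ephile_mix, nphile_mix = nphile_mix,
    nphile_mix_post2014 = nphile_mix_post2014)
  class(cfg) <- "bh_config"
  cfg
}

# vocabulary of conditions: names refer to inst/extdata tables
.bh_ligand_vocab <- function() {
  c("Xantphos", "BINAP", "P(t-Bu)3", "XPhos", "SPhos", "PPh3", "PCy3",
    "DavePhos", "P(o-tol)3", "Triisobutylphosphatrane", "dppp", "IPr-HCl")
}
.bh_base_vocab <- function() {
  c(NaOtBu = 0.50, Cs2CO3 = 0.29, K2CO3 = 0.08, K3PO4 = 0.06,
    KOtBu = 0.04, KOH = 0.02, `P1-tBu phosphazene` = 0.01)
}
.bh_solvent_vocab <- function() {
  c(toluene = 0.48, `1.4-dioxane` = 0.30, THF = 0.08, DMF = 0.06,
    `tert-butanol` = 0.04, DME = 0.04)
}
.bh_pd_sources <- function() {
  c("Pd(OAc)2" = 0.5, "PdCl2" = 0.3, "Pd2(dba)3" = 0.2)
}
.bh_pd_source_smiles <- function() {
  c("Pd(OAc)2" = "CC(=O)O[Pd]OC(C)=O",
    "PdCl2" = "Cl[Pd]Cl",
    "Pd2(dba)3" = "[Pd].[Pd].O=C(C=Cc1ccccc1)C=Cc1ccccc1")
}

# planted condition-affinity model: median(cell, ligand, base) =
# base_yield + lig_aff[ligand, nclass] + base_aff[base, eclass]
.bh_lig_aff <- function() {
  list(
    "Xantphos" = c(Amide = 14, Aryl = 2),
    "BINAP" = c(Aryl = 10, AlkylAryl = 6),
    "P(t-Bu)3" = c(aromN = 14, DiAryl = 10),
    "XPhos" = c(Aryl = 12, Alkyl = 8),
    "SPhos" = c(Aryl = 8, DiAlkyl = 4),
    "PPh3" = c(),
    "PCy3" = c(Alkyl = 6),
    "DavePhos" = c(AlkylAryl = 10),
    "P(o-tol)3" = c(DiAryl = 4),
    "Triisobutylphosphatrane" = c(DiAlkyl = 16),
    "dppp" = c(),
    "IPr-HCl" = c(DiAlkyl = 8, aromN = 6))
}
.bh_base_aff <- function() {
  list(
    "NaOtBu" = c(Br_ARY = 6, Br_HAR = 2),
    "Cs2CO3" = c(Cl_HAR = 6, Cl_ARY = 4),
    "K2CO3" = c(),
    "K3PO4" = c(OTf_ARY = 4, OTs_ARY = 4),
    "KOtBu" = c(Cl_HAR = 8),
    "KOH" = c(Br_ARY = 4),
    "P1-tBu phosphazene" = c(Amide = 0))
}

.aff <- function(tbl, who, cls) {
  v <- tbl[[who]]
  if (is.null(v) || is.na(v[cls]) || !cls %in% names(v)) 0 else unname(v[cls])
}

#' Planted median yield for a condition/class combination
#' @keywords internal
planted_median <- function(cfg, ligand, base, eclass, nclass) {
  if (!is.null(cfg$effect_table)) {
    et <- cfg$effect_table
    hit <- which(et$ligand == ligand & et$base == base &
                 et$ephile_class == eclass & et$nphile_class == nclass)
    if (length(hit) > 0) return(et$median[hit[1]])
  }
  cfg$base_yield + .aff(.bh_lig_aff(), ligand, nclass) +
    .aff(.bh_base_aff(), base, eclass)
}

# expected-median table over the full vocabulary, plus the best combo per
# class cell (the generator's ground truth for cheatsheet recovery)
.bh_truth_medians <- function(cfg) {
  grid <- expand.grid(
    ligand = if (is.null(cfg$ligands)) .bh_ligand_vocab() else names(cfg$ligands),
    base = names(if (is.null(cfg$bases)) .bh_base_vocab() else cfg$bases),
    ephile_class = names(cfg$ephile_mix),
    nphile_class = names(cfg$nphile_mix),
    stringsAsFactors = FALSE)
  grid$median <- mapply(function(l, b, e, nn) planted_median(cfg, l, b, e, nn),
                        grid$ligand, grid$base, grid$ephile_class,
                        grid$nphile_class)
  grid <- tibble::as_tibble(grid)
  best <- grid |>
    dplyr::group_by(.data$ephile_class, .data$nphile_class) |>
    dplyr::arrange(dplyr::desc(.data$median), .data$ligand, .data$base,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::rename(best_ligand = "ligand", best_base = "base",
                  best_median = "median")
  list(medians = grid, best_combo = best)
}

# --- product construction ----------------------------------------------

# pick the reactive N-H nitrogen used for generation: the one with the
# most hydrogens (so a primary amine wins over e.g. a remote lactam N-H),
# ties broken by atom order
.gen_reactive_n <- function(g) {
  cand <- which(g$elem == "N" & g$hcount >= 1L)
  if (length(cand) == 0) return(NA_integer_)
  cand[which.max(g$hcount[cand])]
}

#' Construct the coupling product of two labelled substrates
#'
#' Removes the leaving group from the electrophile, one N-H hydrogen from
#' the nucleophile, and joins the reactive carbon and nitrogen with a
#' single bond.
#'
#' @param e_smiles,n_smiles substrate SMILES; `lg_code` the electrophile's
#'   leaving-group code.
#' @return canonical product SMILES.
#' @export
build_product <- function(e_smiles, n_smiles, lg_code) {
  key <- paste0("prod:", e_smiles, "|", n_smiles, "|", lg_code)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  eg <- normalize_molecule(e_smiles, "substrate")$graph
  ng <- normalize_molecule(n_smiles, "substrate")$graph
  inst <- leaving_group_instances(eg, lg_code)
  if (length(inst) == 0) {
    abort(paste0("no ", lg_code, " leaving group on ", e_smiles),
          class = "bhmeta_generate_error")
  }
  inst <- inst[[1]]
  keep <- setdiff(seq_len(n_atoms(eg)), inst$lg_atoms)
  esub <- mgraph_subset(eg, keep)
  c_new <- match(inst$c_atom, attr(esub, "orig_index"))
  n_at <- .gen_reactive_n(ng)
  if (is.na(n_at)) {
    abort(paste0("no N-H nitrogen on ", n_smiles),
          class = "bhmeta_generate_error")
  }
  off <- n_atoms(esub)
  prod <- list(
    elem = c(esub$elem, ng$elem), arom = c(esub$arom, ng$arom),
    charge = c(esub$charge, ng$charge),
    hcount = c(esub$hcount, ng$hcount),
    bonds = list(from = c(esub$bonds$from, ng$bonds$from + off, c_new),
                 to = c(esub$bonds$to, ng$bonds$to + off, n_at + off),
                 order = c(esub$bonds$order, ng$bonds$order, 1)))
  class(prod) <- "mgraph"
  prod$hcount[n_at + off] <- prod$hcount[n_at + off] - 1L
  can <- ob_canonical(mgraph_smiles(prod))
  if (!nzchar(can)) {
    abort("product construction produced an unparsable structure",
          class = "bhmeta_generate_error")
  }
  .cache_set(key, can)
}

# Pd complex of n_copies of a monodentate phosphine (bond Pd to the P atom)
make_pd_complex <- function(lig_smiles, n_copies = 2) {
  lg <- normalize_molecule(lig_smiles, "reagent")$graph
  if (sum(lg$elem == "P") != 1) return(NA_character_)
  parts <- list()
  elem <- "Pd"; arom <- FALSE; charge <- 0L; hcount <- 0L
  bf <- integer(0); bt <- integer(0); bo <- numeric(0)
  off <- 1L
  for (k in seq_len(n_copies)) {
    elem <- c(elem, lg$elem); arom <- c(arom, lg$arom)
    charge <- c(charge, lg$charge); hcount <- c(hcount, lg$hcount)
    bf <- c(bf, lg$bonds$from + off, 1L)
    bt <- c(bt, lg$bonds$to + off, which(lg$elem == "P") + off)
    bo <- c(bo, lg$bonds$order, 1)
    off <- off + n_atoms(lg)
  }
  g <- structure(list(elem = elem, arom = arom, charge = charge,
                      hcount = hcount,
                      bonds = list(from = bf, to = bt, order = bo)),
                 class = "mgraph")
  mgraph_smiles(g)
}

# an alternative but equivalent SMILES spelling (the package's own writer),
# used so cross-source duplicates are not byte-identical
.respell <- function(smiles) {
  tryCatch(mgraph_smiles(smiles_graph(ob_canonical(smiles))),
           error = function(e) smiles)
}

#' Generate a synthetic reaction corpus with ground truth
#'
#' @param config a [bh_config()].
#' @return list with `records` (raw tibble in the documented CSV schema),
#'   and `truth`: per-record tibble (`record_id`, true electrophile slot,
#'   classes, condition names, duplicate group) plus corpus-level planted
#'   parameters (`best_combo` per class cell, expected medians, Zipf
#'   exponent, duplicate rate).
#' @export
generate_corpus <- function(config = bh_config()) {
  stopifnot(inherits(config, "bh_config"))
  withr::with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(cfg) {
  n <- cfg$n_reactions
  lib <- substrate_library()
  elib <- lib[lib$role == "electrophile", ]
  nlib <- lib[lib$role == "nucleophile" & !lib$tautomer_case &
              lib$class != "Other", ]
  taut_sub <- lib[lib$tautomer_case, ][1, ]
  if (is.null(cfg$ligands)) {
    ligs <- .bh_ligand_vocab()
    lig_w0 <- (seq_along(ligs))^(-cfg$ligand_zipf_s)
  } else {
    ligs <- names(cfg$ligands)
    lig_w0 <- unname(cfg$ligands)
  }
  bases <- if (is.null(cfg$bases)) .bh_base_vocab() else cfg$bases
  solvents <- if (is.null(cfg$solvents)) .bh_solvent_vocab() else cfg$solvents
  pd_w <- .bh_pd_sources(); pd_smi <- .bh_pd_source_smiles()
  lig_tbl <- role_tables()$ligand_names
  lig_smi <- stats::setNames(lig_tbl$smiles, lig_tbl$name)

  years <- seq(cfg$year_range[1], cfg$year_range[2])
  year_w <- 1 + 0.15 * (years - years[1])
  year <- sample(years, n, replace = TRUE, prob = year_w)
  post <- year >= 2014
  doc_type <- ifelse(stats::runif(n) < ifelse(post, 0.65, 0.35),
                     "patent", "nonpatent")
  nclass <- character(n)
  nclass[!post] <- sample(names(cfg$nphile_mix), sum(!post), replace = TRUE,
                          prob = cfg$nphile_mix)
  nclass[post] <- sample(names(cfg$nphile_mix_post2014), sum(post),
                         replace = TRUE, prob = cfg$nphile_mix_post2014)
  eclass <- sample(names(cfg$ephile_mix), n, replace = TRUE,
                   prob = cfg$ephile_mix)

  pick_sub <- function(tb, cls) {
    pool <- which(tb$class == cls)
    tb[pool[sample.int(length(pool), 1)], ]
  }
  specialist <- "Triisobutylphosphatrane"
  lig_i <- integer(n)
  for (i in seq_len(n)) {
    w <- lig_w0
    if (nclass[i] == "DiAlkyl" && grepl("_HAR$", eclass[i])) {
      w[ligs == specialist] <- w[ligs == specialist] * cfg$specialist_boost
    }
    lig_i[i] <- sample.int(length(ligs), 1, prob = w)
  }
  ligand <- ligs[lig_i]
  base <- sample(names(bases), n, replace = TRUE, prob = bases)
  solvent <- sample(names(solvents), n, replace = TRUE, prob = solvents)

  # column accumulators (a per-row tibble would dominate the runtime)
  R <- list(record_id = character(n), source = character(n),
            doc_type = doc_type, pub_year = year,
            reactant_smiles = character(n), product_smiles = character(n),
            reagents = character(n), yield_percent = rep(NA_real_, n),
            temperature_C = numeric(n), time_h = numeric(n))
  TR <- list(record_id = character(n), electrophile_slot = integer(n),
             ephile_class = character(n), nphile_class = character(n),
             ephile_name = character(n), nphile_name = character(n),
             ligand = ligand, base = base, solvent = solvent,
             tautomer_case = logical(n))
  tables <- role_tables()
  solv_smi <- stats::setNames(tables$solvents$smiles, tables$solvents$name)
  base_smi <- stats::setNames(tables$bases$smiles, tables$bases$name)

  for (i in seq_len(n)) {
    is_taut <- i > n - cfg$n_tautomer_cases
    if (is_taut) {
      esub <- elib[elib$name == "bromobenzene", ]
      nsub <- taut_sub
      eclass[i] <- esub$class; nclass[i] <- nsub$class
    } else {
      esub <- pick_sub(elib, eclass[i])
      nsub <- pick_sub(nlib, nclass[i])
    }
    lg_code <- sub("_.*$", "", eclass[i])
    n_for_product <- if (is_taut) {
      # record the hydroxypyridine drawing, build the product from the
      # pyridone drawing: the reactive-site search then needs the
      # tautomer fallback
      "Nc1ccc(-c2ccc(=O)[nH]c2)cc1"
    } else nsub$smiles
    prod <- build_product(esub$smiles, n_for_product, lg_code)

    med <- planted_median(cfg, ligand[i], base[i], eclass[i], nclass[i])
    if (doc_type[i] == "patent" && year[i] < 2014) {
      med <- med + cfg$patent_pre2014_shift
    }
    y <- med + stats::rnorm(1, 0, cfg$yield_sd)
    y <- min(99, max(1, y))
    y <- if (stats::runif(1) < cfg$round_to_ten_prob) {
      min(100, max(10, round(y / 10) * 10))
    } else round(y)
    if (stats::runif(1) < cfg$yield_missing_rate) y <- NA_real_

    # reagent declaration
    rg <- character(0)
    use_complex <- stats::runif(1) < cfg$complex_rate
    cplx <- if (use_complex) make_pd_complex(lig_smi[[ligand[i]]], 2) else NA
    if (use_complex && !is.na(cplx)) {
      rg <- c(rg, paste0(cplx, "|catalyst"))
    } else {
      pd <- sample(names(pd_w), 1, prob = pd_w)
      rg <- c(rg, paste0(pd_smi[[pd]], "|catalyst"),
              paste0(lig_smi[[ligand[i]]], "|reagent"))
    }
    rg <- c(rg, paste0(base_smi[[base[i]]], "|reagent"))
    solv_field <- if (stats::runif(1) < cfg$field_mess_rate) "reagent" else "solvent"
    rg <- c(rg, paste0(solv_smi[[solvent[i]]], "|", solv_field))
    if (stats::runif(1) < 0.10) {
      rg <- c(rg, "C1COCCOCCOCCOCCOCCO1|reagent") # 18-crown-6 additive
    }
    rg <- sample(rg) # declaration order carries no information

    e_first <- stats::runif(1) < 0.5
    reactants <- if (e_first) c(esub$smiles, nsub$smiles) else
      c(nsub$smiles, esub$smiles)
    rid <- sprintf("R%06d", i)
    R$record_id[i] <- rid
    R$source[i] <- sample(c("CAS", "Reaxys", "USPTO"), 1,
                          prob = c(0.4, 0.35, 0.25))
    R$reactant_smiles[i] <- paste(reactants, collapse = ";")
    R$product_smiles[i] <- prod
    R$reagents[i] <- paste(rg, collapse = ";")
    R$yield_percent[i] <- y
    R$temperature_C[i] <- sample(seq(60, 120, 10), 1)
    R$time_h[i] <- sample(c(1, 2, 4, 8, 12, 16, 24), 1)
    TR$record_id[i] <- rid
    TR$electrophile_slot[i] <- if (e_first) 1L else 2L
    TR$ephile_class[i] <- eclass[i]; TR$nphile_class[i] <- nclass[i]
    TR$ephile_name[i] <- esub$name; TR$nphile_name[i] <- nsub$name
    TR$tautomer_case[i] <- is_taut
  }
  records <- tibble::as_tibble(R)
  truth <- tibble::as_tibble(TR)
  truth$dup_group <- truth$record_id
  truth$is_duplicate <- FALSE
  truth$is_near_duplicate <- FALSE

  # cross-source duplicates: identical six key fields, different source /
  # spelling / year / temperature
  n_dup <- round(cfg$duplicate_rate * n)
  if (n_dup > 0) {
    dup_of <- sample.int(n, n_dup, replace = FALSE)
    dtr <- truth[dup_of, ]
    dre <- records[dup_of, ]
    dre$record_id <- sprintf("D%06d", seq_len(n_dup))
    dtr$record_id <- dre$record_id
    dtr$electrophile_slot <- 3L - dtr$electrophile_slot
    dtr$is_duplicate <- TRUE
    for (k in seq_len(n_dup)) {
      orig <- records[dup_of[k], ]
      dre$source[k] <- sample(setdiff(c("CAS", "Reaxys", "USPTO"),
                                      orig$source), 1)
      dre$doc_type[k] <- sample(c("patent", "nonpatent"), 1)
      yr <- orig$pub_year + sample(c(-3:-1, 1:4), 1)
      dre$pub_year[k] <- min(max(yr, cfg$year_range[1]), cfg$year_range[2])
      reac <- strsplit(orig$reactant_smiles, ";", fixed = TRUE)[[1]]
      dre$reactant_smiles[k] <- paste(vapply(rev(reac), .respell, character(1)),
                                      collapse = ";")
      dre$product_smiles[k] <- .respell(orig$product_smiles)
      dre$reagents[k] <- paste(sample(strsplit(orig$reagents, ";",
                                               fixed = TRUE)[[1]]),
                               collapse = ";")
      dre$temperature_C[k] <- sample(seq(60, 120, 10), 1)
    }
    records <- dplyr::bind_rows(records, dre)
    truth <- dplyr::bind_rows(truth, dtr)
  }

  # near-duplicates: same reaction re-emitted with the base in a different
  # salt form; canonical-key dedup keeps these distinct by design
  n_near <- round(cfg$near_duplicate_rate * n)
  if (n_near > 0) {
    swap_pairs <- c(NaOtBu = "KOtBu", KOtBu = "NaOtBu",
                    Cs2CO3 = "K2CO3", K2CO3 = "Cs2CO3")
    cand <- which(!truth$is_duplicate & truth$base %in% names(swap_pairs))
    near_of <- cand[sample.int(length(cand), min(n_near, length(cand)))]
    if (length(near_of) > 0) {
      ntr <- truth[near_of, ]
      nre <- records[near_of, ]
      nre$record_id <- sprintf("Q%06d", seq_along(near_of))
      ntr$record_id <- nre$record_id
      ntr$is_near_duplicate <- TRUE
      for (k in seq_along(near_of)) {
        old_b <- ntr$base[k]
        new_b <- unname(swap_pairs[old_b])
        old_smi <- base_smi[[old_b]]
        new_smi <- base_smi[[new_b]]
        nre$reagents[k] <- sub(old_smi, new_smi, nre$reagents[k], fixed = TRUE)
        ntr$base[k] <- new_b
        ntr$dup_group[k] <- ntr$record_id[k]
      }
      records <- dplyr::bind_rows(records, nre)
      truth <- dplyr::bind_rows(truth, ntr)
    }
  }
  perm <- sample.int(nrow(records))
  records <- records[perm, ]
  truth <- truth[perm, ]

  tm <- .bh_truth_medians(cfg)
  list(records = records,
       truth = list(per_record = truth,
                    best_combo = tm$best_combo,
                    expected_medians = tm$medians,
                    zipf_s = cfg$ligand_zipf_s,
                    duplicate_rate = cfg$duplicate_rate,
                    config = cfg))
}
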