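# Reactant role identification (electrophile vs nucleophile), reactive-site
# detection and substrate classification.
#
# The logic mirrors the curation procedure for C-N coupling corpora:
# leaving-group bookkeeping decides which reactant is the electrophile; the
# reactive carbon is found by severing candidate C-LG bonds and testing the
# remaining skeleton as a substructure of the product; the reactive nitrogen
# by replacing one N-H hydrogen with a carbon and testing likewise, with a
# tautomer-enumeration fallback for inconsistently drawn mobile hydrogens.

.BH_LG_CODES <- c("Br", "Cl", "I", "F", "OTf", "OTs")

#' Leaving-group instances on a molecule
#'
#' Finds aryl-attached instances of one of the six leaving groups
#' Br, Cl, I, F, OTf (aryl triflate) and OTs (aryl tosylate). Halides count
#' only when bonded to an aromatic carbon, which also keeps the fluorines
#' of a triflate CF3 from counting as fluoride leaving groups. OTf/OTs are
#' matched as full ester groups anchored at the aromatic carbon.
#'
#' @param mol `bhmol` or `mgraph`.
#' @param code one of `"Br", "Cl", "I", "F", "OTf", "OTs"`.
#' @return list of instances; each has `c_atom` (the aromatic carbon),
#'   `lg_atoms` (atoms of the leaving group) and `anchor_bond` (bond index
#'   of the C-LG bond to sever).
#' @export
leaving_group_instances <- function(mol, code) {
  g <- if (inherits(mol, "bhmol")) mol$graph else mol
  code <- match.arg(code, .BH_LG_CODES)
  out <- list()
  if (code %in% c("Br", "Cl", "I", "F")) {
    for (x in which(g$elem == code & g$charge == 0L)) {
      nb <- mgraph_neighbors(g, x)
      if (length(nb) == 1 && g$elem[nb] == "C" && g$arom[nb]) {
        out[[length(out) + 1]] <- list(
          c_atom = nb, lg_atoms = x,
          anchor_bond = mgraph_bond_between(g, nb, x))
      }
    }
    return(out)
  }
  pat <- if (code == "OTf") .lg_pattern_otf() else .lg_pattern_ots()
  maps <- mol_subiso_maps(pat, g)
  seen_o <- integer(0)
  for (mp in maps) {
    o_atom <- mp[2]
    if (o_atom %in% seen_o) next
    seen_o <- c(seen_o, o_atom)
    out[[length(out) + 1]] <- list(
      c_atom = mp[1], lg_atoms = unique(mp[-1]),
      anchor_bond = mgraph_bond_between(g, mp[1], o_atom))
  }
  out
}

# patterns written in the package's SMILES-fragment dialect; atom 1 is the
# aromatic anchor carbon, atom 2 the ester oxygen
.lg_pattern_otf <- function() {
  hit <- .cache_get("pat:otf")
  if (!is.null(hit)) return(hit)
  .cache_set("pat:otf", smiles_graph("[c]([O][S](=[O])(=[O])[C]([F])([F])[F])"))
}
.lg_pattern_ots <- function() {
  hit <- .cache_get("pat:ots")
  if (!is.null(hit)) return(hit)
  .cache_set("pat:ots",
             smiles_graph("[c][O][S](=[O])(=[O])[c]1[cH][cH][c]([CH3])[cH][cH]1"))
}

#' Count aryl-attached leaving groups of one type
#' @inheritParams leaving_group_instances
#' @return non-negative integer.
#' @export
count_leaving_groups <- function(mol, code) {
  length(leaving_group_instances(mol, code))
}

.nh_count <- function(mol) {
  g <- if (inherits(mol, "bhmol")) mol$graph else mol
  sum(g$elem == "N" & g$hcount >= 1L)
}

#' Decide which reactant is the electrophile
#'
#' Primary rule: for each leaving-group type, if the reactant-side count
#' exceeds the product-side count by exactly one, only one type changes,
#' and exactly one reactant carries that group, that reactant is the
#' electrophile. The rule fails when both reactants carry the group, when
#' the count change differs from one, or when several types change; the
#' fallback then assigns the nucleophile to the single reactant carrying
#' N-H nitrogens. If both reactants carry N-H (or neither), the pair is
#' unresolved.
#'
#' @param r1,r2,product `bhmol` objects.
#' @return list with `status` (`"ok"` or `"unresolved"`), `electrophile`
#'   (1 or 2), `lg_candidates` (leaving-group codes that changed), and
#'   `rule` (`"leaving_group"` or `"nh_fallback"`).
#' @export
identify_roles <- function(r1, r2, product) {
  cnt <- vapply(.BH_LG_CODES, function(code) {
    c(count_leaving_groups(r1, code), count_leaving_groups(r2, code),
      count_leaving_groups(product, code))
  }, numeric(3))
  delta <- cnt[1, ] + cnt[2, ] - cnt[3, ]
  changing <- which(delta != 0)
  if (length(changing) == 1 && delta[changing] == 1) {
    code <- .BH_LG_CODES[changing]
    has1 <- cnt[1, changing] > 0
    has2 <- cnt[2, changing] > 0
    if (xor(has1, has2)) {
      return(list(status = "ok", electrophile = if (has1) 1L else 2L,
                  lg_candidates = code, rule = "leaving_group"))
    }
  }
  nh1 <- .nh_count(r1); nh2 <- .nh_count(r2)
  if (xor(nh1 > 0, nh2 > 0)) {
    nuc <- if (nh1 > 0) 1L else 2L
    return(list(status = "ok", electrophile = if (nuc == 1L) 2L else 1L,
                lg_candidates = .BH_LG_CODES[delta > 0],
                rule = "nh_fallback"))
  }
  list(status = "unresolved", electrophile = NA_integer_,
       lg_candidates = character(0), rule = "none")
}

# substructure probe with tautomer fallback; returns list(ok, tautomer_used)
.probe_product <- function(probe, product_mol, wildcard = integer(0),
                           taut_cap = 64) {
  if (mol_subiso(probe, product_mol$graph, wildcard = wildcard)) {
    return(list(ok = TRUE, tautomer_used = FALSE))
  }
  tauts <- tryCatch(
    enumerate_tautomers(product_mol$canonical_smiles, cap = taut_cap),
    error = function(e) character(0))
  for (tt in tauts[-1]) {
    tg <- tryCatch(smiles_graph(tt), error = function(e) NULL)
    if (is.null(tg)) next
    if (mol_subiso(probe, tg, wildcard = wildcard)) {
      return(list(ok = TRUE, tautomer_used = TRUE))
    }
  }
  list(ok = FALSE, tautomer_used = FALSE)
}

#' Locate the reactive carbon of the electrophile
#'
#' For every aryl-attached leaving-group instance, the C-LG bond is severed
#' and the skeleton fragment containing the carbon is tested as a
#' substructure of the product (and of its tautomers as a fallback).
#' Candidates that pass are collapsed under graph symmetry; a unique
#' survivor is the reactive carbon.
#'
#' @param e electrophile `bhmol`; `product` the product `bhmol`.
#' @param codes leaving-group types to try (default: the types flagged by
#'   [identify_roles()], or all six).
#' @return list with `status` (`"ok"`/`"fail"`), `c_atom`, `lg_code`,
#'   `tautomer_used`.
#' @export
find_reactive_carbon <- function(e, product, codes = .BH_LG_CODES) {
  g <- e$graph
  passing <- list()
  taut_any <- FALSE
  for (code in codes) {
    for (inst in leaving_group_instances(g, code)) {
      sk <- mgraph_drop_bonds(g, inst$anchor_bond)
      frs <- mgraph_fragments(sk)
      keep <- which(vapply(frs, function(ix) inst$c_atom %in% ix, logical(1)))
      frag <- mgraph_subset(sk, frs[[keep]])
      pr <- .probe_product(frag, product)
      if (pr$ok) {
        taut_any <- taut_any || pr$tautomer_used
        passing[[length(passing) + 1]] <- list(code = code, c_atom = inst$c_atom)
      }
    }
  }
  if (length(passing) == 0) {
    return(list(status = "fail", c_atom = NA_integer_, lg_code = NA_character_,
                tautomer_used = FALSE))
  }
  # collapse symmetry-equivalent candidates of the same leaving-group type
  uniq <- passing[1]
  for (cand in passing[-1]) {
    dup <- any(vapply(uniq, function(u) {
      u$code == cand$code && atoms_equivalent(g, u$c_atom, cand$c_atom)
    }, logical(1)))
    if (!dup) uniq[[length(uniq) + 1]] <- cand
  }
  if (length(uniq) != 1) {
    return(list(status = "fail", c_atom = NA_integer_, lg_code = NA_character_,
                tautomer_used = taut_any))
  }
  list(status = "ok", c_atom = uniq[[1]]$c_atom, lg_code = uniq[[1]]$code,
       tautomer_used = taut_any)
}

#' Locate the reactive nitrogen of the nucleophile
#'
#' For every N-H nitrogen, one hydrogen is replaced by a carbon and the
#' resulting probe tested as a substructure of the product (tautomers as
#' fallback). The added carbon matches any carbon regardless of
#' aromaticity. Symmetry-equivalent candidates are collapsed.
#'
#' @param n nucleophile `bhmol`; `product` the product `bhmol`.
#' @return list with `status`, `n_atom`, `tautomer_used`.
#' @export
find_reactive_nitrogen <- function(n, product) {
  g <- n$graph
  cands <- which(g$elem == "N" & g$hcount >= 1L)
  passing <- integer(0)
  taut_any <- FALSE
  for (a in cands) {
    probe <- g
    probe$elem <- c(probe$elem, "C")
    probe$arom <- c(probe$arom, FALSE)
    probe$charge <- c(probe$charge, 0L)
    probe$hcount <- c(probe$hcount, 0L)
    probe$hcount[a] <- probe$hcount[a] - 1L
    probe$bonds$from <- c(probe$bonds$from, a)
    probe$bonds$to <- c(probe$bonds$to, n_atoms(g) + 1L)
    probe$bonds$order <- c(probe$bonds$order, 1)
    pr <- .probe_product(probe, product, wildcard = n_atoms(g) + 1L)
    if (pr$ok) {
      taut_any <- taut_any || pr$tautomer_used
      passing <- c(passing, a)
    }
  }
  if (length(passing) == 0) {
    return(list(status = "fail", n_atom = NA_integer_, tautomer_used = FALSE))
  }
  uniq <- passing[1]
  for (a in passing[-1]) {
    if (!any(vapply(uniq, function(u) atoms_equivalent(g, u, a), logical(1)))) {
      uniq <- c(uniq, a)
    }
  }
  if (length(uniq) != 1) {
    return(list(status = "fail", n_atom = NA_integer_, tautomer_used = taut_any))
  }
  list(status = "ok", n_atom = uniq[1], tautomer_used = taut_any)
}

#' Classify the electrophile by leaving group and ring kind
#'
#' `HAR` when the fused aromatic ring system containing the reactive carbon
#' holds at least one non-carbon ring atom, `ARY` otherwise. The system-level
#' reading means e.g. a bromide on the carbocyclic ring of a quinoline is
#' still heteroaryl.
#'
#' @param e electrophile `bhmol`; `c_atom` reactive carbon index;
#'   `lg_code` leaving-group code.
#' @param system_level classify on the fused aromatic system (default) or
#'   only the smallest ring holding the carbon.
#' @return label string such as `"Br_ARY"`.
#' @export
classify_electrophile <- function(e, c_atom, lg_code, system_level = TRUE) {
  g <- if (inherits(e, "bhmol")) e$graph else e
  if (!g$arom[c_atom]) {
    abort("reactive carbon is not aromatic (vinyl/alkyl electrophiles out of scope)",
          class = "bhmeta_classify_error")
  }
  arom_atoms <- which(g$arom)
  sub <- mgraph_subset(g, arom_atoms)
  pos <- match(c_atom, attr(sub, "orig_index"))
  comp <- igraph::components(mgraph_igraph(sub))$membership
  ring_kind <- if (system_level) {
    system_atoms <- attr(sub, "orig_index")[comp == comp[pos]]
    if (any(g$elem[system_atoms] != "C")) "HAR" else "ARY"
  } else {
    nbrs <- intersect(mgraph_neighbors(g, c_atom), arom_atoms)
    if (any(g$elem[nbrs] != "C")) "HAR" else "ARY"
  }
  paste0(lg_code, "_", ring_kind)
}

#' Classify the nucleophile by the bonding environment of its nitrogen
#'
#' Precedence: amide (N bonded to a carbonyl carbon), then aromatic ring
#' nitrogen (`aromN`), then ketimine (N doubly bonded to an aliphatic
#' carbon), then neighbour-count classes over aromatic/aliphatic carbon
#' neighbours, with `Other` as the catch-all.
#'
#' @param n nucleophile `bhmol`; `n_atom` reactive nitrogen index.
#' @return one of `"Aryl", "DiAryl", "Alkyl", "DiAlkyl", "AlkylAryl",
#'   "aromN", "Ketimine", "Amide", "Other"`.
#' @export
classify_nucleophile <- function(n, n_atom) {
  g <- if (inherits(n, "bhmol")) n$graph else n
  stopifnot(g$elem[n_atom] == "N")
  nb <- mgraph_neighbors(g, n_atom)
  # amide: any neighbouring carbon carrying a C=O
  for (b in nb) {
    if (g$elem[b] != "C") next
    ks <- mgraph_bond_between(g, n_atom, b)
    for (c2 in setdiff(mgraph_neighbors(g, b), n_atom)) {
      k2 <- mgraph_bond_between(g, b, c2)
      if (g$elem[c2] == "O" && g$bonds$order[k2] == 2) return("Amide")
    }
  }
  if (g$arom[n_atom]) return("aromN")
  dbl_c <- vapply(nb, function(b) {
    g$elem[b] == "C" && g$bonds$order[mgraph_bond_between(g, n_atom, b)] == 2
  }, logical(1))
  if (any(dbl_c) && sum(g$elem[nb] == "C") == sum(dbl_c)) return("Ketimine")
  cn <- nb[g$elem[nb] == "C"]
  n_ar <- sum(g$arom[cn]); n_al <- sum(!g$arom[cn])
  if (n_ar == 2 && n_al == 0) return("DiAryl")
  if (n_ar == 0 && n_al == 2) return("DiAlkyl")
  if (n_ar == 1 && n_al == 1) return("AlkylAryl")
  if (n_ar == 1 && n_al == 0) return("Aryl")
  if (n_ar == 0 && n_al == 1) return("Alkyl")
  "Other"
}

# full structural classification of one reaction, memoised on the canonical
# SMILES triple (duplicate-heavy corpora reuse the same structures often)
classify_triple <- function(r1_can, r2_can, prod_can) {
  key <- paste0("cls:", r1_can, "|", r2_can, "|", prod_can)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  r1 <- normalize_molecule(r1_can, "substrate")
  r2 <- normalize_molecule(r2_can, "substrate")
  pp <- normalize_molecule(prod_can, "substrate")
  res <- list(status = "ok", reason = NA_character_)
  roles <- identify_roles(r1, r2, pp)
  if (roles$status != "ok") {
    res <- list(status = "fail", reason = "roles_unresolved")
    return(.cache_set(key, res))
  }
  e <- if (roles$electrophile == 1L) r1 else r2
  nuc <- if (roles$electrophile == 1L) r2 else r1
  codes <- if (length(roles$lg_candidates) > 0) roles$lg_candidates else .BH_LG_CODES
  rc <- find_reactive_carbon(e, pp, codes = codes)
  rn <- find_reactive_nitrogen(nuc, pp)
  if (rc$status != "ok" || rn$status != "ok") {
    res <- list(status = "fail", reason = "reactive_atom_fail")
    return(.cache_set(key, res))
  }
  ecls <- tryCatch(classify_electrophile(e, rc$c_atom, rc$lg_code),
                   error = function(err) NA_character_)
  if (is.na(ecls)) {
    res <- list(status = "fail", reason = "reactive_atom_fail")
    return(.cache_set(key, res))
  }
  ncls <- classify_nucleophile(nuc, rn$n_atom)
  res <- list(
    status = "ok", reason = NA_character_,
    electrophile = roles$electrophile, rule = roles$rule,
    ephile_key = e$canonical_key, nphile_key = nuc$canonical_key,
    ephile_smiles = e$canonical_smiles, nphile_smiles = nuc$canonical_smiles,
    ephile_class = ecls, nphile_class = ncls,
    reactive_c = rc$c_atom, reactive_n = rn$n_atom, lg_code = rc$lg_code,
    tautomer_used = rc$tautomer_used || rn$tautomer_used)
  .cache_set(key, res)
}

#' Classify reactants for every kept record
#'
#' Adds electrophile/nucleophile identification, reactive atom indices,
#' leaving group, substrate classes and the tautomer-branch flag to a
#' record tibble. Records whose roles cannot be resolved or whose reactive
#' atoms cannot be located uniquely are discarded with `roles_unresolved`
#' or `reactive_atom_fail`.
#'
#' @param records record tibble from [resolve_roles()] (or any stage with
#'   `r1_can`, `r2_can`, `product_can` columns).
#' @return the tibble with classification columns added.
#' @export
classify_reactants <- function(records) {
  n <- nrow(records)
  cols <- list(
    ephile_class = rep(NA_character_, n), nphile_class = rep(NA_character_, n),
    ephile_key = rep(NA_character_, n), nphile_key = rep(NA_character_, n),
    ephile_smiles = rep(NA_character_, n), nphile_smiles = rep(NA_character_, n),
    electrophile_idx = rep(NA_integer_, n),
    reactive_c = rep(NA_integer_, n), reactive_n = rep(NA_integer_, n),
    lg_code = rep(NA_character_, n), tautomer_used = rep(NA, n),
    role_rule = rep(NA_character_, n))
  for (i in seq_len(n)) {
    if (!is.na(records$discard_reason[i])) next
    cl <- classify_triple(records$r1_can[i], records$r2_can[i],
                          records$product_can[i])
    if (cl$status != "ok") {
      records$discard_reason[i] <- cl$reason
      records$discard_detail[i] <- "reactant classification"
      next
    }
    cols$ephile_class[i] <- cl$ephile_class
    cols$nphile_class[i] <- cl$nphile_class
    cols$ephile_key[i] <- cl$ephile_key
    cols$nphile_key[i] <- cl$nphile_key
    cols$ephile_smiles[i] <- cl$ephile_smiles
    cols$nphile_smiles[i] <- cl$nphile_smiles
    cols$electrophile_idx[i] <- cl$electrophile
    cols$reactive_c[i] <- cl$reactive_c
    cols$reactive_n[i] <- cl$reactive_n
    cols$lg_code[i] <- cl$lg_code
    cols$tautomer_used[i] <- cl$tautomer_used
    cols$role_rule[i] <- cl$rule
  }
  for (nm in names(cols)) records[[nm]] <- cols[[nm]]
  records
}
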