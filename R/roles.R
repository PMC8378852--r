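# Reagent role assignment: table lookup for solvents and bases, rules for
# phosphine and NHC ligands, metal sources, and ligand extraction from
# defined Pd complexes.

# metals that mark a species as a catalyst metal source; Fe is deliberately
# absent so ferrocene-backbone ligands (dppf and relatives) stay ligands
.BH_CATALYST_METALS <- c("Pd", "Ni", "Pt", "Cu", "Rh", "Ru", "Ir", "Au", "Ag")

#' Load reagent role lookup tables
#'
#' Reads `solvents.csv`, `bases.csv` (with a base strength rank used for
#' display ordering), optional `ligand_names.csv` (display names for common
#' ligands) and `nhc_patterns.csv` (substructure patterns for N-heterocyclic
#' carbenes and their azolium precursors, in the package's SMILES-fragment
#' dialect). Canonical keys are computed at load time, so the CSVs stay
#' human-editable.
#'
#' @param dir directory holding the CSVs; defaults to the tables shipped
#'   with the package.
#' @return a `bh_role_tables` list with `solvents`, `bases`,
#'   `ligand_names` tibbles, `aliases` (name -> SMILES map covering all
#'   tables) and `nhc_patterns` (list of `mgraph`).
#' @export
role_tables <- function(dir = system.file("extdata", package = "bhmeta")) {
  key <- paste0("tables:", dir)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  solvents <- rd("solvents.csv")
  bases <- rd("bases.csv")
  ligand_names <- if (file.exists(file.path(dir, "ligand_names.csv"))) {
    rd("ligand_names.csv")
  } else tibble::tibble(name = character(0), smiles = character(0))
  keyify <- function(tb) {
    tb$canonical_key <- vapply(tb$smiles, function(s) {
      normalize_molecule(s, "reagent")$canonical_key
    }, character(1), USE.NAMES = FALSE)
    tb
  }
  solvents <- keyify(solvents)
  bases <- keyify(bases)
  ligand_names <- if (nrow(ligand_names) > 0) keyify(ligand_names) else ligand_names
  overlap <- intersect(solvents$canonical_key, bases$canonical_key)
  if (length(overlap) > 0) {
    abort(paste("solvent and base tables overlap on:",
                paste(overlap, collapse = ", ")),
          class = "bhmeta_table_error")
  }
  pat_lines <- readLines(file.path(dir, "nhc_patterns.csv"))
  pat_lines <- trimws(pat_lines)
  pat_lines <- pat_lines[nzchar(pat_lines) & !startsWith(pat_lines, "#")]
  nhc_patterns <- lapply(pat_lines, smiles_graph)
  aliases <- c(
    stats::setNames(solvents$smiles, tolower(solvents$name)),
    stats::setNames(bases$smiles, tolower(bases$name)),
    if (nrow(ligand_names) > 0) {
      stats::setNames(ligand_names$smiles, tolower(ligand_names$name))
    })
  out <- structure(
    list(solvents = solvents, bases = bases, ligand_names = ligand_names,
         aliases = aliases, nhc_patterns = nhc_patterns),
    class = "bh_role_tables")
  .cache_set(key, out)
}

#' Is a species a phosphine-type ligand?
#'
#' True iff the species contains at least one phosphorus atom, no
#' phosphorus-halogen bond (reactive P-X species such as PCl3 are not
#' ligands), and no catalyst metal (a defined Pd complex is a metal source
#' whose ligand is recovered by extraction, not a ligand itself). P-O and
#' P-N bonds are allowed: phosphites and proazaphosphatranes are ligands.
#'
#' @param mol `bhmol` or `mgraph`.
#' @export
is_phosphine_ligand <- function(mol) {
  g <- if (inherits(mol, "bhmol")) mol$graph else mol
  ps <- which(g$elem == "P")
  if (length(ps) == 0) return(FALSE)
  if (any(g$elem %in% .BH_CATALYST_METALS)) return(FALSE)
  for (p in ps) {
    if (any(g$elem[mgraph_neighbors(g, p)] %in% c("F", "Cl", "Br", "I"))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Is a species an N-heterocyclic carbene ligand (or azolium precursor)?
#'
#' Substructure test against the shipped NHC pattern set
#' (imidazol-2-ylidene, imidazolin-2-ylidene and their azolium salts).
#'
#' @param mol `bhmol` or `mgraph`.
#' @param tables role tables (for the pattern list).
#' @export
is_nhc_ligand <- function(mol, tables = role_tables()) {
  g <- if (inherits(mol, "bhmol")) mol$graph else mol
  if (any(g$elem %in% .BH_CATALYST_METALS)) return(FALSE)
  for (pat in tables$nhc_patterns) {
    if (mol_subiso(pat, g)) return(TRUE)
  }
  FALSE
}

#' Assign a role to one reagent species
#'
#' Fixed precedence: solvent lookup, base lookup (so phosphorus-containing
#' superbases are bases, not ligands), phosphine rule, NHC rule, metal
#' source (contains a transition metal), generic catch-all.
#'
#' @param mol `bhmol` (normalized in reagent mode).
#' @param tables role tables from [role_tables()].
#' @return list with `role`, `ligand_kind` (`"phosphine"`/`"NHC"` or NA)
#'   and `provenance` (`"lookup"`, `"rule"`).
#' @export
assign_role <- function(mol, tables = role_tables()) {
  k <- mol$canonical_key
  if (k %in% tables$solvents$canonical_key) {
    return(list(role = "solvent", ligand_kind = NA_character_,
                provenance = "lookup"))
  }
  if (k %in% tables$bases$canonical_key) {
    return(list(role = "base", ligand_kind = NA_character_,
                provenance = "lookup"))
  }
  if (is_phosphine_ligand(mol)) {
    return(list(role = "ligand", ligand_kind = "phosphine", provenance = "rule"))
  }
  if (is_nhc_ligand(mol, tables)) {
    return(list(role = "ligand", ligand_kind = "NHC", provenance = "rule"))
  }
  if (contains_transition_metal(mol)) {
    return(list(role = "metal_source", ligand_kind = NA_character_,
                provenance = "rule"))
  }
  list(role = "generic", ligand_kind = NA_character_, provenance = "rule")
}

#' Extract ligands from a defined metal complex
#'
#' Severs all phosphorus-metal bonds, plus carbene-carbon-metal bonds for
#' NHC complexes (a carbon bonded to two nitrogens and the metal), and
#' collects the resulting metal-free fragments that qualify as phosphine or
#' NHC ligands. Distinct ligands are returned (by canonical key): an empty
#' list signals an undetected ligand, more than one a genuinely ambiguous
#' complex.
#'
#' @param mol a `bhmol` containing a transition metal.
#' @param tables role tables (for NHC patterns).
#' @return list of `bhmol`, one per distinct extracted ligand.
#' @export
extract_ligands_from_complex <- function(mol, tables = role_tables()) {
  g <- mol$graph
  metals <- which(g$elem %in% .BH_TRANSITION_METALS)
  if (length(metals) == 0) return(list())
  sever <- integer(0)
  for (m in metals) {
    for (b in mgraph_neighbors(g, m)) {
      k <- mgraph_bond_between(g, m, b)
      if (g$elem[b] == "P") {
        sever <- c(sever, k)
      } else if (g$elem[b] == "C" &&
                 sum(g$elem[mgraph_neighbors(g, b)] == "N") >= 2) {
        sever <- c(sever, k)
      }
    }
  }
  if (length(sever) == 0) return(list())
  sk <- mgraph_drop_bonds(g, unique(sever))
  out <- list()
  seen <- character(0)
  for (ix in mgraph_fragments(sk)) {
    frag <- mgraph_subset(sk, ix)
    if (any(frag$elem %in% .BH_TRANSITION_METALS)) next
    if (!is_phosphine_ligand(frag) && !is_nhc_ligand(frag, tables)) next
    lig <- tryCatch(normalize_molecule(mgraph_smiles(frag), "reagent"),
                    error = function(e) NULL)
    if (is.null(lig) || lig$canonical_key %in% seen) next
    seen <- c(seen, lig$canonical_key)
    out[[length(out) + 1]] <- lig
  }
  out
}

#' Resolve one declared reagent string to a molecule entity
#'
#' Free-text names are looked up in the alias table first (case
#' insensitive); anything else is treated as SMILES. Returns `NULL` for an
#' unknown name or unparsable structure (such species can only ever be
#' generic reagents).
#'
#' @param spec the declared species string (name or SMILES).
#' @param tables role tables from [role_tables()].
#' @return a `bhmol` or `NULL`.
#' @export
resolve_reagent_species <- function(spec, tables = role_tables()) {
  spec <- trimws(spec)
  if (!nzchar(spec)) return(NULL)
  ali <- unname(tables$aliases[tolower(spec)])
  s <- if (length(ali) == 1 && !is.na(ali)) ali else spec
  tryCatch(normalize_molecule(s, "reagent"), error = function(e) NULL)
}

.display_name <- function(key, tb, fallback) {
  i <- match(key, tb$canonical_key)
  if (!is.na(i)) tb$name[i] else fallback
}

#' Resolve ligand, base and solvent for every kept record
#'
#' Assigns a role to each declared species, pools ligands found as free
#' species with ligands extracted from metal complexes, and resolves one
#' ligand, base and solvent per reaction. Exactly one distinct ligand is
#' required: none discards the record as `ligand_undetected`, several as
#' `ligand_ambiguous`. When several distinct bases or solvents are
#' declared, the first-declared one is kept (`multi_base`/`multi_solvent`
#' flags record this) unless `strict_roles = TRUE`, which discards instead.
#' The Pd source is recorded (`pd_source_key`) but collapsed out of all
#' downstream grouping keys.
#'
#' @param records record tibble (after the upstream filters).
#' @param tables role tables from [role_tables()].
#' @param strict_roles discard records declaring several distinct bases or
#'   solvents instead of keeping the first.
#' @return the tibble with `ligand_key`, `ligand_name`, `ligand_kind`,
#'   `base_key`, `base_name`, `solvent_key`, `solvent_name`,
#'   `pd_source_key`, `multi_base`, `multi_solvent` columns added.
#' @export
resolve_roles <- function(records, tables = role_tables(),
                          strict_roles = FALSE) {
  n <- nrow(records)
  out <- list(
    ligand_key = rep(NA_character_, n), ligand_name = rep(NA_character_, n),
    ligand_kind = rep(NA_character_, n),
    base_key = rep(NA_character_, n), base_name = rep(NA_character_, n),
    solvent_key = rep(NA_character_, n), solvent_name = rep(NA_character_, n),
    pd_source_key = rep(NA_character_, n),
    multi_base = rep(FALSE, n), multi_solvent = rep(FALSE, n))
  for (i in seq_len(n)) {
    if (!is.na(records$discard_reason[i])) next
    rg <- records$reagents[[i]]
    lig_keys <- character(0); lig_mols <- list(); lig_kinds <- character(0)
    base_keys <- character(0); solv_keys <- character(0)
    pd_key <- NA_character_
    for (j in seq_len(nrow(rg))) {
      mol <- resolve_reagent_species(rg$species[j], tables)
      if (is.null(mol)) next
      ra <- assign_role(mol, tables)
      if (ra$role == "ligand") {
        if (!mol$canonical_key %in% lig_keys) {
          lig_keys <- c(lig_keys, mol$canonical_key)
          lig_mols <- c(lig_mols, list(mol))
          lig_kinds <- c(lig_kinds, ra$ligand_kind)
        }
      } else if (ra$role == "base") {
        base_keys <- c(base_keys, mol$canonical_key)
      } else if (ra$role == "solvent") {
        solv_keys <- c(solv_keys, mol$canonical_key)
      } else if (ra$role == "metal_source") {
        if (is.na(pd_key) && any(mol$graph$elem %in% .BH_CATALYST_METALS)) {
          pd_key <- mol$canonical_key
        }
        for (lig in extract_ligands_from_complex(mol, tables)) {
          if (!lig$canonical_key %in% lig_keys) {
            lig_keys <- c(lig_keys, lig$canonical_key)
            lig_mols <- c(lig_mols, list(lig))
            lig_kinds <- c(lig_kinds,
                           if (is_phosphine_ligand(lig)) "phosphine" else "NHC")
          }
        }
      }
    }
    if (length(lig_keys) == 0) {
      records$discard_reason[i] <- "ligand_undetected"
      records$discard_detail[i] <- "no ligand among declared species or complexes"
      next
    }
    if (length(lig_keys) > 1) {
      records$discard_reason[i] <- "ligand_ambiguous"
      records$discard_detail[i] <- paste(length(lig_keys), "distinct ligands")
      next
    }
    ub <- unique(base_keys); us <- unique(solv_keys)
    if (strict_roles && (length(ub) > 1 || length(us) > 1)) {
      records$discard_reason[i] <- "roles_unresolved"
      records$discard_detail[i] <- "multiple distinct bases or solvents"
      next
    }
    out$ligand_key[i] <- lig_keys[1]
    out$ligand_kind[i] <- lig_kinds[1]
    out$ligand_name[i] <- .display_name(
      lig_keys[1], tables$ligand_names, lig_mols[[1]]$canonical_smiles)
    if (length(ub) > 0) {
      out$base_key[i] <- ub[1]
      out$base_name[i] <- .display_name(ub[1], tables$bases, ub[1])
      out$multi_base[i] <- length(ub) > 1
    }
    if (length(us) > 0) {
      out$solvent_key[i] <- us[1]
      out$solvent_name[i] <- .display_name(us[1], tables$solvents, us[1])
      out$multi_solvent[i] <- length(us) > 1
    }
    out$pd_source_key[i] <- pd_key
  }
  for (nm in names(out)) records[[nm]] <- out[[nm]]
  records
}
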