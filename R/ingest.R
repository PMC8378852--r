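# Reading raw reaction tables and the upstream filters of the curation
# pipeline: single-step two-reactants/one-product template, missing
# structures, Pd catalysis, and raw-field duplicate removal.
#
# Stage functions are tibble-in/tibble-out. A record removed at any stage
# gets its single `discard_reason` (and free-text `discard_detail`) filled;
# downstream stages skip discarded rows, so |kept| + |discarded| is the
# input size at every stage.

.BH_SOURCES <- c("CAS", "Reaxys", "USPTO", "synthetic")
.BH_DISCARD_CODES <- c("not_single_step", "missing_structure", "not_pd",
                       "ligand_undetected", "ligand_ambiguous",
                       "roles_unresolved", "reactive_atom_fail", "duplicate")

.BH_COLUMNS <- c("record_id", "source", "doc_type", "pub_year",
                 "reactant_smiles", "product_smiles", "reagents",
                 "yield_percent", "temperature_C", "time_h")

#' Read raw reaction records from CSV/TSV
#'
#' Expects the documented schema: columns `record_id`, `source`,
#' `doc_type` (`patent`/`nonpatent`), `pub_year`, `reactant_smiles`
#' (semicolon-separated), `product_smiles`, `reagents` (semicolon-separated
#' `species|declared_field` pairs, field one of reagent/solvent/catalyst),
#' `yield_percent`, `temperature_C`, `time_h`. Header-driven, so column
#' order is free. Malformed rows are reported, not silently dropped: they
#' are returned in the `parse_errors` attribute (row number and message)
#' and well-formed rows keep their original order.
#'
#' @param path file path, or a data frame already in the schema.
#' @param dialect `"csv"` or `"tsv"`.
#' @param year_range allowed publication-year window.
#' @return a record tibble with list-columns `reactants` (character vectors)
#'   and `reagents` (tibbles with `species`, `field`), plus empty
#'   `discard_reason`/`discard_detail`; attribute `parse_errors`.
#' @export
read_reactions <- function(path, dialect = c("csv", "tsv"),
                           year_range = c(1950, 2035)) {
  dialect <- match.arg(dialect)
  raw <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else if (dialect == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  missing_cols <- setdiff(.BH_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste("missing mandatory columns:", paste(missing_cols, collapse = ", ")),
          class = "bhmeta_schema_error")
  }
  n <- nrow(raw)
  errs <- list()
  keep <- logical(n)
  num <- function(x) suppressWarnings(as.numeric(x))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rid <- as.character(raw$record_id[i])
    err <- NULL
    pub_year <- suppressWarnings(as.integer(raw$pub_year[i]))
    yld <- num(raw$yield_percent[i])
    reac_str <- as.character(raw$reactant_smiles[i])
    if (is.na(rid) || !nzchar(rid)) err <- "empty record_id"
    else if (is.na(reac_str) || !nzchar(trimws(reac_str))) err <- "empty reactant field"
    else if (is.na(pub_year) || pub_year < year_range[1] ||
             pub_year > year_range[2] || nchar(as.character(pub_year)) != 4) {
      err <- "pub_year missing or outside the configured range"
    } else if (!is.na(yld) && (yld < 0 || yld > 100)) {
      err <- "yield_percent outside [0, 100]"
    } else if (!as.character(raw$doc_type[i]) %in% c("patent", "nonpatent")) {
      err <- "doc_type must be patent or nonpatent"
    }
    if (!is.null(err)) {
      errs[[length(errs) + 1]] <- tibble::tibble(row = i, error = err)
      next
    }
    keep[i] <- TRUE
    reactants <- trimws(strsplit(reac_str, ";", fixed = TRUE)[[1]])
    reactants <- reactants[nzchar(reactants)]
    rg_str <- as.character(raw$reagents[i])
    rg <- if (is.na(rg_str) || !nzchar(trimws(rg_str))) {
      tibble::tibble(species = character(0), field = character(0))
    } else {
      parts <- trimws(strsplit(rg_str, ";", fixed = TRUE)[[1]])
      parts <- parts[nzchar(parts)]
      sp <- sub("\\|.*$", "", parts)
      fd <- ifelse(grepl("|", parts, fixed = TRUE),
                   sub("^.*\\|", "", parts), "reagent")
      fd[!fd %in% c("reagent", "solvent", "catalyst")] <- "reagent"
      tibble::tibble(species = sp, field = fd)
    }
    rows[[i]] <- tibble::tibble(
      record_id = rid,
      source = as.character(raw$source[i]),
      doc_type = as.character(raw$doc_type[i]),
      pub_year = pub_year,
      raw_reactants = reac_str,
      raw_product = as.character(raw$product_smiles[i]),
      raw_reagents = if (is.na(rg_str)) "" else rg_str,
      reactants = list(reactants),
      reagents = list(rg),
      yield_percent = yld,
      temperature_C = num(raw$temperature_C[i]),
      time_h = num(raw$time_h[i]))
  }
  records <- dplyr::bind_rows(rows[keep])
  if (nrow(records) == 0) {
    records <- tibble::tibble(
      record_id = character(0), source = character(0), doc_type = character(0),
      pub_year = integer(0), raw_reactants = character(0),
      raw_product = character(0), raw_reagents = character(0),
      reactants = list(), reagents = list(), yield_percent = numeric(0),
      temperature_C = numeric(0), time_h = numeric(0))
  }
  records$discard_reason <- rep(NA_character_, nrow(records))
  records$discard_detail <- rep(NA_character_, nrow(records))
  attr(records, "parse_errors") <- if (length(errs) > 0) {
    dplyr::bind_rows(errs)
  } else tibble::tibble(row = integer(0), error = character(0))
  records
}

#' Keep reactions matching the two-reactants-to-one-product template
#'
#' Kept records have exactly two parseable reactant structures and exactly
#' one parseable product structure. Wrong multiplicities discard as
#' `not_single_step`; empty or unparsable structures as
#' `missing_structure`. Canonical forms of the (substrate-normalized)
#' reactants and product are added as `r1_can`, `r2_can`, `product_can`.
#'
#' @param records record tibble from [read_reactions()].
#' @return the tibble with normalization columns added.
#' @export
filter_template <- function(records) {
  n <- nrow(records)
  r1c <- rep(NA_character_, n); r2c <- rep(NA_character_, n)
  pc <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(records$discard_reason[i])) next
    reac <- records$reactants[[i]]
    prods <- records$raw_product[i]
    prods <- if (is.na(prods)) character(0) else {
      p <- trimws(strsplit(prods, ";", fixed = TRUE)[[1]])
      p[nzchar(p)]
    }
    if (length(reac) != 2 || length(prods) > 1) {
      records$discard_reason[i] <- "not_single_step"
      records$discard_detail[i] <- sprintf("%d reactants, %d products",
                                           length(reac), length(prods))
      next
    }
    if (length(prods) == 0) {
      records$discard_reason[i] <- "missing_structure"
      records$discard_detail[i] <- "product structure missing"
      next
    }
    mols <- lapply(c(reac, prods), function(s) {
      tryCatch(normalize_molecule(s, "substrate"), error = function(e) NULL)
    })
    if (any(vapply(mols, is.null, logical(1)))) {
      records$discard_reason[i] <- "missing_structure"
      records$discard_detail[i] <- "unparsable reactant or product structure"
      next
    }
    r1c[i] <- mols[[1]]$canonical_smiles
    r2c[i] <- mols[[2]]$canonical_smiles
    pc[i] <- mols[[3]]$canonical_smiles
  }
  records$r1_can <- r1c
  records$r2_can <- r2c
  records$product_can <- pc
  records
}

#' Keep reactions with a palladium species among the declared reagents
#'
#' Element-presence test on every declared species regardless of its
#' declared field (fields are unreliable in the source data); records with
#' no Pd-containing species discard as `not_pd`.
#'
#' @param records record tibble.
#' @param tables role tables (for name-alias resolution of species).
#' @return the tibble, `not_pd` discards marked.
#' @export
filter_pd_catalyzed <- function(records, tables = role_tables()) {
  for (i in seq_len(nrow(records))) {
    if (!is.na(records$discard_reason[i])) next
    rg <- records$reagents[[i]]
    has_pd <- FALSE
    for (sp in rg$species) {
      mol <- resolve_reagent_species(sp, tables)
      if (!is.null(mol) && "Pd" %in% mol$graph$elem) { has_pd <- TRUE; break }
    }
    if (!has_pd) {
      records$discard_reason[i] <- "not_pd"
      records$discard_detail[i] <- "no palladium species declared"
    }
  }
  records
}

#' Remove records that are byte-identical on all raw fields
#'
#' The first-pass duplicate removal operating on raw data, before any
#' normalization: two records collapse only when source, document type,
#' year, raw structure fields, raw reagent field, yield, temperature and
#' time all coincide. Later occurrences discard as `duplicate`. Idempotent.
#'
#' @param records record tibble.
#' @return the tibble with raw duplicates marked.
#' @export
basic_dedup <- function(records) {
  sig <- paste(records$source, records$doc_type, records$pub_year,
               records$raw_reactants, records$raw_product,
               records$raw_reagents, records$yield_percent,
               records$temperature_C, records$time_h, sep = "\r")
  sig[!is.na(records$discard_reason)] <- paste0("discarded:",
    seq_len(nrow(records))[!is.na(records$discard_reason)])
  dup <- duplicated(sig)
  records$discard_reason[dup] <- "duplicate"
  records$discard_detail[dup] <- "raw-field duplicate"
  records
}

#' Kept and discarded views of a record tibble
#'
#' @param records record tibble at any stage.
#' @return `kept()`: rows with no discard reason; `discarded()`: the rest.
#' @export
kept <- function(records) records[is.na(records$discard_reason), ]

#' @rdname kept
#' @export
discarded <- function(records) records[!is.na(records$discard_reason), ]

#' Tally records by pipeline fate
#'
#' @param records record tibble.
#' @return tibble of discard reasons (NA = kept) with counts.
#' @export
pipeline_tally <- function(records) {
  records |>
    dplyr::count(.data$discard_reason, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
}
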