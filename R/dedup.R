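# Final cross-source deduplication: a reaction key hashes the canonical
# keys (InChI) of electrophile, nucleophile, product, solvent, base and
# ligand in a fixed order; within a key group only the earliest publication
# is kept.

.BH_KEY_PLACEHOLDER <- "(none)"

#' Compute the reaction key for every kept record
#'
#' SHA-256 digest of the `|`-joined canonical keys of (electrophile,
#' nucleophile, product, solvent, base, ligand), in that fixed order, with
#' a placeholder token for absent solvent/base slots. Identical reactions
#' get identical keys regardless of SMILES spelling or declared-reagent
#' order; temperature, time and yield are deliberately not part of the key.
#'
#' @param records classified record tibble (needs `ephile_key`,
#'   `nphile_key`, `product_can`, `solvent_key`, `base_key`, `ligand_key`).
#' @return the tibble with a `reaction_key` column added.
#' @export
reaction_key <- function(records) {
  n <- nrow(records)
  keys <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(records$discard_reason[i])) next
    if (is.na(records$ephile_key[i]) || is.na(records$nphile_key[i])) {
      abort("reaction_key on a record with unresolved roles (should have been discarded upstream)",
            class = "bhmeta_key_error")
    }
    pkey <- normalize_molecule(records$product_can[i], "substrate")$canonical_key
    comp <- c(records$ephile_key[i], records$nphile_key[i], pkey,
              records$solvent_key[i], records$base_key[i],
              records$ligand_key[i])
    comp[is.na(comp)] <- .BH_KEY_PLACEHOLDER
    keys[i] <- digest::digest(paste(comp, collapse = "|"), algo = "sha256",
                              serialize = FALSE)
  }
  records$reaction_key <- keys
  records
}

#' Collapse duplicate reactions, keeping the earliest publication
#'
#' Within each reaction-key group the record with the smallest publication
#' year is kept; year ties break deterministically by document type
#' (nonpatent first), then source name, then record id. Removed records
#' discard as `duplicate`. Idempotent. Yield disagreement within a group is
#' reported (not acted upon) via the `dupes` attribute, which lists each
#' collapsed group with its yield spread.
#'
#' @param records record tibble with `reaction_key`.
#' @return the tibble with duplicates marked; attribute `dupes`.
#' @export
dedup_keep_earliest <- function(records) {
  idx <- which(is.na(records$discard_reason))
  if (length(idx) == 0) {
    attr(records, "dupes") <- tibble::tibble(
      reaction_key = character(0), kept_id = character(0),
      removed_ids = character(0), n = integer(0), yield_spread = numeric(0))
    return(records)
  }
  sub <- records[idx, ]
  ord <- order(sub$pub_year,
               match(sub$doc_type, c("nonpatent", "patent")),
               sub$source, sub$record_id)
  first_of <- !duplicated(sub$reaction_key[ord])
  keep_pos <- idx[ord][first_of]
  drop_pos <- setdiff(idx, keep_pos)
  records$discard_reason[drop_pos] <- "duplicate"
  records$discard_detail[drop_pos] <- "cross-source duplicate (later publication)"

  grp <- records[idx, c("reaction_key", "record_id", "yield_percent")]
  grp$kept <- idx %in% keep_pos
  dupes <- grp |>
    dplyr::group_by(.data$reaction_key) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(
      kept_id = .data$record_id[.data$kept][1],
      removed_ids = paste(.data$record_id[!.data$kept], collapse = ";"),
      n = dplyr::n(),
      yield_spread = if (sum(!is.na(.data$yield_percent)) >= 2) {
        diff(range(.data$yield_percent, na.rm = TRUE))
      } else NA_real_,
      .groups = "drop")
  attr(records, "dupes") <- dupes
  records
}
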