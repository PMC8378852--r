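#' Run the full curation pipeline on raw records
#'
#' Chains the canonical stage order: template/missing-structure filter,
#' Pd filter, raw duplicate removal, reagent role resolution, reactant
#' classification, reaction-key deduplication (keep earliest). Every
#' removed record carries exactly one discard reason, so
#' kept + discarded = input at the end.
#'
#' @param records raw record tibble from [read_reactions()] (or a raw data
#'   frame in the CSV schema, which is ingested first).
#' @param tables role tables.
#' @param strict_roles see [resolve_roles()].
#' @return the fully annotated record tibble; attribute `dupes` from the
#'   final deduplication.
#' @export
run_pipeline <- function(records, tables = role_tables(),
                         strict_roles = FALSE) {
  if (!"discard_reason" %in% names(records)) {
    records <- read_reactions(records)
  }
  records |>
    filter_template() |>
    filter_pd_catalyzed(tables) |>
    basic_dedup() |>
    resolve_roles(tables, strict_roles = strict_roles) |>
    classify_reactants() |>
    reaction_key() |>
    dedup_keep_earliest()
}
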