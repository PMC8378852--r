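# Yield matrices by reagent x substrate class, the top-k condition
# cheatsheet with a minimum-support rule, and product-diversity proxies.

#' Median-yield matrix over two grouping keys
#'
#' Long-format matrix of reaction counts and yield summaries per
#' (row group x column group) cell. Counts cover all records in the cell;
#' median and quartiles are computed on the records with a reported yield
#' only (count and colour are separate channels in the display). Medians of
#' even-sized groups interpolate linearly between the central values.
#'
#' @param records deduplicated record tibble (kept rows are used).
#' @param row_key,col_key column names to group by (e.g. `"ligand_name"`,
#'   `"nphile_class"`).
#' @return tibble with `row`, `col`, `n`, `n_yield`, `median_yield`,
#'   `q1`, `q3`.
#' @export
median_yield_matrix <- function(records, row_key, col_key) {
  stopifnot(nzchar(row_key), nzchar(col_key))
  kk <- kept(records)
  kk |>
    dplyr::group_by(row = .data[[row_key]], col = .data[[col_key]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_yield = sum(!is.na(.data$yield_percent)),
      median_yield = if (.data$n_yield[1] >= 1) {
        stats::median(.data$yield_percent, na.rm = TRUE)
      } else NA_real_,
      q1 = if (.data$n_yield[1] >= 1) {
        unname(stats::quantile(.data$yield_percent, 0.25, na.rm = TRUE))
      } else NA_real_,
      q3 = if (.data$n_yield[1] >= 1) {
        unname(stats::quantile(.data$yield_percent, 0.75, na.rm = TRUE))
      } else NA_real_,
      .groups = "drop") |>
    dplyr::arrange(.data$row, .data$col)
}

#' Condition cheatsheet: top ligand/base combinations per substrate pair
#'
#' For every (electrophile class x nucleophile class) cell, all
#' (ligand, base) combinations backed by at least `min_count` reactions
#' are ranked by median reported yield and the top `top_k` kept.
#' Median ties rank the larger combination first, then alphabetically.
#' Cells where no combination reaches the support threshold are omitted
#' (an empty recommendation).
#'
#' @param records deduplicated, classified record tibble with resolved
#'   ligand and base.
#' @param min_count minimum reactions per combination (default 20).
#' @param top_k recommendations per cell (default 3).
#' @return tibble with `ephile_class`, `nphile_class`, `rank`,
#'   `ligand`, `base`, `median_yield`, `n`.
#' @export
build_cheatsheet <- function(records, min_count = 20, top_k = 3) {
  kk <- kept(records)
  kk <- kk[!is.na(kk$ligand_key) & !is.na(kk$base_key) &
           !is.na(kk$ephile_class) & !is.na(kk$nphile_class), ]
  combos <- kk |>
    dplyr::group_by(.data$ephile_class, .data$nphile_class,
                    ligand = .data$ligand_name, base = .data$base_name) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_yield = stats::median(.data$yield_percent, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::filter(.data$n >= min_count, !is.na(.data$median_yield))
  combos |>
    dplyr::group_by(.data$ephile_class, .data$nphile_class) |>
    dplyr::arrange(dplyr::desc(.data$median_yield), dplyr::desc(.data$n),
                   .data$ligand, .data$base, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= top_k) |>
    dplyr::ungroup() |>
    dplyr::select("ephile_class", "nphile_class", "rank", "ligand", "base",
                  "median_yield", "n")
}

#' Product diversity proxies per group
#'
#' For each group: mean product molecular weight, mean product heteroatom
#' count, and mean pairwise Tanimoto distance between products (circular
#' fingerprints, radius 4, folded to 2048 bits; groups above `cap` products
#' use a deterministic evenly-spaced subsample). Distance requires at least
#' two products.
#'
#' @param records record tibble (kept rows used).
#' @param grouping column name(s) to group by.
#' @param fp_radius,nbits fingerprint parameters.
#' @param cap pairwise-distance subsample cap.
#' @return tibble with `group`, `n`, `mean_product_mw`,
#'   `mean_product_heteroatoms`, `mean_tanimoto_distance`.
#' @export
diversity_table <- function(records, grouping, fp_radius = 4, nbits = 2048,
                            cap = 60) {
  kk <- kept(records)
  key <- do.call(paste, c(lapply(grouping, function(g) kk[[g]]), sep = " / "))
  groups <- split(seq_len(nrow(kk)), key)
  rows <- lapply(names(groups), function(gname) {
    ix <- groups[[gname]]
    mols <- lapply(kk$product_can[ix], function(s) {
      normalize_molecule(s, "substrate")
    })
    fps <- lapply(mols, morgan_fp, radius = fp_radius, nbits = nbits)
    tibble::tibble(
      group = gname, n = length(ix),
      mean_product_mw = mean(vapply(mols, mol_weight, numeric(1))),
      mean_product_heteroatoms = mean(vapply(mols, mol_heteroatoms, numeric(1))),
      mean_tanimoto_distance = mean_pairwise_tanimoto(fps, cap = cap))
  })
  dplyr::bind_rows(rows)
}
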