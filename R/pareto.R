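# The ligand recommender: per-ligand property profiles (medians and
# population standard deviations of substrate/product properties and
# yield), iterated Pareto-front peeling over user-selected properties, and
# a post-ranking yield filter.

.pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1) return(0)
  sqrt(mean((x - mean(x))^2))
}

#' Ortho-substituent count around a reactive atom
#'
#' For an aromatic reactive atom: the number of non-hydrogen, non-ring
#' substituents on the ring atoms adjacent to it (the leaving group sits on
#' the reactive atom itself, so it is never counted). For an exocyclic
#' amine nitrogen: the same count taken around each of its aromatic ring
#' neighbours. Non-ring reactive atoms with no aromatic neighbour count 0.
#'
#' @param mol `bhmol` or `mgraph`; `atom` the reactive atom index.
#' @return non-negative integer.
#' @export
count_ortho_substituents <- function(mol, atom) {
  g <- if (inherits(mol, "bhmol")) mol$graph else mol
  in_ring <- mgraph_ring_atoms(g)
  count_around <- function(center) {
    ring_nb <- intersect(mgraph_neighbors(g, center), which(in_ring))
    sum(vapply(ring_nb, function(p) {
      subs <- setdiff(mgraph_neighbors(g, p), c(center, which(in_ring)))
      length(subs)
    }, integer(1)))
  }
  if (in_ring[atom]) return(count_around(atom))
  ar_nb <- intersect(mgraph_neighbors(g, atom), which(g$arom))
  if (length(ar_nb) == 0) return(0L)
  sum(vapply(ar_nb, function(c0) {
    ring_nb <- intersect(mgraph_neighbors(g, c0), which(in_ring))
    sum(vapply(ring_nb, function(p) {
      length(setdiff(mgraph_neighbors(g, p), c(c0, atom, which(in_ring))))
    }, integer(1)))
  }, integer(1)))
}

.profile_props <- function(smiles_vec, reactive_atoms = NULL, fp_radius = 4) {
  mols <- lapply(smiles_vec, normalize_molecule, mode = "substrate")
  tibble::tibble(
    mw = vapply(mols, mol_weight, numeric(1)),
    heteroatoms = vapply(mols, mol_heteroatoms, numeric(1)),
    rings = vapply(mols, mol_rings, numeric(1)),
    het_h = vapply(mols, mol_heteroatom_h, numeric(1)),
    ortho = if (is.null(reactive_atoms)) {
      rep(NA_real_, length(mols))
    } else {
      vapply(seq_along(mols), function(i) {
        if (is.na(reactive_atoms[i])) return(NA_real_)
        as.numeric(count_ortho_substituents(mols[[i]], reactive_atoms[i]))
      }, numeric(1))
    },
    fp = lapply(mols, morgan_fp, radius = fp_radius))
}

# per-reaction Tanimoto distance = mean distance of this reaction's
# molecule to the same ligand's other reactions (same scope)
.per_reaction_tani <- function(fps) {
  n <- length(fps)
  if (n < 2) return(rep(0, n))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- tanimoto_distance(fps[[i]], fps[[j]])
  }
  rowSums(d) / (n - 1)
}

#' Per-ligand property profiles
#'
#' For every resolved ligand: the median and population standard deviation
#' of molecular weight, heteroatom count, ring count, heteroatom-H count,
#' ortho-substituent count and per-reaction Tanimoto distance, each over
#' the electrophile, nucleophile and product scope, plus yield. Ligands
#' used once get zero standard deviations and Tanimoto distance with the
#' `low_support` flag set.
#'
#' @param records deduplicated, classified record tibble.
#' @param fp_radius circular fingerprint radius (default 4).
#' @return tibble, one row per ligand, columns
#'   `<stat>_<property>_<scope>` plus `ligand`, `n_reactions`,
#'   `median_yield`, `sd_yield`, `low_support`.
#' @export
build_profiles <- function(records, fp_radius = 4) {
  kk <- kept(records)
  kk <- kk[!is.na(kk$ligand_key), ]
  props_e <- .profile_props(kk$ephile_smiles, kk$reactive_c, fp_radius)
  props_n <- .profile_props(kk$nphile_smiles, kk$reactive_n, fp_radius)
  props_p <- .profile_props(kk$product_can, NULL, fp_radius)

  scopes <- list(ephile = props_e, nphile = props_n, product = props_p)
  out <- list()
  for (lig in unique(kk$ligand_name)) {
    ix <- which(kk$ligand_name == lig)
    row <- list(ligand = lig, n_reactions = length(ix),
                median_yield = stats::median(kk$yield_percent[ix], na.rm = TRUE),
                sd_yield = .pop_sd(kk$yield_percent[ix]),
                low_support = length(ix) < 2)
    for (sc in names(scopes)) {
      pp <- scopes[[sc]][ix, ]
      for (prop in c("mw", "heteroatoms", "rings", "het_h", "ortho")) {
        v <- pp[[prop]]
        row[[paste0("median_", prop, "_", sc)]] <-
          if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
        row[[paste0("sd_", prop, "_", sc)]] <-
          if (all(is.na(v))) NA_real_ else .pop_sd(v)
      }
      tani <- .per_reaction_tani(pp$fp)
      row[[paste0("median_tanimoto_", sc)]] <- stats::median(tani)
      row[[paste0("sd_tanimoto_", sc)]] <- .pop_sd(tani)
    }
    out[[length(out) + 1]] <- tibble::as_tibble(row)
  }
  dplyr::bind_rows(out)
}

#' Iterated Pareto-front ranking of ligand profiles
#'
#' Standard non-domination with maximisation: profile a dominates b iff a
#' is at least as good on every selected column and strictly better on at
#' least one. Front 1 is the non-dominated set; fronts peel iteratively.
#' Use `invert` to minimise selected columns instead.
#'
#' @param profiles tibble from [build_profiles()] (or any table with a
#'   `ligand` column and numeric property columns).
#' @param selected character vector of property column names.
#' @param invert logical vector (recycled) marking columns to minimise.
#' @param include_yield add `median_yield` to the selected set instead of
#'   using it as a post-filter.
#' @return a `bh_pareto` object: tibble `ligand`, `front`, `n_reactions`,
#'   `median_yield` and the selected columns; metadata in attributes.
#' @export
pareto_rank <- function(profiles, selected, invert = FALSE,
                        include_yield = FALSE) {
  if (length(selected) == 0) {
    abort("at least one property must be selected", class = "bhmeta_pareto_error")
  }
  if (include_yield && !"median_yield" %in% selected) {
    selected <- c(selected, "median_yield")
  }
  missing_cols <- setdiff(selected, names(profiles))
  if (length(missing_cols) > 0) {
    abort(paste("unknown profile columns:", paste(missing_cols, collapse = ", ")),
          class = "bhmeta_pareto_error")
  }
  invert <- rep_len(invert, length(selected))
  vals <- as.matrix(profiles[, selected, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[, invert] <- -vals[, invert]
  if (anyNA(vals)) {
    abort("selected properties contain missing values", class = "bhmeta_pareto_error")
  }
  n <- nrow(vals)
  ge <- matrix(TRUE, n, n); gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(vals))) {
    ge <- ge & outer(vals[, k], vals[, k], `<=`) # ge[i,j]: j >= i on k
    gt <- gt | outer(vals[, k], vals[, k], `<`)  # gt[i,j]: j > i on k
  }
  dom <- ge & gt # dom[i,j]: j dominates i
  front <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  f <- 0L
  while (any(remaining)) {
    f <- f + 1L
    nd <- remaining & !apply(dom[, remaining, drop = FALSE], 1, any)
    nd <- nd & remaining
    if (!any(nd)) { # safety: cannot happen with a strict partial order
      nd <- remaining
    }
    front[nd] <- f
    remaining[nd] <- FALSE
    dom[, nd] <- FALSE
  }
  res <- tibble::tibble(
    ligand = profiles$ligand, front = front,
    n_reactions = profiles$n_reactions,
    median_yield = profiles$median_yield)
  res <- dplyr::bind_cols(res, profiles[, setdiff(selected, names(res)),
                                        drop = FALSE])
  res <- dplyr::arrange(res, .data$front, dplyr::desc(.data$median_yield))
  structure(res, class = c("bh_pareto", class(res)),
            selected = selected, invert = invert)
}

#' Drop ligands below a median-yield threshold, after ranking
#'
#' Mirrors the two-step recommender flow: fronts are computed first over
#' the selected properties, then the yield slider removes low-yield
#' ligands without recomputing ranks.
#'
#' @param results `bh_pareto` from [pareto_rank()].
#' @param threshold minimum median yield (percent).
#' @return the filtered `bh_pareto`.
#' @export
filter_by_yield <- function(results, threshold) {
  out <- results[!is.na(results$median_yield) &
                 results$median_yield >= threshold, ]
  structure(out, class = class(results),
            selected = attr(results, "selected"),
            invert = attr(results, "invert"))
}

#' @exportS3Method generics::tidy
tidy.bh_pareto <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @exportS3Method generics::glance
glance.bh_pareto <- function(x, ...) {
  tibble::tibble(
    n_ligands = nrow(x),
    n_fronts = if (nrow(x) > 0) max(x$front) else 0L,
    n_front1 = sum(x$front == 1),
    properties = paste(attr(x, "selected"), collapse = ", "))
}

#' @export
print.bh_pareto <- function(x, ...) {
  cat("Pareto ligand ranking over:",
      paste(attr(x, "selected"), collapse = ", "), "\n")
  NextMethod()
}
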