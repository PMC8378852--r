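# Open Babel bridge (via ChemmineOB) + the normalized molecule entity.
#
# Canonical SMILES and standard InChI come from Open Babel; the molecular
# graph used for substructure work is parsed from the canonical SMILES.
# All conversions are memoised in a package-local cache because corpora
# reuse a small vocabulary of distinct structures.

.bh_cache <- new.env(parent = emptyenv())

.cache_get <- function(key) .bh_cache[[key]]
.cache_set <- function(key, value) { .bh_cache[[key]] <- value; value }

#' Clear the molecule cache
#' @return invisibly, the number of entries removed.
#' @export
clear_mol_cache <- function() {
  n <- length(ls(.bh_cache))
  rm(list = ls(.bh_cache), envir = .bh_cache)
  invisible(n)
}

.ob_strip <- function(x) gsub("[ \t\r\n]", "", x)

# one SMILES -> one converted string; "" on failure
ob_convert1 <- function(smiles, to) {
  key <- paste0("ob:", to, ":", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", to, source = smiles)),
    error = function(e) "")
  .cache_set(key, .ob_strip(out))
}

ob_canonical <- function(smiles) ob_convert1(smiles, "CAN")

ob_inchi <- function(smiles) {
  x <- ob_convert1(smiles, "INCHI")
  if (!nzchar(x)) return("")
  x
}

# Kekulized SMILES via the obabel CLI (-xk output option); used by the
# tautomer enumerator, which needs localized single/double bonds.
ob_kekule <- function(smiles) {
  key <- paste0("obk:", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  out <- tryCatch(
    suppressWarnings(system2("obabel", c("-ismi", "-osmi", "-xk"),
                             input = smiles, stdout = TRUE, stderr = FALSE)),
    error = function(e) character(0))
  out <- out[nzchar(.ob_strip(out))]
  res <- if (length(out) == 0) "" else .ob_strip(sub("\t.*$", "", out[1]))
  .cache_set(key, res)
}

#' Normalize a structure and build a molecule entity
#'
#' In `substrate` mode the largest organic fragment is retained (counterions
#' and co-crystallised species dropped) and trivially ionised centres are
#' neutralised (e.g. an isolated alkoxide O- gains a hydrogen). In
#' `reagent` mode multi-fragment species are kept intact so that ionic
#' bases keep their identity for table lookup.
#'
#' The canonical key is the standard InChI of the normalized species (note
#' that standard InChI treats mobile hydrogens as equivalent, so tautomeric
#' drawings share a key); species Open Babel cannot express as InChI fall
#' back to a canonical-SMILES key.
#'
#' @param s a SMILES string.
#' @param mode `"substrate"` or `"reagent"`.
#' @return a `bhmol` object: list with `input_string`, `canonical_smiles`,
#'   `canonical_key`, and `graph` (an `mgraph`).
#' @export
normalize_molecule <- function(s, mode = c("substrate", "reagent")) {
  mode <- match.arg(mode)
  if (is.null(s) || length(s) != 1 || is.na(s) || !nzchar(trimws(s))) {
    abort("missing structure", class = "bhmeta_missing_structure")
  }
  s <- trimws(s)
  key <- paste0("mol:", mode, ":", s)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)

  can0 <- ob_canonical(s)
  if (!nzchar(can0)) bh_parse_error(paste0("unparsable SMILES: ", s), s)
  g <- smiles_graph(can0)

  if (mode == "substrate") {
    frags <- mgraph_fragments(g)
    if (length(frags) > 1) {
      has_c <- vapply(frags, function(ix) any(g$elem[ix] == "C"), logical(1))
      pool <- if (any(has_c)) frags[has_c] else frags
      sizes <- vapply(pool, length, integer(1))
      g <- mgraph_subset(g, pool[[which.max(sizes)]])
    }
    g <- .neutralize_trivial(g)
    can <- ob_canonical(mgraph_smiles(g))
    if (!nzchar(can)) bh_parse_error(paste0("normalization failed for: ", s), s)
    g <- smiles_graph(can)
  } else {
    can <- can0
  }

  inchi <- ob_inchi(can)
  ckey <- if (nzchar(inchi)) inchi else paste0("SMI:", can)
  out <- structure(
    list(input_string = s, canonical_smiles = can, canonical_key = ckey,
         graph = g),
    class = "bhmol")
  .cache_set(key, out)
}

#' @export
print.bhmol <- function(x, ...) {
  cat("<bhmol> ", x$canonical_smiles, "\n  key: ", x$canonical_key, "\n",
      sep = "")
  invisible(x)
}

# Neutralise chemically trivial charges: -1 on O/S/N with no positively
# charged neighbour gains one H; +1 N with an H and no negatively charged
# neighbour loses one. Zwitterionic pairs (e.g. nitro groups) are left alone.
.neutralize_trivial <- function(g) {
  n <- n_atoms(g)
  for (a in seq_len(n)) {
    nb <- mgraph_neighbors(g, a)
    if (g$charge[a] == -1L && g$elem[a] %in% c("O", "S", "N") &&
        !any(g$charge[nb] > 0)) {
      g$charge[a] <- 0L
      g$hcount[a] <- g$hcount[a] + 1L
    } else if (g$charge[a] == 1L && g$elem[a] == "N" && g$hcount[a] >= 1L &&
               !any(g$charge[nb] < 0)) {
      g$charge[a] <- 0L
      g$hcount[a] <- g$hcount[a] - 1L
    }
  }
  g
}

mol_contains_element <- function(mol, elems) {
  any(mol$graph$elem %in% elems)
}

contains_transition_metal <- function(mol) {
  mol_contains_element(mol, .BH_TRANSITION_METALS)
}
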