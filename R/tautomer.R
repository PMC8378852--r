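# Bounded tautomer enumeration via 1,3-hydrogen shifts.
#
# Used as the fallback in reactive-site detection when a substructure probe
# fails because reactant and product records draw a mobile-hydrogen group in
# different tautomeric forms (the classic case: 2-hydroxypyridine vs
# 2-pyridone). Enumeration works on the Kekulé structure (localized single
# and double bonds, obtained through Open Babel), applies all
# X1=X2-X3(H) -> X1(H)-X2=X3 shifts with X1, X3 in {N, O} and X2 carbon,
# re-canonicalises each result, and repeats breadth-first up to a cap.

#' Enumerate tautomers of a structure
#'
#' @param smiles a SMILES string.
#' @param cap maximum number of distinct tautomers returned (including the
#'   input form). Enumeration stops when the cap is reached.
#' @param max_depth maximum number of successive 1,3-shifts explored.
#' @return character vector of canonical SMILES, the input's canonical form
#'   first.
#' @export
enumerate_tautomers <- function(smiles, cap = 64, max_depth = 4) {
  can0 <- ob_canonical(smiles)
  if (!nzchar(can0)) bh_parse_error(paste0("unparsable SMILES: ", smiles), smiles)
  key <- paste0("taut:", can0, ":", cap, ":", max_depth)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)

  seen <- can0
  queue <- list(list(can = can0, depth = 0L))
  while (length(queue) > 0 && length(seen) < cap) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur$depth >= max_depth) next
    kek <- ob_kekule(cur$can)
    if (!nzchar(kek)) next
    g <- tryCatch(smiles_graph(kek), error = function(e) NULL)
    if (is.null(g)) next
    for (shifted in .shift_13(g)) {
      can <- ob_canonical(mgraph_smiles(shifted))
      if (!nzchar(can) || can %in% seen) next
      seen <- c(seen, can)
      queue[[length(queue) + 1]] <- list(can = can, depth = cur$depth + 1L)
      if (length(seen) >= cap) break
    }
  }
  .cache_set(key, seen)
}

# all single 1,3-shift variants of a kekulized graph
.shift_13 <- function(g) {
  out <- list()
  for (x3 in which(g$elem %in% c("N", "O") & g$hcount >= 1L & !g$arom)) {
    for (k1 in which((g$bonds$from == x3 | g$bonds$to == x3) & g$bonds$order == 1)) {
      x2 <- if (g$bonds$from[k1] == x3) g$bonds$to[k1] else g$bonds$from[k1]
      if (g$elem[x2] != "C") next
      for (k2 in which((g$bonds$from == x2 | g$bonds$to == x2) & g$bonds$order == 2)) {
        x1 <- if (g$bonds$from[k2] == x2) g$bonds$to[k2] else g$bonds$from[k2]
        if (x1 == x3 || !(g$elem[x1] %in% c("N", "O")) || g$arom[x1]) next
        g2 <- g
        g2$hcount[x3] <- g2$hcount[x3] - 1L
        g2$hcount[x1] <- g2$hcount[x1] + 1L
        g2$bonds$order[k1] <- 2
        g2$bonds$order[k2] <- 1
        out[[length(out) + 1]] <- g2
      }
    }
  }
  out
}
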