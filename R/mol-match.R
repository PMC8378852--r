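# Substructure matching = colored subgraph monomorphism (igraph VF2).
#
# Vertex colors encode (element, aromatic flag, charge); edge colors encode
# bond order. Hydrogen counts are deliberately NOT part of the color: a
# pattern atom matches a target atom with any number of hydrogens, which is
# the semantics needed for severed/created attachment points and for
# molecule-as-probe substructure tests.

.vf2_colors <- function(pat, tgt, wildcard = integer(0)) {
  pe <- pat$elem; pe[wildcard] <- "*"
  keys_p <- paste(pe, ifelse(seq_along(pe) %in% wildcard, "w", pat$arom),
                  ifelse(seq_along(pe) %in% wildcard, 0L, pat$charge))
  keys_t <- paste(tgt$elem, tgt$arom, tgt$charge)
  lev <- unique(c(keys_p, keys_t))
  list(p = match(keys_p, lev), t = match(keys_t, lev))
}

# existence of a subgraph monomorphism pattern -> target.
# `wildcard`: pattern atom indices that should match the same element with
# either aromaticity and any charge (used for attachment-point carbons).
mol_subiso <- function(pattern, target, wildcard = integer(0)) {
  if (n_atoms(pattern) > n_atoms(target)) return(FALSE)
  gp <- mgraph_igraph(pattern)
  gt <- mgraph_igraph(target)
  ec_p <- as.integer(pattern$bonds$order * 2)
  ec_t <- as.integer(target$bonds$order * 2)

  base_p <- paste(pattern$elem, pattern$arom, pattern$charge)
  keys_t <- paste(target$elem, target$arom, target$charge)

  variants <- list(base_p)
  for (w in wildcard) {
    new_variants <- list()
    for (v in variants) {
      for (ar in c(FALSE, TRUE)) for (ch in unique(target$charge)) {
        v2 <- v
        v2[w] <- paste(pattern$elem[w], ar, ch)
        new_variants <- c(new_variants, list(v2))
      }
    }
    variants <- unique(new_variants)
  }
  # note: igraph's vf2 sub-isomorphism takes color1/edge.color1 for the
  # TARGET graph and color2/edge.color2 for the pattern (internal argument
  # swap in subgraph_isomorphic); verified against known positives.
  for (v in variants) {
    lev <- unique(c(v, keys_t))
    ok <- tryCatch(
      igraph::subgraph_isomorphic(
        gp, gt, method = "vf2",
        vertex.color1 = match(keys_t, lev), vertex.color2 = match(v, lev),
        edge.color1 = ec_t, edge.color2 = ec_p),
      error = function(e) FALSE)
    if (ok) return(TRUE)
  }
  FALSE
}

# all monomorphism mappings (pattern atom -> target atom), exact colors
mol_subiso_maps <- function(pattern, target) {
  if (n_atoms(pattern) > n_atoms(target)) return(list())
  cols <- .vf2_colors(pattern, target)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(
      mgraph_igraph(pattern), mgraph_igraph(target), method = "vf2",
      vertex.color1 = cols$t, vertex.color2 = cols$p,
      edge.color1 = as.integer(target$bonds$order * 2),
      edge.color2 = as.integer(pattern$bonds$order * 2)),
    error = function(e) list())
  lapply(maps, as.integer)
}

# whole-molecule isomorphism with one distinguished (rooted) atom on each
# side; used to collapse symmetry-equivalent reactive-site candidates.
mols_rooted_isomorphic <- function(m1, root1, m2, root2) {
  if (n_atoms(m1) != n_atoms(m2)) return(FALSE)
  k1 <- paste(m1$elem, m1$arom, m1$charge)
  k2 <- paste(m2$elem, m2$arom, m2$charge)
  k1[root1] <- paste0("ROOT|", k1[root1])
  k2[root2] <- paste0("ROOT|", k2[root2])
  lev <- unique(c(k1, k2))
  tryCatch(
    igraph::isomorphic(
      mgraph_igraph(m1), mgraph_igraph(m2), method = "vf2",
      vertex.color1 = match(k1, lev), vertex.color2 = match(k2, lev),
      edge.color1 = as.integer(m1$bonds$order * 2),
      edge.color2 = as.integer(m2$bonds$order * 2)),
    error = function(e) FALSE)
}

# two atoms of the same molecule are symmetry-equivalent iff an automorphism
# maps one onto the other
atoms_equivalent <- function(m, a, b) {
  if (a == b) return(TRUE)
  mols_rooted_isomorphic(m, a, m, b)
}
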