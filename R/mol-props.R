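# Molecular property block used by the diversity proxies and the ligand
# recommender: molecular weight, heteroatom count, ring count, heteroatom-H
# substructure count, and circular (Morgan-type) fingerprints for Tanimoto
# distances.

#' Molecular weight of a molecule entity (g/mol), including hydrogens
#' @param mol a `bhmol` or `mgraph`.
#' @export
mol_weight <- function(mol) {
  g <- if (inherits(mol, "bhmol")) mol$graph else mol
  w <- .BH_MASS[g$elem]
  w[is.na(w)] <- 0
  sum(w) + sum(g$hcount) * .BH_MASS[["H"]]
}

#' Heteroatom count (non-carbon heavy atoms)
#' @inheritParams mol_weight
#' @export
mol_heteroatoms <- function(mol) {
  g <- if (inherits(mol, "bhmol")) mol$graph else mol
  sum(g$elem != "C")
}

#' Ring count (cyclomatic number: bonds - atoms + fragments)
#' @inheritParams mol_weight
#' @export
mol_rings <- function(mol) {
  g <- if (inherits(mol, "bhmol")) mol$graph else mol
  ncomp <- length(mgraph_fragments(g))
  n_bonds(g) - n_atoms(g) + ncomp
}

#' Number of heteroatom-H groups (N-H, O-H, S-H, P-H bearing atoms)
#' @inheritParams mol_weight
#' @export
mol_heteroatom_h <- function(mol) {
  g <- if (inherits(mol, "bhmol")) mol$graph else mol
  sum(g$elem %in% c("N", "O", "S", "P") & g$hcount >= 1L)
}

# --- circular fingerprints ---------------------------------------------

# deterministic 31-bit integer mixing (doubles keep exact integers < 2^53)
.mix <- function(vals) {
  h <- 2166136261
  for (v in vals) {
    h <- (h * 16777619) %% 2147483647
    h <- (h + v) %% 2147483647
  }
  h
}

#' Circular (Morgan-type) fingerprint
#'
#' Iterative neighbourhood hashing in the spirit of ECFP: the initial atom
#' invariant combines element, degree, hydrogen count, charge and
#' aromaticity; each round folds in the sorted (bond order, neighbour hash)
#' pairs. All environment identifiers from radius 0 to `radius` are folded
#' into a fixed-length bit set.
#'
#' @param mol a `bhmol` or `mgraph`.
#' @param radius neighbourhood radius (default 4).
#' @param nbits folded length (default 2048).
#' @return sorted integer vector of set bit positions (0-based).
#' @export
morgan_fp <- function(mol, radius = 4, nbits = 2048) {
  g <- if (inherits(mol, "bhmol")) mol$graph else mol
  n <- n_atoms(g)
  elem_code <- match(g$elem, names(.BH_MASS), nomatch = 99L)
  deg <- integer(n)
  nb <- vector("list", n)
  bo <- vector("list", n)
  for (k in seq_len(n_bonds(g))) {
    f <- g$bonds$from[k]; t <- g$bonds$to[k]; o <- as.integer(g$bonds$order[k] * 2)
    nb[[f]] <- c(nb[[f]], t); bo[[f]] <- c(bo[[f]], o)
    nb[[t]] <- c(nb[[t]], f); bo[[t]] <- c(bo[[t]], o)
    deg[f] <- deg[f] + 1L; deg[t] <- deg[t] + 1L
  }
  h <- vapply(seq_len(n), function(a) {
    .mix(c(elem_code[a], deg[a], g$hcount[a], g$charge[a] + 10,
           as.integer(g$arom[a])))
  }, numeric(1))
  bits <- h
  if (radius > 0) {
    for (r in seq_len(radius)) {
      h2 <- vapply(seq_len(n), function(a) {
        if (deg[a] == 0) return(.mix(c(h[a], r)))
        pairs <- cbind(bo[[a]], h[nb[[a]]])
        ord <- order(pairs[, 1], pairs[, 2])
        .mix(c(h[a], r, t(pairs[ord, , drop = FALSE])))
      }, numeric(1))
      h <- h2
      bits <- c(bits, h)
    }
  }
  sort(unique(as.integer(bits %% nbits)))
}

#' Tanimoto distance between two fingerprints (bit-position vectors)
#' @param fp1,fp2 integer vectors of set bits as returned by [morgan_fp()].
#' @return 1 - |intersection| / |union|, in [0, 1].
#' @export
tanimoto_distance <- function(fp1, fp2) {
  if (length(fp1) == 0 && length(fp2) == 0) return(0)
  inter <- length(intersect(fp1, fp2))
  1 - inter / (length(fp1) + length(fp2) - inter)
}

# mean pairwise Tanimoto distance of a list of fingerprints; for large
# groups a deterministic evenly-spaced subsample keeps this quadratic step
# bounded (no RNG involved, so results are reproducible by construction).
mean_pairwise_tanimoto <- function(fps, cap = 60) {
  n <- length(fps)
  if (n < 2) return(NA_real_)
  if (n > cap) {
    fps <- fps[unique(round(seq(1, n, length.out = cap)))]
    n <- length(fps)
  }
  tot <- 0; cnt <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    tot <- tot + tanimoto_distance(fps[[i]], fps[[j]])
    cnt <- cnt + 1L
  }
  tot / cnt
}
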