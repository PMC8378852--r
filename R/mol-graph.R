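#' @importFrom rlang abort
NULL

# Standard valences used for implicit-hydrogen completion of organic-subset
# atoms. Multi-valent S/P/N pick the smallest valence >= current bond sum.
.BH_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

.BH_AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s", "se", "as")

# Monoisotopic-free average atomic masses for molecular weight sums.
.BH_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Ni = 58.693,
  Cu = 63.546, Zn = 65.38, Br = 79.904, I = 126.904, Li = 6.94,
  Cs = 132.905, Pd = 106.42, Pt = 195.084, Rh = 102.906, Ru = 101.07
)

.BH_TRANSITION_METALS <- c(
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg"
)

bh_parse_error <- function(msg, smiles = NULL) {
  abort(msg, class = "bhmeta_parse_error", smiles = smiles)
}

#' Parse a SMILES string into a molecular graph
#'
#' A minimal SMILES reader covering the dialect written by Open Babel's
#' canonical SMILES writer: organic-subset and bracket atoms, aromatic
#' lowercase notation, charges, explicit hydrogen counts, ring closures
#' (including `%nn`), branches and dot-separated fragments. Stereo markers
#' are accepted and ignored. Aromatic flags are taken from the lowercase
#' notation; unmarked bonds between two aromatic atoms are aromatic only
#' when they lie on a ring, otherwise single (biaryl bonds).
#'
#' @param s a single SMILES string.
#' @return an object of class `mgraph`: a list with `elem`, `arom`,
#'   `charge`, `hcount` (per-atom vectors), and `bonds`
#'   (matrix-backed list with `from`, `to`, `order`; aromatic order is 1.5).
#' @keywords internal
smiles_graph <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) {
    bh_parse_error("empty SMILES", s)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  nch <- length(chars)

  elem <- character(0); arom <- logical(0)
  charge <- integer(0); hexp <- integer(0) # NA_integer_ = implicit
  bf <- integer(0); bt <- integer(0); bo <- numeric(0) # NA order = default

  prev <- NA_integer_
  stack <- integer(0)
  ring_open <- list() # key: ring number as character -> list(atom, order)
  pend <- NA_real_

  add_atom <- function(el, ar, ch, hh) {
    elem[length(elem) + 1L] <<- el
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- ch
    hexp[length(hexp) + 1L] <<- hh
    idx <- length(elem)
    if (!is.na(prev)) {
      bf[length(bf) + 1L] <<- prev
      bt[length(bt) + 1L] <<- idx
      bo[length(bo) + 1L] <<- pend
    }
    pend <<- NA_real_
    prev <<- idx
    idx
  }

  close_ring <- function(num) {
    key <- as.character(num)
    if (is.null(ring_open[[key]])) {
      if (is.na(prev)) bh_parse_error("ring bond before any atom", s)
      ring_open[[key]] <<- list(atom = prev, order = pend)
      pend <<- NA_real_
    } else {
      op <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      ord <- if (!is.na(pend)) pend else op$order
      bf[length(bf) + 1L] <<- op$atom
      bt[length(bt) + 1L] <<- prev
      bo[length(bo) + 1L] <<- ord
      pend <<- NA_real_
    }
  }

  i <- 1L
  while (i <= nch) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= nch && chars[j] != "]") j <- j + 1L
      if (j > nch) bh_parse_error("unclosed bracket atom", s)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{1,2})?(H[0-9]*)?(\\+[0-9]*|-[0-9]*|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0) bh_parse_error(paste0("bad bracket atom [", body, "]"), s)
      sym <- m[3]
      ar <- sym %in% .BH_AROMATIC_ELEMS
      el <- if (ar) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      } else sym
      hh <- if (m[5] == "") 0L else if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
      chg <- 0L
      if (m[6] != "") {
        cs <- m[6]
        if (grepl("^\\++$", cs)) chg <- nchar(cs)
        else if (grepl("^-+$", cs)) chg <- -nchar(cs)
        else if (cs == "+") chg <- 1L
        else if (cs == "-") chg <- -1L
        else chg <- as.integer(cs)
      }
      add_atom(el, ar, as.integer(chg), hh)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < nch && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), FALSE, 0L, NA_integer_)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, 0L, NA_integer_)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(paste0(toupper(ch)), TRUE, 0L, NA_integer_)
      i <- i + 1L
    } else if (ch == "-") { pend <- 1; i <- i + 1L
    } else if (ch == "=") { pend <- 2; i <- i + 1L
    } else if (ch == "#") { pend <- 3; i <- i + 1L
    } else if (ch == ":") { pend <- 1.5; i <- i + 1L
    } else if (ch %in% c("/", "\\")) { pend <- 1; i <- i + 1L
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) bh_parse_error("unmatched ')'", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") { prev <- NA_integer_; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nch) bh_parse_error("bad %nn ring closure", s)
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else {
      bh_parse_error(paste0("unexpected character '", ch, "'"), s)
    }
  }
  if (length(ring_open) > 0) bh_parse_error("unmatched ring bonds", s)
  if (length(stack) > 0) bh_parse_error("unmatched '('", s)
  if (length(elem) == 0) bh_parse_error("no atoms", s)

  m <- list(elem = elem, arom = arom, charge = charge, hcount = hexp,
            bonds = list(from = bf, to = bt, order = bo))
  m <- .resolve_default_bonds(m)
  m <- .fill_implicit_h(m, smiles = s)
  class(m) <- "mgraph"
  m
}

# Unmarked bonds: aromatic only when both atoms aromatic AND the bond lies
# on a cycle; otherwise single (e.g. biaryl links between two rings).
.resolve_default_bonds <- function(m) {
  bo <- m$bonds$order
  nb <- length(bo)
  if (nb == 0) return(m)
  need <- which(is.na(bo))
  if (length(need) == 0) return(m)
  both_ar <- m$arom[m$bonds$from[need]] & m$arom[m$bonds$to[need]]
  bo[need[!both_ar]] <- 1
  cand <- need[both_ar]
  if (length(cand) > 0) {
    g <- igraph::make_graph(rbind(m$bonds$from, m$bonds$to),
                            n = length(m$elem), directed = FALSE)
    for (k in cand) {
      g2 <- igraph::delete_edges(g, k)
      on_cycle <- igraph::distances(
        g2, v = m$bonds$from[k], to = m$bonds$to[k]) < Inf
      bo[k] <- if (on_cycle) 1.5 else 1
    }
  }
  m$bonds$order <- bo
  m
}

.fill_implicit_h <- function(m, smiles = NULL) {
  n <- length(m$elem)
  bsum <- numeric(n)
  if (length(m$bonds$from) > 0) {
    for (k in seq_along(m$bonds$from)) {
      bsum[m$bonds$from[k]] <- bsum[m$bonds$from[k]] + m$bonds$order[k]
      bsum[m$bonds$to[k]] <- bsum[m$bonds$to[k]] + m$bonds$order[k]
    }
  }
  h <- m$hcount
  for (a in seq_len(n)) {
    if (!is.na(h[a])) next
    el <- m$elem[a]
    vs <- .BH_VALENCE[[el]]
    if (is.null(vs)) { h[a] <- 0L; next }
    if (m$arom[a]) {
      h[a] <- if (el == "C") max(0L, as.integer(4 - floor(bsum[a]))) else 0L
    } else {
      sm <- bsum[a]
      v <- vs[vs >= sm][1]
      if (is.na(v)) {
        if (sm > max(vs) + 0.5) {
          bh_parse_error(sprintf("valence error on %s (bond sum %.1f)", el, sm),
                         smiles)
        }
        v <- max(vs)
      }
      h[a] <- max(0L, as.integer(round(v - sm)))
    }
  }
  m$hcount <- h
  m
}

n_atoms <- function(m) length(m$elem)
n_bonds <- function(m) length(m$bonds$from)

mgraph_igraph <- function(m) {
  igraph::make_graph(rbind(m$bonds$from, m$bonds$to),
                     n = n_atoms(m), directed = FALSE)
}

# connected components as list of atom index vectors
mgraph_fragments <- function(m) {
  g <- mgraph_igraph(m)
  comp <- igraph::components(g)$membership
  split(seq_len(n_atoms(m)), comp)
}

# extract the submolecule on a subset of atoms (bonds within the subset)
mgraph_subset <- function(m, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- integer(n_atoms(m)); map[keep] <- seq_along(keep)
  bsel <- which(m$bonds$from %in% keep & m$bonds$to %in% keep)
  out <- list(
    elem = m$elem[keep], arom = m$arom[keep], charge = m$charge[keep],
    hcount = m$hcount[keep],
    bonds = list(from = map[m$bonds$from[bsel]], to = map[m$bonds$to[bsel]],
                 order = m$bonds$order[bsel])
  )
  class(out) <- "mgraph"
  attr(out, "orig_index") <- keep
  out
}

mgraph_drop_bonds <- function(m, bond_idx) {
  sel <- setdiff(seq_len(n_bonds(m)), bond_idx)
  m$bonds <- list(from = m$bonds$from[sel], to = m$bonds$to[sel],
                  order = m$bonds$order[sel])
  m
}

mgraph_neighbors <- function(m, a) {
  c(m$bonds$to[m$bonds$from == a], m$bonds$from[m$bonds$to == a])
}

mgraph_bond_between <- function(m, a, b) {
  which((m$bonds$from == a & m$bonds$to == b) |
        (m$bonds$from == b & m$bonds$to == a))
}

# atoms that belong to at least one ring
mgraph_ring_atoms <- function(m) {
  g <- mgraph_igraph(m)
  deg_ok <- rep(FALSE, n_atoms(m))
  if (n_bonds(m) == 0) return(deg_ok)
  # an atom is in a ring iff it lies in a biconnected component with a cycle
  bc <- igraph::biconnected_components(g)
  for (i in seq_along(bc$components)) {
    vs <- as.integer(bc$components[[i]])
    es <- length(bc$component_edges[[i]])
    if (es >= length(vs) && length(vs) >= 3) deg_ok[vs] <- TRUE
  }
  deg_ok
}

#' Write an `mgraph` back to SMILES
#'
#' Every atom is written in bracket form with its explicit hydrogen count,
#' so the output is self-describing and round-trips through Open Babel
#' without relying on implicit-valence conventions.
#' @keywords internal
mgraph_smiles <- function(m) {
  n <- n_atoms(m)
  adj <- vector("list", n)
  for (k in seq_len(n_bonds(m))) {
    f <- m$bonds$from[k]; t <- m$bonds$to[k]
    adj[[f]] <- c(adj[[f]], k); adj[[t]] <- c(adj[[t]], k)
  }
  other <- function(k, a) if (m$bonds$from[k] == a) m$bonds$to[k] else m$bonds$from[k]

  visited <- rep(FALSE, n)
  tree_edge <- rep(FALSE, max(1L, n_bonds(m)))
  ring_num <- 0L
  ring_tok <- vector("list", n) # per atom: character tokens of ring closures

  bsym <- function(ord, a, b) {
    if (ord == 1.5) return("")
    if (ord == 2) return("=")
    if (ord == 3) return("#")
    if (m$arom[a] && m$arom[b]) return("-")
    ""
  }
  atom_tok <- function(a) {
    sym <- if (m$arom[a]) tolower(m$elem[a]) else m$elem[a]
    hh <- m$hcount[a]
    hstr <- if (hh == 0) "" else if (hh == 1) "H" else paste0("H", hh)
    ch <- m$charge[a]
    cstr <- if (ch == 0) "" else if (ch == 1) "+" else if (ch == -1) "-" else
      if (ch > 0) paste0("+", ch) else paste0("-", abs(ch))
    paste0("[", sym, hstr, cstr, "]")
  }

  # first pass: mark spanning tree + assign ring closure numbers to back edges
  parts <- character(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    # iterative DFS recording tree edges
    stack <- list(list(atom = root, via = NA_integer_))
    order_seen <- integer(0)
    visited[root] <- TRUE
    dfs_children <- vector("list", n)
    dfs_parent_edge <- rep(NA_integer_, n)
    st <- c(root); pe <- c(NA_integer_)
    # classic explicit stack DFS
    S <- root; PEdge <- NA_integer_
    stk <- list(root)
    while (length(stk) > 0) {
      a <- stk[[length(stk)]]; stk[[length(stk)]] <- NULL
      order_seen <- c(order_seen, a)
      for (k in adj[[a]]) {
        b <- other(k, a)
        if (!visited[b]) {
          visited[b] <- TRUE
          tree_edge[k] <- TRUE
          dfs_children[[a]] <- c(dfs_children[[a]], list(c(b, k)))
          stk[[length(stk) + 1L]] <- b
        }
      }
    }
    # back edges in this component get ring numbers
    comp_atoms <- order_seen
    for (a in comp_atoms) {
      for (k in adj[[a]]) {
        if (tree_edge[k]) next
        b <- other(k, a)
        if (b < a) next # handle each back edge once
        ring_num <- ring_num + 1L
        num_tok <- if (ring_num <= 9) as.character(ring_num) else
          sprintf("%%%02d", ring_num)
        sy <- bsym(m$bonds$order[k], a, b)
        ring_tok[[a]] <- c(ring_tok[[a]], paste0(sy, num_tok))
        ring_tok[[b]] <- c(ring_tok[[b]], paste0(sy, num_tok))
      }
    }
    # second pass: build string recursively over the spanning tree
    build <- function(a) {
      out <- paste0(atom_tok(a), paste0(ring_tok[[a]], collapse = ""))
      kids <- dfs_children[[a]]
      if (length(kids) > 0) {
        segs <- vapply(kids, function(bk) {
          b <- bk[1]; k <- bk[2]
          paste0(bsym(m$bonds$order[k], a, b), build(b))
        }, character(1))
        if (length(segs) > 1) {
          out <- paste0(out,
                        paste0("(", segs[-length(segs)], ")", collapse = ""),
                        segs[length(segs)])
        } else {
          out <- paste0(out, segs)
        }
      }
      out
    }
    parts <- c(parts, build(root))
  }
  paste(parts, collapse = ".")
}
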