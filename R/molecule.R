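#' @importFrom methods new is
#' @importFrom stats sd cor predict kmeans t.test pt rnorm runif setNames
#' @importFrom utils read.csv write.csv head
NULL

# Default valences used to infer implicit hydrogen counts on the heavy-atom
# graph. Unlisted elements are assumed to carry no implicit hydrogens.
.default_valence <- c(
  C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, B = 3L,
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

#' Construct a molecule
#'
#' A molecule is a heavy-atom graph: a data frame of atoms (element symbol,
#' formal charge, aromatic flag) plus a data frame of bonds (indices of the
#' two atoms and the bond order). Hydrogens are implicit and derived from
#' default valences; the suggestion engine and the descriptor layer both work
#' on this representation.
#'
#' @param id Compound identifier (unique within a library).
#' @param atoms Data frame with columns `element` (character), and optionally
#'   `charge` (integer, default 0) and `aromatic` (logical, default FALSE).
#' @param bonds Data frame with columns `a1`, `a2` (atom indices) and `order`
#'   (1, 2, 3, or 4 for aromatic); may have zero rows.
#' @return An object of class `bq_mol`.
#' @export
molecule <- function(id, atoms, bonds = data.frame(a1 = integer(), a2 = integer(), order = integer())) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  atoms <- as.data.frame(atoms)
  stopifnot("element" %in% names(atoms))
  if (is.null(atoms$charge))   atoms$charge   <- rep(0L, nrow(atoms))
  if (is.null(atoms$aromatic)) atoms$aromatic <- rep(FALSE, nrow(atoms))
  atoms <- atoms[, c("element", "charge", "aromatic")]
  atoms$element  <- as.character(atoms$element)
  atoms$charge   <- as.integer(atoms$charge)
  atoms$aromatic <- as.logical(atoms$aromatic)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    stopifnot(all(c("a1", "a2", "order") %in% names(bonds)))
    bonds <- bonds[, c("a1", "a2", "order")]
    bonds[] <- lapply(bonds, as.integer)
    n <- nrow(atoms)
    if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n))
      stop("bond references a non-existent atom", call. = FALSE)
    if (any(bonds$a1 == bonds$a2))
      stop("bond must reference two distinct atoms", call. = FALSE)
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  structure(list(id = id, atoms = atoms, bonds = bonds), class = "bq_mol")
}

#' @export
print.bq_mol <- function(x, ...) {
  cat(sprintf("<bq_mol %s: %d heavy atoms, %d bonds>\n",
              x$id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

mol_natoms <- function(mol) nrow(mol$atoms)

# Sum of bond orders incident to each atom (aromatic order-4 bonds count 1.5).
mol_order_sums <- function(mol) {
  s <- numeric(mol_natoms(mol))
  if (nrow(mol$bonds)) {
    o <- ifelse(mol$bonds$order == 4L, 1.5, mol$bonds$order)
    for (i in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$a1[i]] <- s[mol$bonds$a1[i]] + o[i]
      s[mol$bonds$a2[i]] <- s[mol$bonds$a2[i]] + o[i]
    }
  }
  s
}

# Implicit hydrogen count per heavy atom from default valences.
mol_implicit_h <- function(mol) {
  val <- .default_valence[mol$atoms$element]
  val[is.na(val)] <- 0L
  h <- round(val - mol_order_sums(mol) - abs(mol$atoms$charge))
  pmax(as.integer(h), 0L)
}

mol_degree <- function(mol) {
  d <- integer(mol_natoms(mol))
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds$a1, nbins = mol_natoms(mol))
    t2 <- tabulate(mol$bonds$a2, nbins = mol_natoms(mol))
    d <- t1 + t2
  }
  d
}

mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = mol_natoms(mol), directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2),
                           order = mol$bonds$order)
  igraph::set_vertex_attr(g, "element", value = mol$atoms$element)
}

# Adjacency list: for each atom, the indices of bonded neighbours.
mol_adjacency <- function(mol) {
  adj <- vector("list", mol_natoms(mol))
  for (i in seq_along(adj)) adj[[i]] <- integer()
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# Edge ids (rows of mol$bonds) that lie on a cycle, i.e. are not bridges.
mol_ring_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(integer())
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
}

# Approximate aromaticity perception: an atom is flagged aromatic when it is
# incident to an order-4 bond, or to an in-ring double bond (the usual result
# of reading a Kekule-form SDF of an aromatic ring). Exact Hueckel perception
# is out of scope; only descriptor atom typing consumes this flag.
mol_perceive_aromatic <- function(mol) {
  n <- mol_natoms(mol)
  arom <- rep(FALSE, n)
  if (nrow(mol$bonds)) {
    ring <- mol_ring_bonds(mol)
    for (i in ring) {
      if (mol$bonds$order[i] >= 2L) {
        arom[mol$bonds$a1[i]] <- TRUE
        arom[mol$bonds$a2[i]] <- TRUE
      }
    }
  }
  mol$atoms$aromatic <- arom
  mol
}

# Canonical key for (sub)graph identity. Vertex colors fold together the
# element and the incident bond-order sum, then BLISS canonical labeling
# orders the serialization. Exact for the single-bond fragments this package
# manipulates; isomer pairs differing only in internal bond-order placement
# over an automorphic skeleton could in principle collide (documented).
graph_key <- function(elements, bonds, extra_color = NULL) {
  n <- length(elements)
  if (n == 0L) return("empty")
  code <- as.integer(factor(elements, levels = sort(unique(elements))))
  osum <- numeric(n)
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      o <- if (bonds$order[i] == 4L) 1.5 else bonds$order[i]
      osum[bonds$a1[i]] <- osum[bonds$a1[i]] + o
      osum[bonds$a2[i]] <- osum[bonds$a2[i]] + o
    }
  }
  color <- code * 32L + pmin(as.integer(round(osum * 2)), 31L)
  if (!is.null(extra_color)) color <- color * 4L + as.integer(extra_color)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  perm <- igraph::canonical_permutation(g, colors = color)$labeling
  # position i of the canonical ordering holds original vertex which(perm==i)
  inv <- order(perm)
  elems <- paste(elements[inv], color[inv], sep = ":", collapse = ",")
  if (nrow(bonds)) {
    e1 <- perm[bonds$a1]; e2 <- perm[bonds$a2]
    lo <- pmin(e1, e2); hi <- pmax(e1, e2)
    ord <- order(lo, hi)
    edges <- paste(lo[ord], hi[ord], bonds$order[ord], sep = "-", collapse = ";")
  } else edges <- ""
  paste0(elems, "|", edges)
}

#' Canonical identity key of a molecule
#'
#' Two molecules with the same key have isomorphic heavy-atom graphs with
#' matching elements, charges and bond orders. Used for chimera
#' deduplication and round-trip checks.
#'
#' @param mol A `bq_mol`.
#' @return A character scalar.
#' @export
mol_key <- function(mol) {
  graph_key(paste0(mol$atoms$element, ifelse(mol$atoms$charge == 0L, "",
                                             sprintf("%+d", mol$atoms$charge))),
            mol$bonds)
}

mol_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  nh <- sum(mol_implicit_h(mol))
  parts <- character()
  for (el in c("C", "H", sort(setdiff(names(counts), c("C", "H"))))) {
    k <- if (el == "H") nh + sum(counts[names(counts) == "H"]) else counts[el]
    if (!is.na(k) && length(k) && k > 0)
      parts <- c(parts, paste0(el, ifelse(k > 1, k, "")))
  }
  paste(parts, collapse = "")
}

.atomic_mass <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904,
                  I = 126.904)

mol_weight <- function(mol) {
  m <- .atomic_mass[mol$atoms$element]
  m[is.na(m)] <- 0
  sum(m) + sum(mol_implicit_h(mol)) * .atomic_mass[["H"]]
}
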