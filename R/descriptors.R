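# Two descriptor sets computed from the heavy-atom connection table.
#
# "general"          — physicochemical: additive atomic-contribution logP and
#                      molar refractivity (Crippen-style compact atom typing),
#                      approximate per-atom van der Waals surface areas
#                      partitioned by atomic property bins (Labute-style),
#                      and PEOE (Gasteiger-style) partial-charge statistics.
# "drug_like_index"  — topological: ring, ring-system, linker, framework and
#                      side-chain counts plus a scalar drug-like index over
#                      the structural hierarchy.
#
# The exact descriptor definitions of commercial packages are proprietary;
# these are documented open analogues. The pipeline only requires a
# deterministic, atom-order-invariant compound -> vector map.

# -- additive logP / molar refractivity atom contributions ------------------
# Compact typing; values follow the published additive-contribution scheme
# for the common organic subset.
.crippen <- list(
  C.sp3    = c(logp =  0.1441, mr = 2.503),
  C.sp3.X  = c(logp = -0.2035, mr = 2.753),
  C.sp2    = c(logp =  0.1551, mr = 3.513),
  C.sp     = c(logp =  0.1333, mr = 3.625),
  C.X2     = c(logp = -0.2783, mr = 5.007),
  C.ar.H   = c(logp =  0.1581, mr = 3.350),
  C.ar.C   = c(logp =  0.1360, mr = 3.904),
  C.ar.X   = c(logp = -0.0548, mr = 3.846),
  N.sp3    = c(logp = -0.7096, mr = 2.262),
  N.sp2    = c(logp = -0.2744, mr = 2.400),
  N.am     = c(logp = -0.4458, mr = 2.710),
  N.ar     = c(logp = -0.3239, mr = 2.202),
  O.OH     = c(logp = -0.2893, mr = 0.824),
  O.ether  = c(logp = -0.0684, mr = 1.080),
  O.2      = c(logp = -0.1526, mr = 1.800),
  S        = c(logp =  0.6482, mr = 7.591),
  P        = c(logp =  0.8612, mr = 6.920),
  F        = c(logp =  0.4202, mr = 0.890),
  Cl       = c(logp =  0.6895, mr = 5.853),
  Br       = c(logp =  0.8456, mr = 8.927),
  I        = c(logp =  0.8857, mr = 14.020),
  H.C      = c(logp =  0.1230, mr = 1.057),
  H.X      = c(logp = -0.2677, mr = 1.395),
  other    = c(logp =  0.0000, mr = 3.000)
)

.hetero <- function(el) !(el %in% c("C", "H"))

# Type each heavy atom for the contribution lookup.
crippen_types <- function(mol) {
  el <- mol$atoms$element
  arom <- mol$atoms$aromatic
  adj <- mol_adjacency(mol)
  hyb <- atom_hybridization(mol)
  nh <- mol_implicit_h(mol)
  has_double_X <- rep(FALSE, mol_natoms(mol))
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[i] >= 2L && mol$bonds$order[i] != 4L) {
        a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
        if (.hetero(el[b])) has_double_X[a] <- TRUE
        if (.hetero(el[a])) has_double_X[b] <- TRUE
      }
    }
  }
  vapply(seq_along(el), function(i) {
    nbr <- el[adj[[i]]]
    switch(el[i],
      C = {
        if (arom[i]) {
          if (any(.hetero(nbr))) "C.ar.X"
          else if (nh[i] > 0L) "C.ar.H"
          else "C.ar.C"
        } else if (has_double_X[i]) "C.X2"
        else if (hyb[i] == 1L) "C.sp"
        else if (hyb[i] == 2L) "C.sp2"
        else if (any(.hetero(nbr))) "C.sp3.X"
        else "C.sp3"
      },
      N = {
        if (arom[i]) "N.ar"
        else if (any(vapply(adj[[i]], function(j) el[j] == "C" && has_double_X[j], TRUE))) "N.am"
        else if (hyb[i] <= 2L) "N.sp2"
        else "N.sp3"
      },
      O = {
        if (hyb[i] <= 2L && !arom[i] && length(adj[[i]]) == 1L) "O.2"
        else if (length(adj[[i]]) >= 2L || arom[i]) "O.ether"
        else "O.OH"
      },
      S = "S", P = "P", F = "F", Cl = "Cl", Br = "Br", I = "I",
      "other")
  }, "")
}

# 3 = sp3, 2 = sp2 (double/aromatic), 1 = sp (triple or two doubles)
atom_hybridization <- function(mol) {
  n <- mol_natoms(mol)
  ndouble <- integer(n); ntriple <- integer(n); narom <- integer(n)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]; o <- mol$bonds$order[i]
      if (o == 2L) { ndouble[a] <- ndouble[a] + 1L; ndouble[b] <- ndouble[b] + 1L }
      if (o == 3L) { ntriple[a] <- ntriple[a] + 1L; ntriple[b] <- ntriple[b] + 1L }
      if (o == 4L) { narom[a] <- narom[a] + 1L; narom[b] <- narom[b] + 1L }
    }
  }
  hyb <- rep(3L, n)
  hyb[ndouble >= 1L | narom >= 1L | mol$atoms$aromatic] <- 2L
  hyb[ntriple >= 1L | ndouble >= 2L] <- 1L
  hyb
}

crippen_contrib <- function(types, what = "logp") {
  vapply(types, function(t) .crippen[[t]][[what]], 0)
}

# -- PEOE (Gasteiger-style) partial charges ---------------------------------
# (a, b, c) electronegativity polynomial coefficients per element and
# hybridization; six damped relaxation sweeps (damping 0.5^k), which is fixed
# for determinism.
.peoe_params <- function(el, hyb) {
  key <- paste0(el, ".", hyb)
  tbl <- list(
    "H.3" = c(7.17, 6.24, -0.56), "H.2" = c(7.17, 6.24, -0.56), "H.1" = c(7.17, 6.24, -0.56),
    "C.3" = c(7.98, 9.18, 1.88), "C.2" = c(8.79, 9.32, 1.51), "C.1" = c(10.39, 9.45, 0.73),
    "N.3" = c(11.54, 10.82, 1.36), "N.2" = c(12.87, 11.15, 0.85), "N.1" = c(15.68, 11.70, -0.27),
    "O.3" = c(14.18, 12.92, 1.39), "O.2" = c(17.07, 13.79, 0.47), "O.1" = c(17.07, 13.79, 0.47),
    "S.3" = c(10.14, 9.13, 1.38), "S.2" = c(10.14, 9.13, 1.38), "S.1" = c(10.14, 9.13, 1.38),
    "P.3" = c(8.90, 8.24, 0.96), "P.2" = c(8.90, 8.24, 0.96), "P.1" = c(8.90, 8.24, 0.96),
    "F.3" = c(14.66, 13.85, 2.31), "Cl.3" = c(11.00, 9.69, 1.35),
    "Br.3" = c(10.08, 8.47, 1.16), "I.3" = c(9.90, 7.96, 0.96)
  )
  p <- tbl[[key]]
  if (is.null(p)) p <- tbl[[paste0(el, ".3")]]
  if (is.null(p)) p <- c(7.98, 9.18, 1.88)
  p
}

# Returns list(heavy = charges on heavy atoms, all = charges incl. implicit H)
peoe_charges <- function(mol, sweeps = 6L) {
  nheavy <- mol_natoms(mol)
  hyb <- atom_hybridization(mol)
  nh <- mol_implicit_h(mol)
  el <- mol$atoms$element
  # expand implicit hydrogens into explicit pseudo-atoms
  elements <- c(el, rep("H", sum(nh)))
  hybs <- c(hyb, rep(3L, sum(nh)))
  edges <- cbind(mol$bonds$a1, mol$bonds$a2)
  hidx <- nheavy
  for (i in seq_len(nheavy)) {
    if (nh[i] > 0L) for (k in seq_len(nh[i])) {
      hidx <- hidx + 1L
      edges <- rbind(edges, c(i, hidx))
    }
  }
  n <- length(elements)
  par <- t(vapply(seq_len(n), function(i) .peoe_params(elements[i], hybs[i]), numeric(3)))
  chi_plus <- ifelse(elements == "H", 20.02, rowSums(par))
  q <- as.numeric(mol$atoms$charge)
  q <- c(q, rep(0, n - nheavy))
  if (length(edges)) {
    for (k in seq_len(sweeps)) {
      chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
      damp <- 0.5^k
      dq <- numeric(n)
      for (e in seq_len(nrow(edges))) {
        i <- edges[e, 1]; j <- edges[e, 2]
        if (chi[j] > chi[i]) {
          d <- (chi[j] - chi[i]) / chi_plus[i] * damp
          dq[i] <- dq[i] + d; dq[j] <- dq[j] - d
        } else {
          d <- (chi[i] - chi[j]) / chi_plus[j] * damp
          dq[j] <- dq[j] + d; dq[i] <- dq[i] - d
        }
      }
      q <- q + dq
    }
  }
  list(heavy = q[seq_len(nheavy)], all = q)
}

# -- approximate van der Waals surface areas --------------------------------
.bondi  <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Cl = 1.75,
             Br = 1.85, I = 1.98, S = 1.80, P = 1.80, B = 1.92)
.covrad <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, Cl = 1.02,
             Br = 1.20, I = 1.39, S = 1.05, P = 1.07, B = 0.84)

.radius <- function(el, tbl) { r <- tbl[el]; r[is.na(r)] <- tbl[["C"]]; unname(r) }

# Sphere area minus one spherical cap per neighbour (heavy and implicit H),
# with idealized bond lengths from covalent radii.
atom_vsa <- function(mol) {
  el <- mol$atoms$element
  rv <- .radius(el, .bondi)
  rc <- .radius(el, .covrad)
  nh <- mol_implicit_h(mol)
  area <- 4 * pi * rv^2
  cap <- function(i, rj, rcj, order = 1L) {
    d <- rc[i] + rcj - 0.07 * (min(order, 3L) - 1L)
    h <- rv[i] - (d^2 + rv[i]^2 - rj^2) / (2 * d)
    min(max(h, 0), 2 * rv[i]) * 2 * pi * rv[i]
  }
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]; o <- mol$bonds$order[b]
      area[i] <- area[i] - cap(i, rv[j], rc[j], o)
      area[j] <- area[j] - cap(j, rv[i], rc[i], o)
    }
  }
  for (i in seq_along(el)) if (nh[i] > 0L)
    area[i] <- area[i] - nh[i] * cap(i, .bondi[["H"]], .covrad[["H"]])
  pmax(area, 0)
}

#' Compute the general (physicochemical) descriptor vector
#'
#' Additive-atomic-contribution logP and molar refractivity, molecular
#' weight, approximate van der Waals surface area (total and partitioned by
#' per-atom logP, molar-refractivity and partial-charge bins), and summary
#' statistics of PEOE partial charges (computed over all atoms including
#' implicit hydrogens).
#'
#' @param mol A `bq_mol`.
#' @return A named numeric vector (19 descriptors).
#' @export
compute_general_descriptors <- function(mol) {
  if (mol_natoms(mol) == 0L) stop("empty molecule")
  types <- crippen_types(mol)
  nh <- mol_implicit_h(mol)
  htype <- ifelse(.hetero(mol$atoms$element), "H.X", "H.C")
  logp_atom <- crippen_contrib(types, "logp")
  mr_atom <- crippen_contrib(types, "mr")
  logp <- sum(logp_atom) + sum(nh * vapply(htype, function(t) .crippen[[t]][["logp"]], 0))
  mr <- sum(mr_atom) + sum(nh * vapply(htype, function(t) .crippen[[t]][["mr"]], 0))
  q <- peoe_charges(mol)
  vsa <- atom_vsa(mol)
  bin_sum <- function(x, breaks) {
    idx <- findInterval(x, breaks, left.open = TRUE) + 1L
    vapply(seq_len(length(breaks) + 1L), function(b) sum(vsa[idx == b]), 0)
  }
  slogp_vsa <- bin_sum(logp_atom, c(-0.2, 0.05, 0.15))
  smr_vsa <- bin_sum(mr_atom, c(2.6, 3.6))
  peoe_vsa <- bin_sum(q$heavy, c(-0.05, 0, 0.05))
  c(logp = logp, mr = mr, mw = mol_weight(mol),
    vsa_total = sum(vsa),
    setNames(slogp_vsa, paste0("slogp_vsa", 1:4)),
    setNames(smr_vsa, paste0("smr_vsa", 1:3)),
    setNames(peoe_vsa, paste0("peoe_vsa", 1:4)),
    q_pos = sum(q$all[q$all > 0]), q_neg = sum(q$all[q$all < 0]),
    q_min = if (length(q$all)) min(q$all) else 0,
    q_max = if (length(q$all)) max(q$all) else 0)
}

#' Compute the drug-like-index (topological) descriptor vector
#'
#' Characterizes the structural hierarchy of a molecule: number of rings
#' (cyclomatic count), ring atoms, fused ring systems, linker atoms (acyclic
#' atoms on paths between ring systems), framework size (ring systems plus
#' linkers, obtained by iteratively pruning terminal atoms), side-chain atom
#' counts split by element class, and a scalar drug-like index combining
#' them.
#'
#' @param mol A `bq_mol`.
#' @return A named numeric vector (11 descriptors).
#' @export
compute_drug_like_index <- function(mol) {
  n <- mol_natoms(mol)
  if (n == 0L) stop("empty molecule")
  g <- mol_graph(mol)
  ncomp <- igraph::components(g)$no
  n_rings <- nrow(mol$bonds) - n + ncomp
  ringb <- mol_ring_bonds(mol)
  ring_atoms <- sort(unique(c(mol$bonds$a1[ringb], mol$bonds$a2[ringb])))
  n_ring_systems <- if (length(ring_atoms)) {
    rg <- igraph::make_empty_graph(n = length(ring_atoms), directed = FALSE)
    idx <- match(seq_len(n), ring_atoms)
    if (length(ringb))
      rg <- igraph::add_edges(rg, rbind(idx[mol$bonds$a1[ringb]], idx[mol$bonds$a2[ringb]]))
    igraph::components(rg)$no
  } else 0L
  # framework: iteratively strip degree-1 vertices; what survives is the
  # union of ring systems and linkers (empty for acyclic molecules)
  keep <- rep(TRUE, n)
  deg <- mol_degree(mol)
  adj <- mol_adjacency(mol)
  repeat {
    leaves <- which(keep & deg <= 1L)
    if (!length(leaves)) break
    keep[leaves] <- FALSE
    for (v in leaves) for (w in adj[[v]]) if (keep[w]) deg[w] <- deg[w] - 1L
    deg[leaves] <- 0L
  }
  framework <- which(keep)
  linkers <- setdiff(framework, ring_atoms)
  side <- setdiff(seq_len(n), framework)
  el <- mol$atoms$element
  dli <- 2 * n_rings + n_ring_systems + 0.5 * length(linkers) +
    0.1 * length(framework) + 0.05 * length(side)
  c(n_atoms = n,
    n_heteroatoms = sum(.hetero(el)),
    n_rings = n_rings,
    n_ring_atoms = length(ring_atoms),
    n_ring_systems = n_ring_systems,
    n_linker_atoms = length(linkers),
    framework_size = length(framework),
    n_sidechain_atoms = length(side),
    n_sidechain_carbon = sum(el[side] == "C"),
    n_sidechain_hetero = sum(.hetero(el[side])),
    dli = dli)
}

#' Build a descriptor matrix for a library
#'
#' Rows follow library record order; compounds whose descriptor computation
#' fails are excluded and reported in the `failures` field.
#'
#' @param library A `bq_library`.
#' @param set_tag `"general"` or `"drug_like_index"`.
#' @return A `bq_descmat`: list with `ids`, `values` (compounds x
#'   descriptors matrix), `set_tag`, `failures`.
#' @export
build_matrix <- function(library, set_tag = c("general", "drug_like_index")) {
  set_tag <- match.arg(set_tag)
  if (!length(library$records)) stop("empty library", call. = FALSE)
  fun <- if (set_tag == "general") compute_general_descriptors else compute_drug_like_index
  rows <- list(); ids <- character(); failures <- character()
  for (r in library$records) {
    v <- tryCatch(fun(r$molecule), error = function(e) e)
    if (inherits(v, "error")) {
      failures <- c(failures, sprintf("%s: %s", r$molecule$id, conditionMessage(v)))
    } else {
      rows[[length(rows) + 1L]] <- v
      ids <- c(ids, r$molecule$id)
    }
  }
  if (!length(rows))
    stop("descriptor computation failed for every compound", call. = FALSE)
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  if (anyNA(values)) stop("NaN/NA in descriptor matrix", call. = FALSE)
  structure(list(ids = ids, values = values, set_tag = set_tag,
                 failures = failures), class = "bq_descmat")
}

#' @export
print.bq_descmat <- function(x, ...) {
  cat(sprintf("<bq_descmat [%s]: %d compounds x %d descriptors>\n",
              x$set_tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Z-score a descriptor matrix
#'
#' Columns are centered and scaled to unit population (root-mean-square)
#' standard deviation on the full library (division by max-min distance
#' must see all compounds), so a two-value column \{1, 3\} maps to
#' \{-1, +1\}. Zero-variance columns cannot enter a distance computation
#' and are dropped with a warning.
#'
#' @param mat A `bq_descmat` or plain numeric matrix.
#' @return List with `matrix` (normalized values) and `normalization`
#'   (per-column center/scale plus names of dropped columns).
#' @export
normalize_descriptors <- function(mat) {
  values <- if (inherits(mat, "bq_descmat")) mat$values else as.matrix(mat)
  if (nrow(values) < 2L) stop("need at least 2 rows to normalize", call. = FALSE)
  ctr <- colMeans(values)
  scl <- sqrt(colMeans(sweep(values, 2, ctr)^2))
  keep <- scl > 1e-12
  if (!any(keep)) stop("all descriptor columns have zero variance", call. = FALSE)
  dropped <- colnames(values)[!keep]
  if (length(dropped))
    warning("dropping zero-variance descriptor columns: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  z <- sweep(sweep(values[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  list(matrix = z,
       normalization = list(center = ctr[keep], scale = scl[keep],
                            dropped = dropped, method = "zscore"))
}

#' Write a descriptor matrix to CSV (first column = compound id)
#' @param mat A `bq_descmat`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_descriptors <- function(mat, path) {
  df <- data.frame(id = mat$ids, mat$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor matrix from CSV written by [write_descriptors()]
#' @param path CSV path.
#' @param set_tag Descriptor-set tag to attach.
#' @return A `bq_descmat`.
#' @export
read_descriptors <- function(path, set_tag = "general") {
  df <- utils::read.csv(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  structure(list(ids = df[[1]], values = values, set_tag = set_tag,
                 failures = character()), class = "bq_descmat")
}
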