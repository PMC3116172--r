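# Scaffold matching and R-group decomposition. A scaffold is a connected
# core graph with numbered attachment positions; a compound matches when the
# core embeds as an induced subgraph (element- and bond-order-exact) and
# every non-core atom belongs to a fragment hanging off exactly one declared
# position. Subgraph embedding is solved by igraph's LAD algorithm with
# element-restricted candidate domains.

#' Define a scaffold
#'
#' @param id Scaffold identifier.
#' @param atoms,bonds Core graph in [molecule()] format; must be connected.
#' @param positions Named integer vector: names are position labels (e.g.
#'   `"8"`), values are core atom indices where substituents may attach.
#' @return A `bq_scaffold`.
#' @export
scaffold <- function(id, atoms, bonds, positions) {
  core <- molecule(id, atoms, bonds)
  if (igraph::components(mol_graph(core))$no != 1L)
    stop("scaffold core must be connected", call. = FALSE)
  positions <- stats::setNames(as.integer(positions), names(positions))
  if (anyDuplicated(positions) || is.null(names(positions)))
    stop("positions must be distinct, named atom indices", call. = FALSE)
  if (any(positions < 1L | positions > mol_natoms(core)))
    stop("position index outside the core", call. = FALSE)
  structure(list(id = id, core = core, positions = positions),
            class = "bq_scaffold")
}

#' @export
print.bq_scaffold <- function(x, ...) {
  cat(sprintf("<bq_scaffold %s: %d core atoms, positions %s>\n",
              x$id, mol_natoms(x$core), paste(names(x$positions), collapse = ",")))
  invisible(x)
}

# fragment: list(atoms, bonds, attach) in molecule() format; NULL encodes H
fragment_key <- function(frag) {
  if (is.null(frag)) return("H")
  extra <- rep(0L, nrow(frag$atoms)); extra[frag$attach] <- 1L
  graph_key(frag$atoms$element, frag$bonds, extra_color = extra)
}

fragment_name <- function(frag) {
  if (is.null(frag)) return("H")
  el <- frag$atoms$element
  n <- length(el)
  if (n == 1L)
    return(switch(el, C = "methyl", O = "hydroxyl", N = "amino",
                  F = "fluoro", Cl = "chloro", Br = "bromo", I = "iodo",
                  paste0(el, "-group")))
  if (n == 2L && all(el == "C")) return("ethyl")
  if (n == 3L && all(el == "C")) {
    deg <- tabulate(c(frag$bonds$a1, frag$bonds$a2), nbins = 3L)
    return(if (deg[frag$attach] == 2L) "isopropyl" else "propyl")
  }
  if (n == 2L && sort(el)[1] == "C" && sort(el)[2] == "O")
    return(if (el[frag$attach] == "O") "methoxy" else "hydroxymethyl")
  paste0("frag-", paste(sort(el), collapse = ""))
}

# First embedding of the scaffold core in mol that admits a valid R-group
# partition, or NULL. Returns list(map, rgroups) where rgroups is a list
# keyed by position label (NULL entries = hydrogen).
find_scaffold_embedding <- function(mol, sc) {
  core <- sc$core
  nc <- mol_natoms(core); nm <- mol_natoms(mol)
  if (nm < nc) return(NULL)
  tab_m <- table(mol$atoms$element); tab_c <- table(core$atoms$element)
  if (any(is.na(tab_m[names(tab_c)]) | tab_m[names(tab_c)] < tab_c)) return(NULL)
  gm <- mol_graph(mol); gc <- mol_graph(core)
  domains <- lapply(seq_len(nc), function(v)
    which(mol$atoms$element == core$atoms$element[v] &
          mol$atoms$charge == core$atoms$charge[v]))
  if (any(!lengths(domains))) return(NULL)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(pattern = gc, target = gm, method = "lad",
                                  induced = TRUE, domains = domains),
    error = function(e) list())
  bond_order_of <- function(a, b) {
    hit <- which((mol$bonds$a1 == a & mol$bonds$a2 == b) |
                 (mol$bonds$a1 == b & mol$bonds$a2 == a))
    if (length(hit)) mol$bonds$order[hit[1]] else NA_integer_
  }
  for (mp in maps) {
    map <- as.integer(mp)
    # exact bond orders on the core
    ok <- TRUE
    for (e in seq_len(nrow(core$bonds))) {
      o <- bond_order_of(map[core$bonds$a1[e]], map[core$bonds$a2[e]])
      if (is.na(o) || o != core$bonds$order[e]) { ok <- FALSE; break }
    }
    if (!ok) next
    rest <- setdiff(seq_len(nm), map)
    rgroups <- stats::setNames(vector("list", length(sc$positions)),
                               names(sc$positions))
    if (length(rest)) {
      sub <- igraph::induced_subgraph(gm, rest)
      comp <- igraph::components(sub)$membership
      for (ci in seq_len(max(comp))) {
        members <- rest[comp == ci]
        # bonds from this fragment into the core
        links <- which((mol$bonds$a1 %in% members & mol$bonds$a2 %in% map) |
                       (mol$bonds$a2 %in% members & mol$bonds$a1 %in% map))
        if (length(links) != 1L) { ok <- FALSE; break }
        if (mol$bonds$order[links] != 1L) { ok <- FALSE; break }
        core_atom <- if (mol$bonds$a1[links] %in% map) mol$bonds$a1[links] else mol$bonds$a2[links]
        frag_atom <- if (core_atom == mol$bonds$a1[links]) mol$bonds$a2[links] else mol$bonds$a1[links]
        pos_idx <- which(sc$positions == which(map == core_atom))
        if (!length(pos_idx)) { ok <- FALSE; break }
        lab <- names(sc$positions)[pos_idx]
        if (!is.null(rgroups[[lab]])) { ok <- FALSE; break }  # one fragment per position
        sel <- match(members, members)
        fa <- mol$atoms[members, , drop = FALSE]
        rownames(fa) <- NULL
        fb <- mol$bonds[mol$bonds$a1 %in% members & mol$bonds$a2 %in% members, ,
                        drop = FALSE]
        fb$a1 <- match(fb$a1, members); fb$a2 <- match(fb$a2, members)
        rownames(fb) <- NULL
        rgroups[[lab]] <- list(atoms = fa, bonds = fb,
                               attach = match(frag_atom, members))
      }
    }
    if (ok) return(list(map = map, rgroups = rgroups))
  }
  NULL
}

#' Match a library against a prioritized scaffold list
#'
#' Each compound is assigned to the first scaffold (in list order) whose
#' core embeds with a valid R-group partition; compounds matching no
#' scaffold are reported as unmatched — a normal outcome, not an error.
#'
#' @param library A `bq_library`.
#' @param scaffolds List of `bq_scaffold` in priority order.
#' @return A `bq_matchset`: list with `matches` (per matched compound:
#'   compound id, scaffold id, position -> fragment map) and `unmatched`
#'   (ids).
#' @export
match_scaffolds <- function(library, scaffolds) {
  if (!length(scaffolds)) stop("scaffold set is empty", call. = FALSE)
  matches <- list(); unmatched <- character()
  for (rec in library$records) {
    mol <- rec$molecule
    hit <- NULL
    for (sc in scaffolds) {
      emb <- find_scaffold_embedding(mol, sc)
      if (!is.null(emb)) {
        hit <- list(id = mol$id, scaffold = sc$id, rgroups = emb$rgroups)
        break
      }
    }
    if (is.null(hit)) unmatched <- c(unmatched, mol$id)
    else matches[[mol$id]] <- hit
  }
  structure(list(matches = matches, unmatched = unmatched),
            class = "bq_matchset")
}

#' @export
print.bq_matchset <- function(x, ...) {
  cat(sprintf("<bq_matchset: %d matched, %d unmatched>\n",
              length(x$matches), length(x$unmatched)))
  invisible(x)
}

#' Reassemble a molecule from a scaffold and an R-group map
#'
#' @param sc A `bq_scaffold`.
#' @param rgroups List keyed by position label; each entry a fragment
#'   (`atoms`, `bonds`, `attach`) or `NULL` for hydrogen.
#' @param id Identifier for the assembled molecule.
#' @return A `bq_mol` whose graph is the core plus the attached fragments.
#' @export
reassemble <- function(sc, rgroups, id = "chimera") {
  atoms <- sc$core$atoms
  bonds <- sc$core$bonds
  for (lab in names(rgroups)) {
    frag <- rgroups[[lab]]
    if (is.null(frag)) next
    offset <- nrow(atoms)
    atoms <- rbind(atoms, frag$atoms)
    if (nrow(frag$bonds))
      bonds <- rbind(bonds, data.frame(a1 = frag$bonds$a1 + offset,
                                       a2 = frag$bonds$a2 + offset,
                                       order = frag$bonds$order))
    bonds <- rbind(bonds, data.frame(a1 = sc$positions[[lab]],
                                     a2 = frag$attach + offset, order = 1L))
  }
  molecule(id, atoms, bonds)
}
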