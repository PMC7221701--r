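#' Molecular graph objects
#'
#' A `qf_molecule` is a light-weight attributed graph: a data frame of atoms
#' (element, formal charge, implicit hydrogen count, optional 3D coordinates
#' and partial charges) plus a data frame of bonds (atom indices and bond
#' order, with aromatic bonds flagged). It is the substrate for every
#' descriptor in the package. Topological descriptors operate on the
#' hydrogen-suppressed graph; constitutional and information-content
#' descriptors on the hydrogen-filled graph (implicit hydrogens are
#' materialized on demand, see [hydrogen_filled_graph()]).
#'
#' @param id compound identifier.
#' @param elements character vector of element symbols, one per heavy (or
#'   explicit) atom, in input order.
#' @param bonds data frame with integer columns `a1`, `a2` and numeric
#'   `order` (1, 2, 3) plus logical `aromatic`. Aromatic bonds carry numeric
#'   order 1.5 wherever a number is required.
#' @param formal_charge integer vector of formal charges (e), recycled 0.
#' @param explicit_h integer vector of hydrogen counts fixed by the input
#'   (e.g. bracket atoms in SMILES), or `NA` to assign by valence rules.
#' @param coords optional numeric matrix (n x 3) of Cartesian coordinates in
#'   Angstrom.
#' @param partial_charge optional numeric vector of atomic partial charges.
#'
#' @return an object of class `qf_molecule`.
#' @export
new_molecule <- function(id, elements, bonds,
                         formal_charge = 0L,
                         explicit_h = NA_integer_,
                         coords = NULL,
                         partial_charge = NULL) {
  n <- length(elements)
  if (n == 0L) stop("molecule needs at least one atom", call. = FALSE)
  .element_row(elements) # validates symbols
  formal_charge <- rep_len(as.integer(formal_charge), n)
  explicit_h <- rep_len(as.integer(explicit_h), n)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(),
                        order = numeric(), aromatic = logical())
  }
  stopifnot(all(c("a1", "a2", "order") %in% names(bonds)))
  if (is.null(bonds$aromatic)) bonds$aromatic <- bonds$order == 1.5
  bonds$a1 <- as.integer(bonds$a1)
  bonds$a2 <- as.integer(bonds$a2)
  if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n)) {
    stop("bond endpoint outside atom range", call. = FALSE)
  }
  if (any(bonds$a1 == bonds$a2)) stop("self-loop bond", call. = FALSE)
  key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
  if (anyDuplicated(key)) stop("duplicate bond", call. = FALSE)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 3L)
  }
  if (!is.null(partial_charge)) {
    partial_charge <- rep_len(as.numeric(partial_charge), n)
  }
  atoms <- data.frame(
    element = elements,
    atomic_number = atomic_number(elements),
    formal_charge = formal_charge,
    implicit_h = 0L,
    stringsAsFactors = FALSE
  )
  mol <- structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         coords = coords, partial_charge = partial_charge),
    class = "qf_molecule"
  )
  mol$atoms$implicit_h <- .assign_implicit_h(mol, explicit_h)
  mol
}

# Implicit hydrogen count per atom from standard valence rules: the smallest
# allowed (charge-adjusted) valence >= ceil(sum of bond orders) is filled up
# with hydrogens. Atoms with an explicit H count keep it.
.assign_implicit_h <- function(mol, explicit_h) {
  n <- nrow(mol$atoms)
  bsum <- numeric(n)
  if (nrow(mol$bonds)) {
    ord <- ifelse(mol$bonds$aromatic, 1.5, mol$bonds$order)
    for (i in seq_len(nrow(mol$bonds))) {
      bsum[mol$bonds$a1[i]] <- bsum[mol$bonds$a1[i]] + ord[i]
      bsum[mol$bonds$a2[i]] <- bsum[mol$bonds$a2[i]] + ord[i]
    }
  }
  vapply(seq_len(n), function(i) {
    if (!is.na(explicit_h[i])) return(explicit_h[i])
    vs <- .allowed_valences(mol$atoms$element[i], mol$atoms$formal_charge[i])
    need <- ceiling(bsum[i] - 1e-9)
    fit <- vs[vs >= need]
    if (!length(fit)) {
      stop(sprintf("valence violation at atom %d (%s): bond order sum %.1f",
                   i, mol$atoms$element[i], bsum[i]), call. = FALSE)
    }
    as.integer(fit[1] - need)
  }, integer(1))
}

#' @export
print.qf_molecule <- function(x, ...) {
  cat(sprintf("<qf_molecule %s: %d heavy atoms, %d bonds, formula %s>\n",
              x$id, heavy_atom_count(x), nrow(x$bonds),
              molecular_formula(x)))
  invisible(x)
}

#' Number of non-hydrogen atoms
#'
#' Heavy-atom count is the denominator of ligand efficiency and the atom
#' count of all hydrogen-suppressed topological descriptors.
#'
#' @param mol a `qf_molecule`.
#' @return integer count of non-hydrogen atoms.
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "qf_molecule"))
  sum(mol$atoms$element != "H")
}

#' Molecular weight
#'
#' Sum of standard atomic masses over all atoms including implicit hydrogens.
#'
#' @param mol a `qf_molecule`.
#' @return molecular weight in Da.
#' @export
molecular_weight <- function(mol) {
  stopifnot(inherits(mol, "qf_molecule"))
  sum(atomic_mass(mol$atoms$element)) +
    sum(mol$atoms$implicit_h) * atomic_mass("H")
}

#' Total atom count including implicit hydrogens
#' @param mol a `qf_molecule`.
#' @return integer atom count of the hydrogen-filled graph.
#' @export
total_atom_count <- function(mol) {
  nrow(mol$atoms) + sum(mol$atoms$implicit_h)
}

#' Hydrogen-bond donor and acceptor counts
#'
#' Uses the dominant convention: donors are hydrogens on nitrogen or oxygen,
#' acceptors are the nitrogen and oxygen atoms themselves.
#'
#' @param mol a `qf_molecule`.
#' @return named integer vector `c(donors =, acceptors =)`.
#' @export
hbond_counts <- function(mol) {
  stopifnot(inherits(mol, "qf_molecule"))
  no <- mol$atoms$element %in% c("N", "O")
  donors <- sum(mol$atoms$implicit_h[no])
  # explicit hydrogen atoms bonded to N/O
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
      ea <- mol$atoms$element[a]; eb <- mol$atoms$element[b]
      if (ea == "H" && eb %in% c("N", "O")) donors <- donors + 1L
      if (eb == "H" && ea %in% c("N", "O")) donors <- donors + 1L
    }
  }
  c(donors = as.integer(donors), acceptors = as.integer(sum(no)))
}

#' Molecular formula in Hill order
#' @param mol a `qf_molecule`.
#' @return character scalar, e.g. `"C2H6O"`.
#' @export
molecular_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  h <- sum(mol$atoms$implicit_h) + sum(mol$atoms$element == "H")
  counts <- counts[names(counts) != "H"]
  parts <- character()
  fmt <- function(sym, k) if (k == 1L) sym else paste0(sym, k)
  if ("C" %in% names(counts)) {
    parts <- c(parts, fmt("C", counts[["C"]]))
    counts <- counts[names(counts) != "C"]
    if (h > 0) parts <- c(parts, fmt("H", h))
    for (s in sort(names(counts))) parts <- c(parts, fmt(s, counts[[s]]))
  } else {
    all_c <- counts
    if (h > 0) all_c <- c(all_c, H = h)
    for (s in sort(names(all_c))) parts <- c(parts, fmt(s, all_c[[s]]))
  }
  paste(parts, collapse = "")
}

# Hydrogen-suppressed graph as an igraph object; vertex attribute `aidx`
# maps back to atom indices in the molecule.
.heavy_graph <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  map <- integer(nrow(mol$atoms)); map[heavy] <- seq_along(heavy)
  b <- mol$bonds
  keep <- b$a1 %in% heavy & b$a2 %in% heavy
  el <- cbind(map[b$a1[keep]], map[b$a2[keep]])
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  igraph::set_vertex_attr(g, "aidx", value = heavy)
}

#' Topological distance matrix
#'
#' Shortest path lengths, in bonds, between all pairs of heavy atoms of the
#' hydrogen-suppressed graph. The matrix underlies the Balaban index and the
#' Kier shape indices.
#'
#' @param mol a `qf_molecule` whose heavy-atom graph is connected.
#' @return symmetric integer matrix with zero diagonal.
#' @export
topo_distance_matrix <- function(mol) {
  g <- .heavy_graph(mol)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    stop(sprintf(
      "disconnected heavy-atom graph (%d components; sizes %s)",
      comp$no, paste(comp$csize, collapse = ", ")), call. = FALSE)
  }
  d <- igraph::distances(g)
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

# Neighbor list of the hydrogen-filled graph: implicit hydrogens are
# materialized as extra atoms bonded by single bonds to their parent.
hydrogen_filled_graph <- function(mol) {
  n <- nrow(mol$atoms)
  elements <- mol$atoms$element
  edges <- if (nrow(mol$bonds)) {
    data.frame(a1 = mol$bonds$a1, a2 = mol$bonds$a2,
               order = ifelse(mol$bonds$aromatic, 1.5, mol$bonds$order))
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = numeric())
  }
  nh <- mol$atoms$implicit_h
  for (i in seq_len(n)) {
    if (nh[i] > 0L) {
      newidx <- length(elements) + seq_len(nh[i])
      elements <- c(elements, rep("H", nh[i]))
      edges <- rbind(edges, data.frame(a1 = i, a2 = newidx, order = 1))
    }
  }
  list(elements = elements, edges = edges)
}
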