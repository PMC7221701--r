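#' @title Topological and constitutional molecular descriptors
#' @description Descriptor families computed solely from the molecular
#'   graph: Kier shape indices and the Balaban index on the
#'   hydrogen-suppressed graph, information-content indices and
#'   constitutional descriptors on the hydrogen-filled graph, and
#'   Sanderson-electronegativity (Zefirov) partial charges. Quantum-chemical
#'   (AM1-type) descriptors are never computed here; they are ingested as
#'   external columns via [attach_external_descriptors()].
#' @name descriptors
NULL

# condition for descriptors that are undefined for a given structure
# (e.g. kappa3 on a molecule with no length-3 path); the descriptor-matrix
# builder stores these as NA rather than imputing zero
descriptor_undefined <- function(msg) {
  stop(structure(class = c("qf_descriptor_undefined", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.adjacency <- function(mol) {
  g <- .heavy_graph(mol)
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

#' Kier shape index
#'
#' Kappa shape descriptors of the hydrogen-suppressed graph, from the heavy
#' atom count A and the number P_m of paths with m bonds:
#' kappa1 = A(A-1)^2/P1^2, kappa2 = (A-1)(A-2)^2/P2^2, and
#' kappa3 = (A-1)(A-3)^2/P3^2 for odd A, (A-3)(A-2)^2/P3^2 for even A.
#'
#' @param mol a `qf_molecule`.
#' @param order path length m, 1, 2 or 3.
#' @return the kappa value; an error of class `qf_descriptor_undefined` is
#'   raised when no path of the requested length exists.
#' @export
kier_shape_index <- function(mol, order = 3L) {
  stopifnot(order %in% 1:3)
  adj <- .adjacency(mol)
  a <- nrow(adj)
  deg <- rowSums(adj)
  p <- switch(order,
    sum(adj) / 2,
    sum(deg * (deg - 1)) / 2,
    {
      tri <- sum(diag(adj %*% adj %*% adj)) / 6
      s <- 0
      idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
      if (nrow(idx)) {
        s <- sum((deg[idx[, 1]] - 1) * (deg[idx[, 2]] - 1))
      }
      s - 3 * tri
    })
  if (p <= 0) {
    descriptor_undefined(sprintf("no path of length %d; kappa%d undefined",
                                 order, order))
  }
  switch(order,
    a * (a - 1)^2 / p^2,
    (a - 1) * (a - 2)^2 / p^2,
    if (a %% 2 == 1) (a - 1) * (a - 3)^2 / p^2 else (a - 3) * (a - 2)^2 / p^2)
}

#' Balaban distance-connectivity index J
#'
#' J = q/(mu+1) * sum over edges (s_i s_j)^(-1/2), where q is the number of
#' edges of the hydrogen-suppressed graph, mu its cyclomatic number and s_i
#' the i-th row sum of the topological distance matrix. A single-atom
#' molecule returns 0 by convention.
#'
#' @param mol a `qf_molecule` with a connected heavy-atom graph.
#' @return the Balaban index.
#' @export
balaban_index <- function(mol) {
  a <- heavy_atom_count(mol)
  if (a < 2L) return(0)
  d <- topo_distance_matrix(mol)
  adj <- .adjacency(mol)
  q <- sum(adj) / 2
  mu <- q - a + 1
  s <- rowSums(d)
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  q / (mu + 1) * sum(1 / sqrt(s[idx[, 1]] * s[idx[, 2]]))
}

#' Information-content indices
#'
#' Shannon-entropy descriptors over atom equivalence classes of the
#' hydrogen-filled graph. Order-0 classes are element types; higher orders
#' refine classes by the multiset of neighbor classes up to `order`
#' coordination shells. The bonding variant (BIC) augments the neighbor
#' signature with bond orders (aromatic bonds count 1.5). With class
#' frequencies p_c over n atoms: IC = -sum p_c log2 p_c,
#' SIC = IC / log2 n, CIC = log2 n - IC.
#'
#' @param mol a `qf_molecule`.
#' @param variant one of `"IC"`, `"SIC"`, `"BIC"`, `"CIC"`.
#' @param order number of refinement shells, 0, 1 or 2.
#' @return descriptor value in bits (SIC is dimensionless in \[0, 1\]).
#' @export
information_content <- function(mol, variant = c("IC", "SIC", "BIC", "CIC"),
                                order = 0L) {
  variant <- match.arg(variant)
  stopifnot(order %in% 0:2)
  g <- hydrogen_filled_graph(mol)
  n <- length(g$elements)
  if (n == 1L) return(0)
  cls <- .atom_classes(g, order, bonded = variant == "BIC")
  p <- as.numeric(table(cls)) / n
  ic <- -sum(p * log2(p))
  switch(variant,
    IC = ic, BIC = ic,
    SIC = ic / log2(n),
    CIC = log2(n) - ic)
}

# Iterative equivalence-class refinement on a hydrogen-filled graph.
.atom_classes <- function(g, order, bonded = FALSE) {
  n <- length(g$elements)
  nb <- vector("list", n)
  e <- g$edges
  for (k in seq_len(nrow(e))) {
    nb[[e$a1[k]]] <- rbind(nb[[e$a1[k]]], c(e$a2[k], e$order[k]))
    nb[[e$a2[k]]] <- rbind(nb[[e$a2[k]]], c(e$a1[k], e$order[k]))
  }
  cls <- match(g$elements, unique(g$elements))
  for (shell in seq_len(order)) {
    sig <- vapply(seq_len(n), function(i) {
      if (is.null(nb[[i]])) return(sprintf("%d|", cls[i]))
      neigh <- if (bonded) {
        paste(cls[nb[[i]][, 1]], nb[[i]][, 2], sep = ":")
      } else {
        as.character(cls[nb[[i]][, 1]])
      }
      paste0(cls[i], "|", paste(sort(neigh), collapse = ","))
    }, "")
    cls <- match(sig, unique(sig))
  }
  cls
}

#' Constitutional descriptors
#'
#' Simple composition descriptors of the hydrogen-filled molecule: atom and
#' bond counts, element counts, molecular weight, average atomic weight
#' (MW over all atoms including hydrogens) and the cyclomatic ring count.
#'
#' @param mol a `qf_molecule`.
#' @return named numeric vector.
#' @export
constitutional_descriptors <- function(mol) {
  n_tot <- total_atom_count(mol)
  mw <- molecular_weight(mol)
  heavy <- mol$atoms$element != "H"
  nb_heavy <- sum(mol$bonds$a1 %in% which(heavy) &
                    mol$bonds$a2 %in% which(heavy))
  c(
    n_atoms = n_tot,
    n_heavy = heavy_atom_count(mol),
    n_bonds = nrow(mol$bonds) + sum(mol$atoms$implicit_h),
    n_rings = nb_heavy - sum(heavy) + 1,
    MW = mw,
    avg_atom_weight = mw / n_tot,
    n_C = sum(mol$atoms$element == "C"),
    n_N = sum(mol$atoms$element == "N"),
    n_O = sum(mol$atoms$element == "O"),
    n_S = sum(mol$atoms$element == "S"),
    n_halogen = sum(mol$atoms$element %in% c("F", "Cl", "Br", "I"))
  )
}

#' Zefirov (Sanderson electronegativity equalization) partial charges
#'
#' One-shot geometric-mean equalization: with Sanderson electronegativities
#' S_i and molecular electronegativity S_mol = (prod S_i)^(1/n) over the
#' hydrogen-filled atom set, q_i = (S_mol - S_i) / (2.08 sqrt(S_i)). The
#' charges are then shifted uniformly so they sum to the net formal charge.
#'
#' @param mol a `qf_molecule`.
#' @return a `qf_chargeset`: data frame with columns `atom` (index into the
#'   hydrogen-filled atom list; explicit atoms come first), `element`,
#'   `charge`, `parent` (heavy-atom index for materialized hydrogens) and
#'   attribute `scheme = "zefirov"`.
#' @export
zefirov_charges <- function(mol) {
  g <- hydrogen_filled_graph(mol)
  s <- sanderson_en(g$elements)
  smol <- exp(mean(log(s)))
  q <- (smol - s) / (2.08 * sqrt(s))
  net <- sum(mol$atoms$formal_charge)
  q <- q + (net - sum(q)) / length(q)
  n_explicit <- nrow(mol$atoms)
  parent <- rep(NA_integer_, length(q))
  if (length(q) > n_explicit) {
    extra <- g$edges[g$edges$a2 > n_explicit, , drop = FALSE]
    parent[extra$a2] <- extra$a1
  }
  structure(
    data.frame(atom = seq_along(q), element = g$elements, charge = q,
               parent = parent, stringsAsFactors = FALSE),
    scheme = "zefirov", class = c("qf_chargeset", "data.frame"))
}

#' Build a charge set from externally supplied per-atom charges
#'
#' Used to ingest quantum-chemical (e.g. AM1) partial charges computed
#' outside the package for the explicit atoms of a molecule.
#'
#' @param mol a `qf_molecule`.
#' @param charges numeric vector, one value per explicit atom.
#' @return a `qf_chargeset` with `scheme = "external"`.
#' @export
external_charges <- function(mol, charges) {
  n <- nrow(mol$atoms)
  stopifnot(length(charges) == n)
  structure(
    data.frame(atom = seq_len(n), element = mol$atoms$element,
               charge = as.numeric(charges), parent = NA_integer_,
               stringsAsFactors = FALSE),
    scheme = "external", class = c("qf_chargeset", "data.frame"))
}

#' Extremum of partial charge over an element selection
#'
#' @param charges a `qf_chargeset`.
#' @param element element symbol to filter on, or `NULL` for any atom.
#' @param which `"min"` or `"max"`.
#' @return the extremal charge; error of class `qf_descriptor_undefined` if
#'   no atom matches the filter.
#' @export
charge_extrema <- function(charges, element = NULL,
                           which = c("min", "max")) {
  which <- match.arg(which)
  stopifnot(inherits(charges, "qf_chargeset"))
  q <- charges$charge
  if (!is.null(element)) q <- q[charges$element == element]
  if (!length(q)) {
    descriptor_undefined(sprintf("no %s atom for charge extremum",
                                 if (is.null(element)) "?" else element))
  }
  if (which == "min") min(q) else max(q)
}
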