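#' Solvent-accessible surface area by sphere-point sampling
#'
#' Shrake-Rupley style SASA with a deterministic Fibonacci (golden-spiral)
#' point lattice, so results are reproducible for a fixed `n_points`. Each
#' atom is inflated by the probe radius; a surface point is accessible when
#' it lies outside every other inflated sphere.
#'
#' @param mol a `qf_molecule` with 3D coordinates for every atom. Van der
#'   Waals radii come from a fixed internal Bondi table unless `radii` is
#'   supplied.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points number of lattice points per atom sphere (default 960).
#' @param radii optional numeric vector of per-atom vdW radii (Angstrom).
#' @return a `qf_sasa` object: data frame with per-atom `area` (Angstrom^2)
#'   and attributes `probe_radius`, `n_points` and `tmsa` (total molecular
#'   surface area = sum of per-atom areas).
#' @export
shrake_rupley_sasa <- function(mol, probe = 1.4, n_points = 960L,
                               radii = NULL) {
  stopifnot(inherits(mol, "qf_molecule"))
  if (is.null(mol$coords)) {
    stop("SASA requires 3D coordinates; read the structure from SDF",
         call. = FALSE)
  }
  n <- nrow(mol$atoms)
  if (is.null(radii)) radii <- bondi_radius(mol$atoms$element)
  stopifnot(length(radii) == n, all(radii > 0))
  r <- radii + probe
  pts <- .fibonacci_sphere(n_points)
  xyz <- mol$coords
  area <- numeric(n)
  for (i in seq_len(n)) {
    # neighbors whose inflated spheres can occlude atom i
    d2 <- rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2)
    nbr <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    p <- pts * r[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nbr) {
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj > r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * mean(accessible)
  }
  structure(
    data.frame(atom = seq_len(n), element = mol$atoms$element, area = area),
    probe_radius = probe, n_points = as.integer(n_points),
    tmsa = sum(area), class = c("qf_sasa", "data.frame"))
}

# Deterministic quasi-uniform unit-sphere lattice (golden spiral).
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Charged partial surface area (CPSA) descriptors
#'
#' Combines atomic partial charges with per-atom solvent-accessible surface
#' areas on the same explicit-atom ordering. With Q+ the sum of positive
#' charges, S_a per-atom SASA, TMSA the total area, acceptors the N/O atoms
#' and donor hydrogens the (explicit) H on N/O:
#' PPSA1 = sum of S_a over positively charged atoms; PPSA2 = Q+ x PPSA1;
#' HASA = sum of acceptor S_a; FHASA = HASA/TMSA;
#' HACA1 = sum of acceptor q_a S_a; HACA2 = HACA1/sqrt(TMSA);
#' HDCA1 = sum of donor-H q_h S_h; HDCA2 = HDCA1/sqrt(TMSA).
#'
#' Donor hydrogens must be explicit atoms with coordinates; structures meant
#' for CPSA should therefore be read from hydrogen-filled SDF records.
#'
#' @param mol a `qf_molecule`.
#' @param charges a `qf_chargeset` covering the explicit atoms of `mol`.
#' @param sasa a `qf_sasa` from [shrake_rupley_sasa()] on the same molecule.
#' @return named numeric vector of CPSA descriptors including `TMSA`.
#' @export
cpsa_descriptors <- function(mol, charges, sasa) {
  stopifnot(inherits(charges, "qf_chargeset"), inherits(sasa, "qf_sasa"))
  n <- nrow(mol$atoms)
  if (nrow(sasa) != n) stop("SASA/molecule atom count mismatch",
                            call. = FALSE)
  q <- charges$charge[seq_len(n)]
  s <- sasa$area
  tmsa <- sum(s)
  if (tmsa <= 0) stop("TMSA is zero", call. = FALSE)
  el <- mol$atoms$element
  acceptors <- el %in% c("N", "O")
  donor_h <- rep(FALSE, n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    a1 <- b$a1[k]; a2 <- b$a2[k]
    if (el[a1] == "H" && el[a2] %in% c("N", "O")) donor_h[a1] <- TRUE
    if (el[a2] == "H" && el[a1] %in% c("N", "O")) donor_h[a2] <- TRUE
  }
  pos <- q > 0
  ppsa1 <- sum(s[pos])
  c(
    TMSA = tmsa,
    PPSA1 = ppsa1,
    PPSA2 = sum(q[pos]) * ppsa1,
    HASA = sum(s[acceptors]),
    FHASA = sum(s[acceptors]) / tmsa,
    HACA1 = sum(q[acceptors] * s[acceptors]),
    HACA2 = sum(q[acceptors] * s[acceptors]) / sqrt(tmsa),
    HDCA1 = sum(q[donor_h] * s[donor_h]),
    HDCA2 = sum(q[donor_h] * s[donor_h]) / sqrt(tmsa)
  )
}
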