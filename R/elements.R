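# Element reference data used across the package.
#
# Scope is the organic subset a small-molecule screening library needs
# (C, H, N, O, S, P, halogens, B, Si). Unknown elements raise errors at the
# point of use rather than being silently imputed.

.ELEMENTS <- local({
  df <- data.frame(
    symbol = c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
               "Cl", "Br", "I"),
    number = c(1L, 5L, 6L, 7L, 8L, 9L, 14L, 15L, 16L, 17L, 35L, 53L),
    # standard atomic weights (Da)
    mass = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 28.086,
             30.974, 32.06, 35.453, 79.904, 126.904),
    # Sanderson electronegativities (electronegativity equalization)
    sanderson = c(2.592, 2.275, 2.746, 3.194, 3.654, 4.000, 2.138,
                  2.515, 2.957, 3.475, 3.219, 2.778),
    # Bondi van der Waals radii (Angstrom)
    vdw = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.10, 1.80, 1.80,
            1.75, 1.85, 1.98),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$symbol
  df
})

# Allowed valences per element, ascending. Implicit hydrogen assignment picks
# the smallest allowed valence that accommodates the explicit bond order sum.
.VALENCES <- list(
  H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L, Si = 4L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

.element_row <- function(symbol) {
  row <- .ELEMENTS[match(symbol, .ELEMENTS$symbol), ]
  if (anyNA(row$symbol)) {
    bad <- unique(symbol[!symbol %in% .ELEMENTS$symbol])
    stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  row
}

#' Standard atomic mass of an element
#'
#' @param symbol character vector of element symbols.
#' @return numeric vector of atomic masses in Da.
#' @keywords internal
atomic_mass <- function(symbol) .element_row(symbol)$mass

sanderson_en <- function(symbol) .element_row(symbol)$sanderson

bondi_radius <- function(symbol) .element_row(symbol)$vdw

atomic_number <- function(symbol) .element_row(symbol)$number

# Default valence adjusted for formal charge: group-14 elements lose a bond
# per unit |charge| (carbanion/carbocation both trivalent); N/P/O/S/halogens
# shift by the signed charge (N+ tetravalent, O- monovalent).
.allowed_valences <- function(symbol, charge = 0L) {
  v <- .VALENCES[[symbol]]
  if (is.null(v)) stop("unknown element: ", symbol, call. = FALSE)
  if (charge != 0L) {
    if (symbol %in% c("C", "Si")) v <- v - abs(charge) else v <- v + charge
  }
  v[v >= 0L]
}
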