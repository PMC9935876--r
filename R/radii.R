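#' Van der Waals radii used for surface-area calculations
#'
#' A fixed, published-style set of heavy-atom van der Waals radii (Angstrom).
#' Unknown elements fall back to the carbon radius of 1.70 A so that atoms
#' with exotic chemistry still contribute a sphere of plausible size.
#'
#' @return Named numeric vector of radii in Angstrom, with an attribute
#'   `default` holding the fallback radius.
#' @examples
#' vdw_radii()[["C"]]
#' @export
vdw_radii <- function() {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         CA = 1.97, H = 1.20)
  attr(r, "default") <- 1.70
  r
}

#' Resolve element symbols to van der Waals radii
#'
#' @param element character vector of element symbols ("C", "N", "CA" for
#'   calcium, ...). Case-insensitive.
#' @param radii radii table as returned by [vdw_radii()]; may be overridden
#'   to change the radius set.
#' @return numeric vector of radii (Angstrom); unknown elements get the
#'   table's default.
#' @export
element_radius <- function(element, radii = vdw_radii()) {
  key <- toupper(trimws(element))
  out <- unname(radii[key])
  out[is.na(out)] <- attr(radii, "default")
  out
}

# Derive an element symbol from a PDB atom name when the element column is
# blank. Strips digits/primes, then takes a leading two-letter calcium or the
# first letter. " CA " the atom name is carbon-alpha; calcium arrives as a
# hetero atom named "CA" with residue name "CA", which read_structure flags.
guess_element <- function(elety, resid, is_het) {
  e <- gsub("[^A-Za-z]", "", elety)
  out <- toupper(substr(e, 1L, 1L))
  ca <- is_het & toupper(resid) == "CA" & toupper(e) == "CA"
  out[ca] <- "CA"
  out
}
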