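#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic SASA: each atom's solvent-expanded sphere (radius
#' `r_vdw + probe`) is sampled at `n_points` quasi-uniform Fibonacci-lattice
#' points, and its area is the unoccluded point fraction times the sphere
#' area. No randomness is involved, so results are exactly reproducible.
#' Neighbour occlusion checks are restricted to atoms within
#' `r_i + r_j + 2 * probe`.
#'
#' @param x a [structure3d()] object, or a data.frame/matrix of atoms with
#'   columns `x`, `y`, `z` and `radius`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param n_points sphere sample points per atom (default 960; >= 16).
#' @return An object of class `sasa_result`: list with `per_atom_area`
#'   (Angstrom^2, one per atom, in input order), `total_area`,
#'   `probe_radius`, `n_sphere_points`.
#' @examples
#' one_c <- data.frame(x = 0, y = 0, z = 0, radius = 1.7)
#' compute_sasa(one_c)$total_area   # 4*pi*(1.7 + 1.4)^2
#' @export
compute_sasa <- function(x, probe_radius = 1.4, n_points = 960) {
  if (inherits(x, "structure3d")) {
    xyz <- coords(x)
    radius <- x$atoms$radius
  } else {
    x <- as.data.frame(x)
    stopifnot(all(c("x", "y", "z", "radius") %in% names(x)))
    xyz <- as.matrix(x[, c("x", "y", "z")])
    radius <- x$radius
  }
  if (nrow(xyz) < 1L) stop("need at least one atom")
  if (!all(is.finite(xyz))) {
    bad <- which(!apply(is.finite(xyz), 1L, all))[1L]
    stop("non-finite coordinates for atom at row ", bad)
  }
  per_atom <- .sasa_cpp(xyz, as.numeric(radius), probe_radius,
                        as.integer(n_points))
  structure(list(per_atom_area = as.numeric(per_atom),
                 total_area = sum(per_atom),
                 probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total_area, length(x$per_atom_area), x$probe_radius,
              x$n_sphere_points))
  invisible(x)
}
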