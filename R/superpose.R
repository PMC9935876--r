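#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation aligning a mobile point set onto
#' a reference (SVD solution; reflections are excluded by flipping the sign
#' of the smallest singular vector when needed).
#'
#' The recovered transform maps mobile coordinates as
#' `t(R %*% (x - centroid_mobile)) + centroid_reference`, applied row-wise
#' by [apply_superposition()].
#'
#' @param mobile,reference n x 3 matrices of paired coordinates (same row
#'   order), n >= 3 and not collinear.
#' @return A `superposition` object: list with `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom) and `n_atoms`.
#' @examples
#' p <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch_superpose(p, p)
#' fit$rmsd   # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  if (ncol(P) != 3L || ncol(Q) != 3L) stop("coordinate sets must be n x 3")
  if (nrow(P) != nrow(Q))
    stop("coordinate sets differ in length: ", nrow(P), " vs ", nrow(Q))
  if (nrow(P) < 3L) stop("need at least 3 points")
  cm <- colMeans(P); cr <- colMeans(Q)
  P0 <- sweep(P, 2L, cm); Q0 <- sweep(Q, 2L, cr)
  if (qr(P0)$rank < 2L || qr(Q0)$rank < 2L)
    stop("points are collinear; superposition is underdetermined")
  H <- crossprod(P0, Q0)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)            # rotation: x' = R x (column vectors)
  moved <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q0)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd, n_atoms = nrow(P)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition of %d atoms: rmsd %.3f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param fit a `superposition` from [kabsch_superpose()].
#' @param xyz n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(fit, xyz) {
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(fit$rotation), 2L, fit$translation, `+`)
}

#' Pair equivalent atoms of two structures
#'
#' Atoms are matched by (mapped chain, residue number, insertion code, atom
#' name); residues present in only one structure are dropped and counted.
#' Pairing is independent of atom order in either file.
#'
#' @param struct_A,struct_B [structure3d()] objects.
#' @param atom_name atom name to pair (default "CA"; use `NULL` for all
#'   common atom names).
#' @param chain_map named character vector mapping chains of A to chains of
#'   B (default: identity on shared chain ids).
#' @return list with `xyz_A`, `xyz_B` (paired n x 3 matrices), `keys`
#'   (pairing identifiers), `n_paired`, `n_unpaired_A`, `n_unpaired_B`.
#' @export
pair_common_residues <- function(struct_A, struct_B, atom_name = "CA",
                                 chain_map = NULL) {
  a <- struct_A$atoms[!struct_A$atoms$is_het, ]
  b <- struct_B$atoms[!struct_B$atoms$is_het, ]
  if (!is.null(atom_name)) {
    a <- a[a$elety %in% atom_name, ]
    b <- b[b$elety %in% atom_name, ]
  }
  if (is.null(chain_map)) {
    shared <- intersect(unique(a$chain), unique(b$chain))
    chain_map <- setNames(shared, shared)
  }
  a <- a[a$chain %in% names(chain_map), ]
  b <- b[b$chain %in% chain_map, ]
  key_a <- paste(chain_map[a$chain], a$resno, a$insert, a$elety)
  key_b <- paste(b$chain, b$resno, b$insert, b$elety)
  common <- intersect(key_a, key_b)
  if (!length(common)) stop("no common atoms to pair")
  ia <- match(common, key_a); ib <- match(common, key_b)
  ord <- order(common)
  list(xyz_A = as.matrix(a[ia[ord], c("x", "y", "z")]),
       xyz_B = as.matrix(b[ib[ord], c("x", "y", "z")]),
       keys = common[ord],
       n_paired = length(common),
       n_unpaired_A = nrow(a) - length(common),
       n_unpaired_B = nrow(b) - length(common))
}

#' Superpose one structure onto another over common residues
#'
#' Convenience wrapper: pairs common atoms (default C-alpha, the atom set
#' conventionally quoted for inter-structure RMSDs) and runs
#' [kabsch_superpose()].
#'
#' @inheritParams pair_common_residues
#' @return A `superposition` object with pairing counts attached.
#' @export
superpose_structures <- function(struct_A, struct_B, atom_name = "CA",
                                 chain_map = NULL) {
  pr <- pair_common_residues(struct_A, struct_B, atom_name, chain_map)
  fit <- kabsch_superpose(pr$xyz_A, pr$xyz_B)
  fit$n_unpaired_A <- pr$n_unpaired_A
  fit$n_unpaired_B <- pr$n_unpaired_B
  fit
}

#' Long axis of an EC domain
#'
#' The domain axis is the unit vector from the centroid of the domain's
#' N-terminal third of C-alpha atoms to the centroid of its C-terminal
#' third. Terminal-third centroids avoid the sign ambiguity of inertia
#' eigenvectors and track the visual long axis of an elongated beta-sandwich
#' domain; an inertia-eigenvector mode is available for sensitivity checks
#' (its sign is fixed by agreement with the terminal-third axis).
#'
#' @param struct a domain-annotated [structure3d()].
#' @param chain chain identifier.
#' @param domain domain label, e.g. "EC1".
#' @param method "thirds" (default) or "inertia".
#' @return list with `domain`, `centroid` and unit `axis`.
#' @export
domain_axis <- function(struct, chain, domain, method = c("thirds",
                                                          "inertia")) {
  method <- match.arg(method)
  sel <- atom_select(struct, chain = chain, domain = domain, elety = "CA")
  if (!length(sel)) stop("no C-alpha atoms for domain ", domain,
                         " on chain ", chain)
  a <- struct$atoms[sel, ]
  a <- a[order(a$resno, a$insert), ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 6L) stop("domain ", domain, " has too few residues (", n,
                   ") for an axis")
  third <- max(2L, floor(n / 3))
  v <- colMeans(xyz[(n - third + 1L):n, , drop = FALSE]) -
    colMeans(xyz[1:third, , drop = FALSE])
  if (method == "inertia") {
    centered <- sweep(xyz, 2L, colMeans(xyz))
    ev <- eigen(crossprod(centered), symmetric = TRUE)$vectors[, 1L]
    if (sum(ev * v) < 0) ev <- -ev       # orient N -> C
    v <- ev
  }
  list(domain = domain, centroid = colMeans(xyz),
       axis = v / sqrt(sum(v^2)))
}

#' Tilt of a terminal EC domain relative to a reference structure
#'
#' Superposes the query onto the reference over the C-alpha atoms of the
#' `align_on` domains (default EC2-EC3), then measures the angle between
#' the two structures' `domain` axes. This is the bend-angle reading used
#' to compare the EC1 orientation of a cadherin against a straight
#' reference: a hinge at the EC1-EC2 linker shows up directly as this
#' angle.
#'
#' @param query,reference domain-annotated [structure3d()] objects.
#' @param chain_query,chain_ref chains carrying the domains (default: first
#'   chain of each).
#' @param align_on domains used for superposition (default c("EC2","EC3")).
#' @param domain the tilted domain measured (default "EC1").
#' @param axis_method see [domain_axis()].
#' @return Angle in degrees, in [0, 180].
#' @export
ec1_tilt_angle <- function(query, reference, chain_query = NULL,
                           chain_ref = NULL, align_on = c("EC2", "EC3"),
                           domain = "EC1",
                           axis_method = c("thirds", "inertia")) {
  axis_method <- match.arg(axis_method)
  if (is.null(chain_query)) chain_query <- query$chains[1L]
  if (is.null(chain_ref)) chain_ref <- reference$chains[1L]
  for (d in c(align_on, domain)) {
    if (!d %in% query$atoms$domain[query$atoms$chain == chain_query])
      stop("query chain ", chain_query, " lacks domain ", d)
    if (!d %in% reference$atoms$domain[reference$atoms$chain == chain_ref])
      stop("reference chain ", chain_ref, " lacks domain ", d)
  }
  sq <- atom_select(query, chain = chain_query, domain = align_on,
                    elety = "CA")
  sr <- atom_select(reference, chain = chain_ref, domain = align_on,
                    elety = "CA")
  aq <- query$atoms[sq, ]; ar <- reference$atoms[sr, ]
  key_q <- paste(aq$domain, aq$resno, aq$insert)
  key_r <- paste(ar$domain, ar$resno, ar$insert)
  common <- intersect(key_q, key_r)
  if (length(common) < 3L)
    stop("fewer than 3 common alignment residues")
  fit <- kabsch_superpose(
    as.matrix(aq[match(common, key_q), c("x", "y", "z")]),
    as.matrix(ar[match(common, key_r), c("x", "y", "z")]))
  moved <- query
  moved$atoms[, c("x", "y", "z")] <-
    apply_superposition(fit, coords(query))
  ax_q <- domain_axis(moved, chain_query, domain, method = axis_method)$axis
  ax_r <- domain_axis(reference, chain_ref, domain,
                      method = axis_method)$axis
  acos(pmin(1, pmax(-1, sum(ax_q * ax_r)))) * 180 / pi
}
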