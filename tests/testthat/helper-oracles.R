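# Shared builders and independent oracles. Oracles here deliberately avoid
# the package's own code paths (different algorithms, plain-R loops) so that
# agreement between the two routes is informative.

# Analytic buried area for two intersecting spheres at solvent-expanded
# radii Ri = ri + probe: the buried cap on sphere i has height
# hi = Ri - (d^2 + Ri^2 - Rj^2) / (2 d) and area 2 pi Ri hi.
two_sphere_buried <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  if (d >= R1 + R2) return(c(0, 0))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(2 * pi * R1 * h1, 2 * pi * R2 * h2)
}

# Minimal complex of isolated cross-chain atom pairs: pair k is one atom on
# chain A at (0, 20 k, 0) and one on chain B at (d_k, 20 k, 0); pairs are far
# enough apart that every burial is a pure two-sphere problem.
atom_pair_complex <- function(distances, elements = NULL,
                              domains_A = "EC1", domains_B = "EC1") {
  k <- seq_along(distances)
  if (is.null(elements)) elements <- rep("C", length(k))
  domains_A <- rep_len(domains_A, length(k))
  domains_B <- rep_len(domains_B, length(k))
  structure3d(data.frame(
    chain = rep(c("A", "B"), each = length(k)),
    resno = rep(k, 2L), insert = "", resid = "ALA", elety = "CA",
    element = rep(elements, 2L),
    x = c(rep(0, length(k)), distances),
    y = rep(20 * k, 2L), z = 0, is_het = FALSE,
    domain = c(domains_A, domains_B)))
}

# Planted-contact schedule that keeps every (domain, residue-offset) pair
# unique: contacts 2j-1 and 2j share the generator's j-th residue offset but
# use disjoint domain pairs, so no two contacts touch the same residue.
planted_contact_list <- function(n_hb, n_sb, dist_hb = 3.0, dist_sb = 3.2) {
  lapply(seq_len(n_hb + n_sb), function(k) {
    list(domain_A = if (k %% 2L) "EC1" else "EC3",
         domain_B = if (k %% 2L) "EC2" else "EC4",
         kind = if (k <= n_hb) "hbond" else "salt_bridge",
         distance = if (k <= n_hb) dist_hb else dist_sb)
  })
}

# Rotation matrix from an axis-angle (Rodrigues) vector.
rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rigidly transform a structure3d in place.
transform_structure <- function(st, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  st$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2L, t, `+`)
  st
}

# Direct numerical superposition: minimise the residual sum of squares over
# a 6-parameter rigid transform (Rodrigues rotation + translation) with a
# general-purpose optimiser, from two starts.
numeric_superpose_rmsd <- function(P, Q) {
  obj <- function(par) {
    moved <- sweep(P %*% t(rodrigues(par[1:3])), 2L, par[4:6], `+`)
    sum((moved - Q)^2)
  }
  best <- Inf
  for (s in list(c(0, 0, 0), c(0.4, -0.3, 0.2))) {
    o <- stats::optim(c(s, colMeans(Q) - colMeans(P)), obj,
                      method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
    best <- min(best, o$value)
  }
  sqrt(best / nrow(P))
}

# Monte-Carlo SASA with uniform random sphere directions (normalised
# Gaussians) - a different point set and accessibility loop from the
# lattice-based implementation.
mc_sasa_total <- function(atoms, probe = 1.4, n_pts = 1500L, seed = 42L) {
  set.seed(seed)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atoms$radius + probe
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    g <- matrix(rnorm(3L * n_pts), ncol = 3L)
    dirs <- g / sqrt(rowSums(g^2))
    pts <- sweep(dirs * rad[i], 2L, xyz[i, ], `+`)
    nb <- which(sqrt(colSums((t(xyz) - xyz[i, ])^2)) < rad[i] +
                  max(rad) + 1e-9)
    nb <- setdiff(nb, i)
    acc <- rep(TRUE, n_pts)
    for (j in nb) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > rad[j]^2
    }
    total <- total + 4 * pi * rad[i]^2 * mean(acc)
  }
  total
}

# Brute-force cross-chain contact enumeration with chemistry re-derived for
# the residue types the toy generator emits (ALA, LYS, ASP).
brute_contacts <- function(st, d_hb = 3.5, d_sb = 4.0) {
  a <- st$atoms
  A <- a[a$chain == "A", ]
  B <- a[a$chain == "B", ]
  donor <- function(x) (x$elety == "N" & x$resid != "PRO") |
    (x$resid == "LYS" & x$elety == "NZ")
  acceptor <- function(x) x$elety %in% c("O", "OXT") |
    (x$resid == "ASP" & x$elety %in% c("OD1", "OD2"))
  basic_n <- function(x) x$resid == "LYS" & x$elety == "NZ"
  acidic_o <- function(x) x$resid == "ASP" & x$elety %in% c("OD1", "OD2")
  hb <- NULL
  sb <- NULL
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B$x - A$x[i])^2 + (B$y - A$y[i])^2 + (B$z - A$z[i])^2)
    is_sb <- (basic_n(A[i, ]) & acidic_o(B)) |
      (acidic_o(A[i, ]) & basic_n(B))
    is_hb <- ((donor(A[i, ]) & acceptor(B)) |
                (acceptor(A[i, ]) & donor(B))) & !is_sb
    for (j in which(is_hb & d <= d_hb & d > 0))
      hb <- rbind(hb, data.frame(resno_A = A$resno[i],
                                 elety_A = A$elety[i],
                                 resno_B = B$resno[j],
                                 elety_B = B$elety[j]))
    for (j in which(is_sb & d <= d_sb & d > 0))
      sb <- rbind(sb, data.frame(resno_A = A$resno[i],
                                 elety_A = A$elety[i],
                                 resno_B = B$resno[j],
                                 elety_B = B$elety[j]))
  }
  list(hbond = hb, salt_bridge = sb)
}

contact_keys <- function(df) {
  if (is.null(df) || !nrow(df)) return(character())
  sort(paste(df$resno_A, df$elety_A, df$resno_B, df$elety_B))
}

# Exhaustive 12-residue window check for the phosphomotif.
brute_motif_starts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  if (L < 12L) return(integer())
  ok <- vapply(seq_len(L - 11L), function(i) {
    ch[i] == "D" && ch[i + 2L] == "N" && ch[i + 3L] == "D" &&
      ch[i + 11L] %in% c("S", "T")
  }, logical(1L))
  which(ok)
}

# Mass-action oracle for the one-set-of-sites cumulative heat: solve the
# free-ligand equation numerically instead of using the closed form.
oracle_cumulative_heat <- function(params, i) {
  dv <- sum(params$injection_volumes[seq_len(i)])
  f <- dv / params$V0
  Mt <- params$Mt0 * (1 - f / 2) / (1 + f / 2)
  Xt <- params$X0 * f / (1 + f / 2)
  g <- function(x) x + params$n * Mt * params$K * x /
    (1 + params$K * x) - Xt
  x <- stats::uniroot(g, c(0, Xt), tol = 1e-18)$root
  bound <- params$n * Mt * params$K * x / (1 + params$K * x)
  bound * params$delta_H * params$V0
}

# Brute-force Euclidean-disc dilation of a rasterised boundary set.
brute_edge_mask <- function(boundaries, r) {
  core <- fatdachs:::rasterize_boundaries(boundaries)
  sh <- dim(core)
  idx <- which(core, arr.ind = TRUE)
  out <- matrix(FALSE, sh[1], sh[2])
  for (i in seq_len(sh[1]))
    for (j in seq_len(sh[2]))
      out[i, j] <- any((idx[, 1] - i)^2 + (idx[, 2] - j)^2 <= r^2)
  out
}
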