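test_that("Kabsch recovers a pure rigid motion exactly", {
  set.seed(1)
  P <- matrix(rnorm(60), ncol = 3)
  R <- rodrigues(c(0.3, -0.8, 0.5))
  Q <- sweep(P %*% t(R), 2, c(5, -2, 9), `+`)
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(fit, P), Q, tolerance = 1e-9)
})

test_that("Kabsch never returns a reflection", {
  set.seed(2)
  P <- matrix(rnorm(30), ncol = 3)
  Q <- P %*% diag(c(-1, 1, 1))        # best improper fit is a mirror
  fit <- kabsch_superpose(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches direct numerical minimisation", {
  set.seed(3)
  P <- matrix(rnorm(90), ncol = 3)
  Q <- sweep(P %*% t(rodrigues(c(1.1, 0.2, -0.4))), 2, c(1, 2, 3), `+`) +
    matrix(rnorm(90, 0, 0.3), ncol = 3)
  fit <- kabsch_superpose(P, Q)
  expect_lt(abs(fit$rmsd - numeric_superpose_rmsd(P, Q)), 1e-6)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  expect_error(kabsch_superpose(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "differ in length")
})

test_that("structure superposition pairs residues independent of atom order", {
  toy <- make_toy_complex(domains_per_chain = 2L, seed = 9L)
  st <- toy$structure
  moved <- transform_structure(st, rodrigues(c(0.2, 0.9, -0.1)),
                               c(10, -4, 2))
  fit <- superpose_structures(moved, st)
  expect_lt(fit$rmsd, 1e-9)
  # shuffling the mobile structure's rows changes nothing
  shuffled <- moved
  set.seed(4)
  shuffled$atoms <- shuffled$atoms[sample(nrow(shuffled$atoms)), ]
  fit2 <- superpose_structures(shuffled, st)
  expect_equal(fit2$rmsd, fit$rmsd, tolerance = 1e-9)
})

test_that("domain axes are unit length and track the chain direction", {
  toy <- make_toy_complex(seed = 12L)
  ax1 <- domain_axis(toy$structure, "A", "EC1")
  ax2 <- domain_axis(toy$structure, "A", "EC2")
  expect_equal(sum(ax1$axis^2), 1, tolerance = 1e-12)
  # helical chain A runs along +z, so consecutive domain axes agree
  expect_gt(sum(ax1$axis * ax2$axis), 0.99)
  # inertia axis agrees with the terminal-thirds axis for a straight domain
  ax1i <- domain_axis(toy$structure, "A", "EC1", method = "inertia")
  expect_gt(abs(sum(ax1$axis * ax1i$axis)), 0.99)
})

test_that("a planted hinge bend is read back as the tilt angle", {
  ref <- make_toy_complex(seed = 21L)$structure
  bent <- make_toy_complex(hinge_bend = list(chain = "A", domain = "EC1",
                                             degrees = 30),
                           seed = 21L)$structure
  tilt <- ec1_tilt_angle(bent, ref, chain_query = "A", chain_ref = "A")
  expect_lt(abs(tilt - 30), 1)
  # unbent structure reads ~0
  expect_lt(ec1_tilt_angle(ref, ref, chain_query = "A", chain_ref = "A"),
            1e-6)
})

test_that("tilt measurement is invariant to rigid motion of the query", {
  ref <- make_toy_complex(seed = 22L)$structure
  bent <- make_toy_complex(hinge_bend = list(chain = "A", domain = "EC1",
                                             degrees = 18),
                           seed = 22L)$structure
  t0 <- ec1_tilt_angle(bent, ref, chain_query = "A", chain_ref = "A")
  moved <- transform_structure(bent, rodrigues(c(-0.7, 0.3, 1.2)),
                               c(3, 30, -12))
  t1 <- ec1_tilt_angle(moved, ref, chain_query = "A", chain_ref = "A")
  expect_equal(t1, t0, tolerance = 1e-6)
})
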