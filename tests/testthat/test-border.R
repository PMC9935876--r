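test_that("polyline lengths and rasterisation are exact on straight lines", {
  bs <- boundary_set(list(cbind(5, 0:9)), c(21, 21))
  expect_equal(bs$total_length, 9)
  core <- fatdachs:::rasterize_boundaries(bs)
  expect_equal(sum(core), 10)              # 10 pixels on the raster
  expect_true(all(which(core, arr.ind = TRUE)[, 1] == 6))  # 0-based row 5
  # a diagonal has Euclidean length sqrt(2) per step
  bd <- boundary_set(list(cbind(0:4, 0:4)), c(10, 10))
  expect_equal(bd$total_length, 4 * sqrt(2))
})

test_that("edge masks equal a brute-force Euclidean dilation", {
  shapes <- list(list(cbind(5, 1:10)),                 # straight
                 list(cbind(c(2, 8, 8), c(2, 5, 12))), # bent polyline
                 list(cbind(3, 1:6), cbind(10:14, 8))) # two polylines
  for (pl in shapes) {
    bs <- boundary_set(pl, c(17, 17))
    for (r in c(1, 2, 3.5))
      expect_identical(make_edge_mask(bs, r)$mask, brute_edge_mask(bs, r))
  }
  bs <- boundary_set(shapes[[1]], c(17, 17))
  expect_error(make_edge_mask(bs, 0.5), ">= 1")
  # dilation is monotone in r
  expect_true(all(make_edge_mask(bs, 2)$mask >= make_edge_mask(bs, 1)$mask))
})

test_that("uniform-image closed forms hold to 1e-9", {
  bs <- boundary_set(list(cbind(6, 2:12), cbind(2:12, 6)), c(15, 15))
  mask <- make_edge_mask(bs, 2)
  L <- bs$total_length
  m <- sum(mask$mask)
  img <- matrix(7.25, 15, 15)
  expect_equal(border_accumulation(img, mask, L), 7.25 * m / L,
               tolerance = 1e-9)
  # constants pass through the reflective-padding blur exactly
  expect_equal(border_complexes(img, img, 2, mask, L), 7.25^2 * m / L,
               tolerance = 1e-9)
  expect_equal(gaussian_blur(img, 1.7), img, tolerance = 1e-12)
})

test_that("accumulation is linear and complexes bilinear in intensity", {
  set.seed(20)
  X <- matrix(runif(100, 1, 2), 10, 10)
  Y <- matrix(runif(100, 1, 2), 10, 10)
  bs <- boundary_set(list(cbind(4, 1:8)), c(10, 10))
  mask <- make_edge_mask(bs, 1)
  L <- bs$total_length
  expect_equal(border_accumulation(2 * X + 3 * Y, mask, L),
               2 * border_accumulation(X, mask, L) +
                 3 * border_accumulation(Y, mask, L), tolerance = 1e-12)
  expect_equal(border_complexes(2 * X, 3 * Y, 1.5, mask, L),
               6 * border_complexes(X, Y, 1.5, mask, L), tolerance = 1e-12)
})

test_that("statistics are invariant to how the tracing splits into polylines", {
  full <- boundary_set(list(cbind(5, 0:10)), c(12, 12))
  split2 <- boundary_set(list(cbind(5, 0:4), cbind(5, 4:10)), c(12, 12))
  expect_equal(split2$total_length, full$total_length)
  set.seed(21)
  img <- matrix(runif(144, 50, 150), 12, 12)
  for (r in 1:2)
    expect_equal(
      border_accumulation(img, make_edge_mask(split2, r), split2$total_length),
      border_accumulation(img, make_edge_mask(full, r), full$total_length),
      tolerance = 1e-12)
})

test_that("compare_groups matches the hand-computed pooled t test", {
  res <- compare_groups(c(1, 2, 3), c(2, 3, 4), alternative = "greater")
  # pooled variance 1, se = sqrt(2/3), t = -sqrt(3/2), df = 4
  expect_equal(res$t, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, stats::pt(-sqrt(3 / 2), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$mean_wt, 2)
  expect_equal(res$sem_wt, 1 / sqrt(3))
  # the study design: 12 vs 10 embryos, one-sided
  res2 <- compare_groups(rnorm(12), rnorm(10))
  expect_equal(res2$df, 20)
  # direction flips under "less"
  res3 <- compare_groups(c(1, 2, 3), c(2, 3, 4), alternative = "less")
  expect_equal(res3$p_value, 1 - res$p_value, tolerance = 1e-12)
})

test_that("degenerate constant groups are handled explicitly", {
  same <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_true(same$degenerate)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 0.5)
  diff_ <- compare_groups(c(2, 2, 2), c(3, 3, 3))
  expect_true(diff_$degenerate)
  expect_true(is.nan(diff_$t))
  expect_true(is.na(diff_$p_value))
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("boundary sets round trip through JSON", {
  bs <- boundary_set(list(cbind(c(1, 7), c(2, 9)), cbind(3:6, 3)),
                     c(20, 24))
  path <- tempfile(fileext = ".json")
  write_boundaries(bs, path)
  back <- read_boundaries(path)
  expect_equal(back$image_shape, bs$image_shape)
  expect_equal(length(back$polylines), length(bs$polylines))
  for (k in seq_along(bs$polylines))
    expect_equal(unname(as.matrix(back$polylines[[k]])),
                 unname(as.matrix(bs$polylines[[k]])))
  expect_equal(back$total_length, bs$total_length)
})
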