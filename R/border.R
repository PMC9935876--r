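#' Construct a set of traced cell-boundary polylines
#'
#' Boundaries are manual traces of cell-cell borders: ordered lists of
#' pixel-coordinate vertices. Coordinates are 0-based `(row, col)` in a
#' row-major image, matching the JSON interchange format written by
#' [write_boundaries()].
#'
#' @param polylines list of n x 2 matrices (columns row, col; 0-based),
#'   each with >= 2 vertices.
#' @param image_shape integer c(rows, cols).
#' @return A `boundary_set`: list with `polylines`, `image_shape` and
#'   `total_length` (sum of Euclidean segment lengths, pixels).
#' @export
boundary_set <- function(polylines, image_shape) {
  if (!length(polylines)) stop("empty polyline list")
  image_shape <- as.integer(image_shape)
  polylines <- lapply(polylines, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 2L)
      stop("each polyline needs >= 2 (row, col) vertices")
    if (any(p[, 1] < 0 | p[, 1] > image_shape[1] - 1L |
              p[, 2] < 0 | p[, 2] > image_shape[2] - 1L))
      stop("polyline vertex outside image bounds")
    unname(p)
  })
  L <- sum(vapply(polylines, function(p)
    sum(sqrt(rowSums(diff(p)^2))), numeric(1L)))
  if (L <= 0) stop("total boundary length must be positive")
  structure(list(polylines = polylines, image_shape = image_shape,
                 total_length = L), class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("boundary_set: %d polylines, total length %.1f px on %dx%d image\n",
              length(x$polylines), x$total_length, x$image_shape[1],
              x$image_shape[2]))
  invisible(x)
}

#' Read / write boundary annotations as JSON
#'
#' Format: `{"image_shape": [rows, cols], "polylines": [[[r,c], ...], ...]}`
#' with 0-based row-major pixel coordinates.
#'
#' @param path JSON file.
#' @return A [boundary_set()].
#' @export
read_boundaries <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  polys <- j$polylines
  if (is.array(polys) && length(dim(polys)) == 3L)
    polys <- lapply(seq_len(dim(polys)[1L]), function(i) polys[i, , ])
  boundary_set(polys, j$image_shape)
}

#' @rdname read_boundaries
#' @param boundaries a [boundary_set()] to write.
#' @export
write_boundaries <- function(boundaries, path) {
  jsonlite::write_json(list(image_shape = boundaries$image_shape,
                            polylines = lapply(boundaries$polylines,
                                               unname)),
                       path, digits = NA)
  invisible(path)
}

# 8-connected raster of a segment (Bresenham on real-valued endpoints);
# returns 1-based (row, col) pixel indices
raster_segment <- function(p0, p1) {
  n <- max(abs(p1 - p0))
  if (n < 1) return(matrix(round(p0) + 1L, ncol = 2L))
  t <- seq(0, 1, length.out = ceiling(n) + 1L)
  px <- unique(cbind(round(p0[1] + t * (p1[1] - p0[1])),
                     round(p0[2] + t * (p1[2] - p0[2]))))
  px + 1L
}

rasterize_boundaries <- function(boundaries) {
  sh <- boundaries$image_shape
  mask <- matrix(FALSE, sh[1], sh[2])
  for (p in boundaries$polylines) {
    for (i in seq_len(nrow(p) - 1L)) {
      px <- raster_segment(p[i, ], p[i + 1L, ])
      mask[px] <- TRUE
    }
  }
  mask
}

#' Dilate traced boundaries into a binary edge mask
#'
#' Rasterizes each polyline with 8-connected line drawing, then dilates by
#' a Euclidean disc of radius `r` (pixel offsets with
#' `dr^2 + dc^2 <= r^2`). The radius should be slightly larger than the
#' characteristic boundary width so the mask covers the full fluorescent
#' border signal.
#'
#' @param boundaries a [boundary_set()].
#' @param r dilation radius in pixels (>= 1).
#' @return An `edge_mask`: list with the logical `mask` matrix and
#'   `dilation_radius`.
#' @export
make_edge_mask <- function(boundaries, r = 3) {
  stopifnot(inherits(boundaries, "boundary_set"))
  if (r < 1) stop("dilation radius must be >= 1")
  core <- rasterize_boundaries(boundaries)
  offs <- expand.grid(dr = -floor(r):floor(r), dc = -floor(r):floor(r))
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  sh <- dim(core)
  mask <- matrix(FALSE, sh[1], sh[2])
  idx <- which(core, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    rr <- idx[, 1] + offs$dr[k]
    cc <- idx[, 2] + offs$dc[k]
    ok <- rr >= 1L & rr <= sh[1] & cc >= 1L & cc <= sh[2]
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  structure(list(mask = mask, dilation_radius = r), class = "edge_mask")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "edge_mask")) mask$mask else mask
}

#' Border accumulation of a fluorescence channel
#'
#' Sum of channel intensity over the edge-mask pixels, divided by the
#' total geometric boundary length (pixels) — intensity per unit border
#' length, independent of how many polylines the tracing was split into.
#'
#' @param image non-negative numeric matrix (one channel).
#' @param mask an [make_edge_mask()] result (or logical matrix).
#' @param L total boundary length in pixels (e.g.
#'   `boundaries$total_length`).
#' @return Border accumulation (intensity * pixels / pixel length).
#' @export
border_accumulation <- function(image, mask, L) {
  m <- as_mask_matrix(mask)
  image <- as.matrix(image)
  if (!all(dim(image) == dim(m)))
    stop("image and mask shapes differ: ",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(m), collapse = "x"))
  if (L <= 0) stop("boundary length must be positive")
  sum(image[m]) / L
}

#' Border complexes: blurred-channel-product colocalization statistic
#'
#' Both channels are Gaussian-blurred with the same sigma, multiplied
#' elementwise, restricted to the edge mask, summed and divided by the
#' total boundary length. The product of blurred channels rewards
#' fluorescence that is present in both channels at the same border
#' location, i.e. trans-complexes rather than one-sided accumulation.
#'
#' @param image_A,image_B non-negative channel matrices of equal shape.
#' @param blur_sigma Gaussian sigma in pixels (>= 0; 0 skips blurring).
#' @param mask an [make_edge_mask()] result (or logical matrix).
#' @param L total boundary length in pixels.
#' @return Border-complex level (blurred-product units / pixel length).
#' @export
border_complexes <- function(image_A, image_B, blur_sigma = 2, mask, L) {
  A <- as.matrix(image_A); B <- as.matrix(image_B)
  if (!all(dim(A) == dim(B)))
    stop("channel shapes differ: ", paste(dim(A), collapse = "x"),
         " vs ", paste(dim(B), collapse = "x"))
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (blur_sigma > 0) {
    A <- gaussian_blur(A, blur_sigma)
    B <- gaussian_blur(B, blur_sigma)
  }
  border_accumulation(A * B, mask, L)
}

# separable Gaussian blur with reflective edge padding; constants map to
# themselves exactly, which the closed-form uniform-image identities rely on
gaussian_blur <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    pad <- c(v[pmin(n, pmax(1L, half:1))], v,
             v[pmin(n, pmax(1L, n - (1:half) + 1L))])
    as.numeric(stats::filter(pad, k, sides = 2))[(half + 1L):(half + n)]
  }
  out <- apply(img, 2L, conv1)
  t(apply(t(out), 2L, conv1))
}

#' One-sided unpaired t test between groups of border statistics
#'
#' The classic unpaired two-sample t test (pooled variance by default;
#' Welch available), one-sided in the stated direction, with group means
#' and standard errors of the mean as conventionally plotted.
#'
#' @param values_wt,values_mut numeric vectors (>= 2 values each).
#' @param alternative "greater" tests wt > mut; "less" tests wt < mut.
#' @param var_equal pooled-variance test (default TRUE).
#' @return list with `t`, `df`, `p_value`, `mean_wt`, `mean_mut`,
#'   `sem_wt`, `sem_mut` and `degenerate` (TRUE when both groups have zero
#'   variance, in which case `t` is undefined/NaN).
#' @export
compare_groups <- function(values_wt, values_mut,
                           alternative = c("greater", "less"),
                           var_equal = TRUE) {
  alternative <- match.arg(alternative)
  if (length(values_wt) < 2L || length(values_mut) < 2L)
    stop("both groups need at least 2 values")
  degenerate <- var(values_wt) == 0 && var(values_mut) == 0
  if (degenerate && isTRUE(all.equal(mean(values_wt), mean(values_mut)))) {
    # identical constant groups: no evidence either way
    return(list(t = 0, df = length(values_wt) + length(values_mut) - 2L,
                p_value = 0.5,
                mean_wt = mean(values_wt), mean_mut = mean(values_mut),
                sem_wt = 0, sem_mut = 0, degenerate = TRUE))
  }
  if (degenerate) {
    # distinct constant groups: t statistic is undefined (0/0 scale)
    return(list(t = NaN, df = length(values_wt) + length(values_mut) - 2L,
                p_value = NA_real_,
                mean_wt = mean(values_wt), mean_mut = mean(values_mut),
                sem_wt = 0, sem_mut = 0, degenerate = TRUE))
  }
  tt <- t.test(values_wt, values_mut, alternative = alternative,
               var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_wt = mean(values_wt), mean_mut = mean(values_mut),
       sem_wt = sd(values_wt) / sqrt(length(values_wt)),
       sem_mut = sd(values_mut) / sqrt(length(values_mut)),
       degenerate = degenerate)
}

#' Per-image border statistics for a two-channel image
#'
#' Convenience wrapper computing both single-channel accumulations and the
#' border-complex statistic with one mask.
#'
#' @param image_A,image_B channel matrices.
#' @param boundaries a [boundary_set()].
#' @param r dilation radius (pixels).
#' @param blur_sigma Gaussian sigma (pixels).
#' @return list with `accumulation_A`, `accumulation_B`, `complexes` and
#'   the parameters used.
#' @export
border_stats <- function(image_A, image_B, boundaries, r = 3,
                         blur_sigma = 2) {
  mask <- make_edge_mask(boundaries, r)
  L <- boundaries$total_length
  list(accumulation_A = border_accumulation(image_A, mask, L),
       accumulation_B = border_accumulation(image_B, mask, L),
       complexes = border_complexes(image_A, image_B, blur_sigma, mask, L),
       r = r, blur_sigma = blur_sigma, total_length = L)
}

#' Read a one- or two-channel TIFF image as numeric matrices
#'
#' @param path TIFF file.
#' @return list of channel matrices (row-major, rows = image height).
#' @export
read_channels <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  # EBImage stores x (columns) first; transpose to row x col matrices
  if (length(d) == 2L) return(list(t(EBImage::imageData(img))))
  lapply(seq_len(d[3L]), function(k) t(EBImage::imageData(img)[, , k]))
}
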