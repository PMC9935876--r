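# Seed-deterministic generators producing fixtures with known ground truth
# for every analysis stage. Geometry is deliberately toy-like (bead/helix
# chains, polygonal cell mosaics): every downstream operator depends only on
# distances, labels, axes and intensities, not on fold or tissue realism.

#' Generate a synthetic two-chain multi-domain complex
#'
#' Builds two antiparallel helical poly-alanine-like chains (atoms N, CA,
#' C, O, CB per residue) segmented into equal-size domains named
#' "EC1", "EC2", ..., separated widely enough that the only interchain
#' contacts are the planted ones. Each planted contact relocates one
#' designated atom per chain to lie at exactly the requested distance in
#' the inter-chain gap; a hinge bend rigidly rotates one domain about the
#' interdomain linker.
#'
#' @param domains_per_chain domains per chain (default 4).
#' @param residues_per_domain residues per domain (default 24).
#' @param planted_contacts list of contacts, each a list with `domain_A`,
#'   `domain_B` (labels on chains A and B), `kind` ("hbond",
#'   "salt_bridge" or "vdw") and `distance` (Angstrom).
#' @param hinge_bend `NULL`, or list(`chain`, `domain`, `degrees`): rigid
#'   rotation of that domain about the linker to its neighbour
#'   (0-180 degrees).
#' @param chain_sep distance between the chain axes in Angstrom (default
#'   40; planted distances must stay below half of it).
#' @param jitter coordinate jitter s.d. in Angstrom (default 0.05),
#'   seeded, applied before planting so planted distances stay exact.
#' @param seed integer seed.
#' @return list with `structure` (a [structure3d()], chains "A" and "B"),
#'   `annotation` (a [domain_annotation()]), `contacts` (ground-truth
#'   data.frame: kind, chain/resno/atom on both sides, domains, distance)
#'   and `spec` (the arguments).
#' @export
make_toy_complex <- function(domains_per_chain = 4L,
                             residues_per_domain = 24L,
                             planted_contacts = list(),
                             hinge_bend = NULL, chain_sep = 40,
                             jitter = 0.05, seed = 1L) {
  stopifnot(domains_per_chain >= 1L, residues_per_domain >= 6L)
  for (pc in planted_contacts) {
    for (dom in c(pc$domain_A, pc$domain_B)) {
      dnum <- suppressWarnings(as.integer(sub("EC", "", dom)))
      if (is.na(dnum) || dnum < 1L || dnum > domains_per_chain)
        stop("planted contact references absent domain: ", dom)
    }
    if (pc$distance <= 0) stop("planted contact distance must be positive")
    if (pc$distance >= chain_sep / 2)
      stop("planted contact distance ", pc$distance,
           " A is incompatible with a chain separation of ", chain_sep, " A")
  }
  if (!is.null(hinge_bend) &&
      (hinge_bend$degrees < 0 || hinge_bend$degrees > 180))
    stop("hinge bend must be in [0, 180] degrees")
  set.seed(as.integer(seed))
  n_res <- domains_per_chain * residues_per_domain
  rise <- 3.0; radius <- 2.3; turn <- 100 * pi / 180
  build_chain <- function() {
    # helical CA trace with fixed intra-residue offsets
    do.call(rbind, lapply(seq_len(n_res), function(i) {
      th <- i * turn
      ca <- c(radius * cos(th), radius * sin(th), i * rise)
      u <- c(cos(th), sin(th), 0)          # radial unit vector
      data.frame(resno = i,
                 elety = c("N", "CA", "C", "O", "CB"),
                 x = ca[1] + c(-0.8 * u[1], 0, 0.8 * u[1], 1.2 * u[1],
                               1.5 * u[1]),
                 y = ca[2] + c(-0.8 * u[2], 0, 0.8 * u[2], 1.2 * u[2],
                               1.5 * u[2]),
                 z = ca[3] + c(-1.2, 0, 1.2, 1.9, 0.3))
    }))
  }
  a <- build_chain(); b <- build_chain()
  # antiparallel partner chain across the inter-chain gap
  zmax <- (n_res + 1) * rise
  b$x <- chain_sep - b$x
  b$z <- zmax - b$z
  a$chain <- "A"; b$chain <- "B"
  at <- rbind(a, b)
  at$resid <- "ALA"
  at$x <- at$x + rnorm(nrow(at), 0, jitter)
  at$y <- at$y + rnorm(nrow(at), 0, jitter)
  at$z <- at$z + rnorm(nrow(at), 0, jitter)

  dom_of <- function(resno)
    paste0("EC", (resno - 1L) %/% residues_per_domain + 1L)
  ann <- domain_annotation(data.frame(
    chain = rep(c("A", "B"), each = domains_per_chain),
    domain = rep(paste0("EC", seq_len(domains_per_chain)), 2L),
    start = rep((seq_len(domains_per_chain) - 1L) * residues_per_domain +
                  1L, 2L),
    end = rep(seq_len(domains_per_chain) * residues_per_domain, 2L)))

  if (!is.null(hinge_bend)) {
    dnum <- as.integer(sub("EC", "", hinge_bend$domain))
    if (is.na(dnum) || dnum < 1L || dnum > domains_per_chain)
      stop("hinge domain not present: ", hinge_bend$domain)
    ch <- hinge_bend$chain
    sel <- at$chain == ch &
      dom_of(at$resno) == hinge_bend$domain
    # pivot at the linker between this domain and its inboard neighbour
    pivot_res <- if (dnum == 1L) residues_per_domain + 1L
                 else (dnum - 1L) * residues_per_domain
    pivot <- colMeans(at[at$chain == ch & at$resno == pivot_res,
                         c("x", "y", "z")])
    th <- hinge_bend$degrees * pi / 180
    R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
                3L, 3L)                    # rotation about the y axis
    xyz <- t(t(as.matrix(at[sel, c("x", "y", "z")])) - pivot)
    at[sel, c("x", "y", "z")] <- t(R %*% t(xyz) + pivot)
  }

  truth <- NULL
  mid_res <- function(domain)
    (as.integer(sub("EC", "", domain)) - 1L) * residues_per_domain +
      residues_per_domain %/% 2L
  atom_kinds <- list(
    hbond = list(resid = c("ALA", "ALA"), elety = c("N", "O")),
    salt_bridge = list(resid = c("LYS", "ASP"), elety = c("NZ", "OD1")),
    vdw = list(resid = c("ALA", "ALA"), elety = c("CB", "CB")))
  for (k in seq_along(planted_contacts)) {
    pc <- planted_contacts[[k]]
    ak <- atom_kinds[[pc$kind]]
    if (is.null(ak)) stop("unknown contact kind: ", pc$kind)
    rA <- mid_res(pc$domain_A) + (k - 1L) %% residues_per_domain %/% 2L
    rB <- mid_res(pc$domain_B) + (k - 1L) %% residues_per_domain %/% 2L
    yk <- 10 * (k - 1L)
    zk <- mean(at$z[at$chain == "A" & at$resno == rA])
    # mutate residue identities so contact chemistry matches the kind
    if (ak$resid[1L] != "ALA")
      at$resid[at$chain == "A" & at$resno == rA] <- ak$resid[1L]
    if (ak$resid[2L] != "ALA")
      at$resid[at$chain == "B" & at$resno == rB] <- ak$resid[2L]
    add_atom <- function(chain, resno, elety) {
      if (!any(at$chain == chain & at$resno == resno &
                 at$elety == elety)) {
        tmpl <- at[at$chain == chain & at$resno == resno, ][1L, ]
        tmpl$elety <- elety
        at <<- rbind(at, tmpl)
      }
    }
    add_atom("A", rA, ak$elety[1L])
    add_atom("B", rB, ak$elety[2L])
    iA <- which(at$chain == "A" & at$resno == rA & at$elety == ak$elety[1L])
    iB <- which(at$chain == "B" & at$resno == rB & at$elety == ak$elety[2L])
    at[iA, c("x", "y", "z")] <- c(chain_sep / 2 - pc$distance / 2, yk, zk)
    at[iB, c("x", "y", "z")] <- c(chain_sep / 2 + pc$distance / 2, yk, zk)
    truth <- rbind(truth, data.frame(
      kind = pc$kind, chain_A = "A", resno_A = rA,
      resid_A = ak$resid[1L], elety_A = ak$elety[1L],
      domain_A = pc$domain_A, chain_B = "B", resno_B = rB,
      resid_B = ak$resid[2L], elety_B = ak$elety[2L],
      domain_B = pc$domain_B, distance = pc$distance,
      stringsAsFactors = FALSE))
  }
  at$element <- substr(at$elety, 1L, 1L)
  at$insert <- ""
  at$is_het <- FALSE
  st <- structure3d(at, id = sprintf("toy_complex_seed%d", seed))
  st <- assign_domains(st, ann)
  list(structure = st, annotation = ann, contacts = truth,
       spec = list(domains_per_chain = domains_per_chain,
                   residues_per_domain = residues_per_domain,
                   planted_contacts = planted_contacts,
                   hinge_bend = hinge_bend, chain_sep = chain_sep,
                   jitter = jitter, seed = seed))
}

#' Generate a synthetic multiple sequence alignment
#'
#' Conserved columns carry one (seeded) residue shared by every row; all
#' other columns are sampled uniformly over the 20 amino acids per row. A
#' Four-jointed phosphomotif (D-X-N-D-[X]7-S, 12 columns) can be planted
#' into every row at a stated position; its constrained positions are
#' written identically in all rows, the seven spacer positions and X vary
#' per row.
#'
#' @param n_rows sequences (>= 2).
#' @param length alignment columns.
#' @param conserved_columns integer vector of fully conserved columns.
#' @param motif_plant optional 1-based start column for the planted motif.
#' @param seed integer seed.
#' @return An [msa()] with attributes `conserved_columns` and
#'   `motif_start` (ground truth).
#' @export
make_msa <- function(n_rows = 18L, length = 60L,
                     conserved_columns = integer(), motif_plant = NULL,
                     seed = 1L) {
  if (n_rows < 2L) stop("n_rows must be >= 2")
  if (!is.null(motif_plant) && motif_plant + 11L > length)
    stop("planted motif at ", motif_plant, " overruns sequence end")
  if (base::length(conserved_columns) &&
      (min(conserved_columns) < 1L || max(conserved_columns) > length))
    stop("conserved column outside alignment")
  set.seed(as.integer(seed))
  m <- matrix(sample(AA20, n_rows * length, replace = TRUE),
              nrow = n_rows)
  for (j in conserved_columns) m[, j] <- sample(AA20, 1L)
  if (!is.null(motif_plant)) {
    m[, motif_plant] <- "D"
    m[, motif_plant + 2L] <- "N"
    m[, motif_plant + 3L] <- "D"
    m[, motif_plant + 11L] <- "S"
  }
  out <- msa(setNames(apply(m, 1L, paste0, collapse = ""),
                      sprintf("homolog_%02d", seq_len(n_rows))))
  attr(out, "conserved_columns") <- sort(unique(c(
    conserved_columns,
    if (!is.null(motif_plant))
      motif_plant + c(0L, 2L, 3L, 11L))))
  attr(out, "motif_start") <- motif_plant
  out
}

#' Generate a synthetic two-channel cell-field image
#'
#' A jittered polygonal cell mosaic: cell-cell boundaries are straight-ish
#' polylines through jittered grid vertices (so the true boundary set is
#' known exactly), and each channel is
#' `background * (1 + max(f - 1, 0) * K(d)) + noise`, where `d` is the
#' pixel's distance to the nearest enriched boundary and the kernel `K`
#' is 1 within the characteristic boundary half-width and falls off as a
#' 1-pixel Gaussian shoulder beyond it. A factor `f <= 1` means no
#' enrichment; `f` is the peak fold-intensity of the border over the
#' background.
#'
#' @param image_shape c(rows, cols) (default c(128, 128)).
#' @param n_cells approximate cell count (>= 2; realised as a grid mosaic
#'   with at least this many cells).
#' @param border_enrichment length-2 numeric: peak fold-enrichment of
#'   channels A and B (>= 0).
#' @param background background intensity (default 100).
#' @param noise_sd Gaussian noise s.d. (default 2; intensities clipped at
#'   0).
#' @param border_width characteristic boundary half-width in pixels
#'   (default 2.5).
#' @param enrich_subset_A,enrich_subset_B optional integer vectors of
#'   polyline indices that are enriched in each channel (`NULL` = all),
#'   for planting coincident vs disjoint border signals.
#' @param seed integer seed.
#' @return list with `channels` (list of two matrices), `boundaries` (a
#'   [boundary_set()]) and `truth` (factors, width, subsets, cell count).
#' @export
make_cell_image <- function(image_shape = c(128L, 128L), n_cells = 9L,
                            border_enrichment = c(3, 3),
                            background = 100, noise_sd = 2,
                            border_width = 2.5,
                            enrich_subset_A = NULL,
                            enrich_subset_B = NULL, seed = 1L) {
  if (n_cells < 2L) stop("n_cells must be >= 2")
  stopifnot(all(image_shape > 8L), all(is.finite(border_enrichment)),
            all(border_enrichment >= 0), background > 0, noise_sd >= 0)
  set.seed(as.integer(seed))
  gr <- max(1L, round(sqrt(n_cells)))
  gc <- ceiling(n_cells / gr)
  rows <- image_shape[1L]; cols <- image_shape[2L]
  margin <- 2
  vr <- seq(margin, rows - 1 - margin, length.out = gr + 1L)
  vc <- seq(margin, cols - 1 - margin, length.out = gc + 1L)
  jit <- min(diff(vr), diff(vc)) * 0.15
  vert_r <- outer(vr, rep(1, gc + 1L))
  vert_c <- outer(rep(1, gr + 1L), vc)
  interior_r <- if (gr > 1L) 2:gr else integer(0)
  interior_c <- if (gc > 1L) 2:gc else integer(0)
  if (gr > 1L)
    vert_r[interior_r, ] <- vert_r[interior_r, ] +
      matrix(runif((gr - 1L) * (gc + 1L), -jit, jit), gr - 1L)
  if (gc > 1L)
    vert_c[, interior_c] <- vert_c[, interior_c] +
      matrix(runif((gr + 1L) * (gc - 1L), -jit, jit), ncol = gc - 1L)
  polylines <- list()
  # interior horizontal grid lines (cell-cell borders), one polyline each
  for (i in interior_r)
    polylines <- c(polylines, list(cbind(vert_r[i, ], vert_c[i, ])))
  for (j in interior_c)
    polylines <- c(polylines, list(cbind(vert_r[, j], vert_c[, j])))
  if (!length(polylines))
    stop("mosaic has no interior boundaries; increase n_cells")
  bs <- boundary_set(polylines, image_shape)

  dist_to <- function(subset) {
    sub <- if (is.null(subset)) bs
           else boundary_set(bs$polylines[subset], image_shape)
    core <- rasterize_boundaries(sub)
    dist_transform(core)
  }
  kernel <- function(d)
    ifelse(d <= border_width, 1, exp(-(d - border_width)^2 / 2))
  channel <- function(f, subset) {
    base <- matrix(background, rows, cols)
    if (f > 1) {
      K <- kernel(dist_to(subset))
      base <- background * (1 + (f - 1) * K)
    }
    # first arg carries the dim attribute through pmax
    pmax(base + matrix(rnorm(rows * cols, 0, noise_sd), rows, cols), 0)
  }
  chA <- channel(border_enrichment[1L], enrich_subset_A)
  chB <- channel(border_enrichment[2L], enrich_subset_B)
  list(channels = list(A = chA, B = chB), boundaries = bs,
       truth = list(border_enrichment = border_enrichment,
                    background = background, noise_sd = noise_sd,
                    border_width = border_width,
                    enrich_subset_A = enrich_subset_A,
                    enrich_subset_B = enrich_subset_B,
                    n_cells = gr * gc, seed = seed))
}

# Euclidean distance transform: distance of every pixel to the nearest
# TRUE pixel of `core` (exact brute force over core pixels, vectorised per
# core pixel; core sets are small line rasters)
dist_transform <- function(core) {
  sh <- dim(core)
  idx <- which(core, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(Inf, sh[1], sh[2]))
  rr <- matrix(seq_len(sh[1]), sh[1], sh[2])
  cc <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
  d2 <- matrix(Inf, sh[1], sh[2])
  for (k in seq_len(nrow(idx))) {
    cand <- (rr - idx[k, 1])^2 + (cc - idx[k, 2])^2
    d2 <- pmin(d2, cand)
  }
  sqrt(d2)
}

#' Write a complete fixture suite to a directory
#'
#' Emits one of everything the pipeline consumes: a toy complex (PDB +
#' domain JSON + ground-truth contact TSV), a synthetic MSA (FASTA), a
#' simulated thermogram (CSV + JSON) and a synthetic two-channel image
#' (TIFF + boundary JSON + truth JSON). All generators are seeded from
#' `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture_suite <- function(dir, seed = 7L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(dir, ...)
  toy <- make_toy_complex(
    planted_contacts = list(
      list(domain_A = "EC2", domain_B = "EC3", kind = "hbond",
           distance = 3.0),
      list(domain_A = "EC4", domain_B = "EC1", kind = "salt_bridge",
           distance = 3.2),
      list(domain_A = "EC3", domain_B = "EC2", kind = "vdw",
           distance = 5.0)),
    seed = seed)
  write_structure(toy$structure, f("toy_complex.pdb"))
  jsonlite::write_json(toy$annotation, f("toy_domains.json"),
                       dataframe = "rows", digits = NA)
  utils::write.table(toy$contacts, f("toy_contacts_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  aln <- make_msa(n_rows = 18L, length = 60L,
                  conserved_columns = c(5L, 10L, 15L), motif_plant = 30L,
                  seed = seed)
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), f("toy_msa.fasta"))
  tg <- simulate_thermogram(
    itc_params(n = 1, K = 1 / 0.47e-6, delta_H = -8000),
    noise_sd = 0.15, seed = seed)
  write_thermogram(tg, f("toy_thermogram.csv"))
  img <- make_cell_image(seed = seed)
  # 16-bit TIFF, channels stacked; intensities scaled by the recorded factor
  scale <- 4 * max(unlist(img$channels))
  arr <- array(0, dim = c(ncol(img$channels$A), nrow(img$channels$A), 2L))
  arr[, , 1L] <- t(img$channels$A) / scale
  arr[, , 2L] <- t(img$channels$B) / scale
  EBImage::writeImage(EBImage::Image(arr), f("toy_image.tif"),
                      type = "tiff", bits.per.sample = 16L)
  write_boundaries(img$boundaries, f("toy_boundaries.json"))
  jsonlite::write_json(c(img$truth, list(intensity_scale = scale)),
                       f("toy_image_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(pdb = f("toy_complex.pdb"), domains = f("toy_domains.json"),
              contacts = f("toy_contacts_truth.tsv"),
              msa = f("toy_msa.fasta"),
              thermogram = f("toy_thermogram.csv"),
              image = f("toy_image.tif"),
              boundaries = f("toy_boundaries.json"),
              image_truth = f("toy_image_truth.json")))
}
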