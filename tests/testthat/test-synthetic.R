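test_that("generators are seed-deterministic", {
  pc <- planted_contact_list(2L, 1L)
  t1 <- make_toy_complex(planted_contacts = pc, seed = 4L)
  t2 <- make_toy_complex(planted_contacts = pc, seed = 4L)
  expect_identical(t1$structure$atoms, t2$structure$atoms)
  t3 <- make_toy_complex(planted_contacts = pc, seed = 5L)
  expect_false(identical(t1$structure$atoms, t3$structure$atoms))
  expect_identical(make_msa(seed = 4L), make_msa(seed = 4L))
  i1 <- make_cell_image(seed = 4L)
  i2 <- make_cell_image(seed = 4L)
  expect_identical(i1$channels, i2$channels)
})

test_that("toy complex bookkeeping matches its own ground truth", {
  pc <- planted_contact_list(3L, 2L, dist_hb = 3.1, dist_sb = 3.6)
  toy <- make_toy_complex(planted_contacts = pc, seed = 6L)
  st <- toy$structure
  expect_equal(st$chains, c("A", "B"))
  a <- st$atoms
  # every planted contact's atom pair sits at exactly the planted distance
  for (k in seq_len(nrow(toy$contacts))) {
    tr <- toy$contacts[k, ]
    pa <- a[a$chain == "A" & a$resno == tr$resno_A & a$elety == tr$elety_A, ]
    pb <- a[a$chain == "B" & a$resno == tr$resno_B & a$elety == tr$elety_B, ]
    expect_equal(sqrt(sum((pa[, c("x", "y", "z")] -
                             pb[, c("x", "y", "z")])^2)),
                 tr$distance, tolerance = 1e-9)
    expect_equal(pa$resid, tr$resid_A)
    expect_equal(pa$domain, tr$domain_A)
  }
  # domain annotation covers every residue
  expect_false(any(a$domain == "linker"))
  expect_equal(sort(unique(a$domain)), paste0("EC", 1:4))
})

test_that("toy complex rejects impossible requests", {
  expect_error(make_toy_complex(planted_contacts = list(
    list(domain_A = "EC1", domain_B = "EC1", kind = "hbond",
         distance = 25))), "chain separation")
  expect_error(make_toy_complex(planted_contacts = list(
    list(domain_A = "EC1", domain_B = "EC1", kind = "covalent",
         distance = 2))), "unknown contact kind")
  expect_error(make_toy_complex(domains_per_chain = 2L,
                                planted_contacts = list(
    list(domain_A = "EC1", domain_B = "EC3", kind = "hbond",
         distance = 3))), "absent domain")
  expect_error(make_toy_complex(hinge_bend = list(chain = "A",
                                                  domain = "EC1",
                                                  degrees = 270)),
               "0, 180")
  expect_error(make_toy_complex(hinge_bend = list(chain = "A",
                                                  domain = "EC9",
                                                  degrees = 20)),
               "hinge domain")
})

test_that("synthetic MSA plants conserved columns and the motif", {
  aln <- make_msa(n_rows = 8L, length = 40L, conserved_columns = c(2L, 9L),
                  motif_plant = 20L, seed = 7L)
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  for (j in c(2L, 9L)) expect_equal(length(unique(m[, j])), 1L)
  expect_true(all(m[, 20] == "D" & m[, 22] == "N" & m[, 23] == "D" &
                    m[, 31] == "S"))
  expect_equal(attr(aln, "motif_start"), 20L)
  expect_true(all(c(2L, 9L, 20L) %in% attr(aln, "conserved_columns")))
  expect_error(make_msa(length = 20L, motif_plant = 15L), "overruns")
  expect_error(make_msa(n_rows = 1L), "n_rows")
})

test_that("synthetic images honour the planted enrichment model", {
  flat <- make_cell_image(image_shape = c(64, 64), n_cells = 4L,
                          border_enrichment = c(1, 1), noise_sd = 0,
                          seed = 8L)
  expect_equal(dim(flat$channels$A), c(64, 64))
  expect_true(all(flat$channels$A == 100))
  expect_true(all(flat$channels$B == 100))
  rich <- make_cell_image(image_shape = c(64, 64), n_cells = 4L,
                          border_enrichment = c(4, 1), noise_sd = 0,
                          seed = 8L)
  core <- fatdachs:::rasterize_boundaries(rich$boundaries)
  # peak fold-enrichment on the boundary core, background far away
  expect_equal(mean(rich$channels$A[core]) / 100, 4, tolerance = 1e-9)
  expect_true(all(rich$channels$B == 100))
  far <- fatdachs:::dist_transform(core) > 10
  expect_equal(max(abs(rich$channels$A[far] - 100)), 0, tolerance = 1e-6)
  expect_error(make_cell_image(n_cells = 1L), "n_cells")
})

test_that("subset enrichment separates coincident from disjoint signals", {
  np <- length(make_cell_image(seed = 9L)$boundaries$polylines)
  subA <- seq_len(ceiling(np / 2))
  subB <- setdiff(seq_len(np), subA)
  dis <- make_cell_image(border_enrichment = c(5, 5), noise_sd = 1,
                         enrich_subset_A = subA, enrich_subset_B = subB,
                         seed = 9L)
  coi <- make_cell_image(border_enrichment = c(5, 5), noise_sd = 1,
                         enrich_subset_A = subA, enrich_subset_B = subA,
                         seed = 9L)
  s_dis <- border_stats(dis$channels$A, dis$channels$B, dis$boundaries)
  s_coi <- border_stats(coi$channels$A, coi$channels$B, coi$boundaries)
  expect_gt(s_coi$complexes, s_dis$complexes)
})

test_that("the fixture suite is complete and every artifact reads back", {
  dir <- tempfile("fixtures")
  files <- write_fixture_suite(dir, seed = 7L)
  expect_true(all(file.exists(files)))
  st <- read_structure(files[["pdb"]])
  st <- assign_domains(st, read_domain_config(files[["domains"]]))
  expect_equal(st$chains, c("A", "B"))
  truth <- utils::read.delim(files[["contacts"]])
  rep_ <- interface_report(st, "A", "B")
  expect_equal(unname(rep_$counts[["hbond"]]),
               sum(truth$kind == "hbond"))
  expect_equal(unname(rep_$counts[["salt_bridge"]]),
               sum(truth$kind == "salt_bridge"))
  aln <- read_msa(files[["msa"]])
  expect_equal(aln$length, 60L)
  tg <- read_thermogram(files[["thermogram"]])
  fit <- fit_one_site(tg)
  expect_true(fit$converged)
  expect_lt(abs(fit$Kd_uM - 0.47) / 0.47, 0.25)   # 0.15 ucal noise
  ch <- read_channels(files[["image"]])
  expect_length(ch, 2L)
  bs <- read_boundaries(files[["boundaries"]])
  expect_equal(dim(ch[[1]]), unname(bs$image_shape))
  img_truth <- jsonlite::fromJSON(files[["image_truth"]])
  # 16-bit quantised intensities still recover the planted enrichment
  core <- fatdachs:::rasterize_boundaries(bs)
  lvl <- mean(ch[[1]][core]) * img_truth$intensity_scale
  expect_equal(lvl / img_truth$background, img_truth$border_enrichment[1],
               tolerance = 0.05)
})
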