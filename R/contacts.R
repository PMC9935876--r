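# Heavy-atom polar-contact chemistry tables. Deposited models carry no
# hydrogens, so donors/acceptors are identified by residue and atom name and
# contacts are distance-only by default.

hb_donor_table <- function() {
  list(backbone = "N",   # all residues except proline
       ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
       ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH",
       TRP = "NE1")
}

hb_acceptor_table <- function() {
  list(backbone = c("O", "OXT"),
       ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
       GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
       HIS = c("ND1", "NE2"), MET = NULL)
}

basic_n_table <- function() {
  list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"))
}

acidic_o_table <- function() {
  list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
}

atom_in_table <- function(atoms, tab, include_backbone = TRUE) {
  hit <- rep(FALSE, nrow(atoms))
  if (include_backbone && !is.null(tab$backbone))
    hit <- hit | (!atoms$is_het & atoms$elety %in% tab$backbone)
  for (res in setdiff(names(tab), "backbone")) {
    if (is.null(tab[[res]])) next
    hit <- hit | (atoms$resid == res & atoms$elety %in% tab[[res]])
  }
  hit
}

is_hb_donor <- function(atoms) {
  d <- atom_in_table(atoms, hb_donor_table())
  d & !(atoms$resid == "PRO" & atoms$elety == "N")   # proline N has no H
}

is_hb_acceptor <- function(atoms) atom_in_table(atoms, hb_acceptor_table())
is_basic_n <- function(atoms) atom_in_table(atoms, basic_n_table(),
                                            include_backbone = FALSE)
is_acidic_o <- function(atoms) atom_in_table(atoms, acidic_o_table(),
                                             include_backbone = FALSE)

contact_record <- function(atoms, ia, ib, dist, kind) {
  data.frame(kind = kind,
             chain_A = atoms$chain[ia], resno_A = atoms$resno[ia],
             resid_A = atoms$resid[ia], elety_A = atoms$elety[ia],
             domain_A = atoms$domain[ia],
             chain_B = atoms$chain[ib], resno_B = atoms$resno[ib],
             resid_B = atoms$resid[ib], elety_B = atoms$elety[ib],
             domain_B = atoms$domain[ib],
             distance = dist, stringsAsFactors = FALSE)
}

cross_chain_pairs <- function(struct, chain_A, chain_B, cutoff) {
  a <- struct$atoms
  for (ch in c(chain_A, chain_B))
    if (!ch %in% struct$chains) stop("chain absent from structure: ", ch)
  iA <- which(a$chain == chain_A)
  iB <- which(a$chain == chain_B)
  m <- .pairs_within_cpp(as.matrix(a[iA, c("x", "y", "z")]),
                         as.matrix(a[iB, c("x", "y", "z")]), cutoff)
  list(atoms = a, ia = iA[m[, 1]], ib = iB[m[, 2]], dist = m[, 3])
}

#' Interchain hydrogen bonds (heavy-atom criterion)
#'
#' Donor-acceptor pairs where one heavy atom is a donor-bearing N/O and the
#' other an acceptor N/O, at heavy-atom distance `<= d_max`. Pairs that also
#' qualify as salt bridges (basic-group N against acidic-group O) are
#' excluded here and reported by [find_salt_bridges()] instead. An optional
#' acceptor-angle filter rejects geometrically implausible pairs.
#'
#' @param complex a [structure3d()].
#' @param chain_A,chain_B chain identifiers.
#' @param d_max heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param min_angle optional minimum donor-acceptor-acceptor-antecedent
#'   angle in degrees; `NULL` (default) disables the angle term.
#' @return data.frame of contact records (one row per qualifying atom pair)
#'   with chain/residue/atom identities, domains and distances.
#' @export
find_hydrogen_bonds <- function(complex, chain_A, chain_B, d_max = 3.5,
                                min_angle = NULL) {
  p <- cross_chain_pairs(complex, chain_A, chain_B, d_max)
  a <- p$atoms
  don <- is_hb_donor(a); acc <- is_hb_acceptor(a)
  sb <- (is_basic_n(a)[p$ia] & is_acidic_o(a)[p$ib]) |
    (is_acidic_o(a)[p$ia] & is_basic_n(a)[p$ib])
  ok <- ((don[p$ia] & acc[p$ib]) | (acc[p$ia] & don[p$ib])) & !sb &
    p$dist > 0
  out <- contact_record(a, p$ia[ok], p$ib[ok], p$dist[ok], "hbond")
  if (!is.null(min_angle) && nrow(out) > 0) {
    keep <- vapply(seq_len(nrow(out)), function(k) {
      acceptor_angle_ok(a, p$ia[ok][k], p$ib[ok][k], min_angle)
    }, logical(1L))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# angle at the acceptor between its bonded antecedent (nearest same-residue
# heavy atom) and the donor; loose plausibility screen
acceptor_angle_ok <- function(atoms, ia, ib, min_angle) {
  same <- which(atoms$chain == atoms$chain[ib] &
                  atoms$resno == atoms$resno[ib] &
                  atoms$insert == atoms$insert[ib])
  same <- setdiff(same, ib)
  if (!length(same)) return(TRUE)
  b <- as.numeric(atoms[ib, c("x", "y", "z")])
  d2 <- colSums((t(as.matrix(atoms[same, c("x", "y", "z")])) - b)^2)
  ante <- as.numeric(atoms[same[which.min(d2)], c("x", "y", "z")])
  don <- as.numeric(atoms[ia, c("x", "y", "z")])
  v1 <- ante - b; v2 <- don - b
  ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  ang >= min_angle
}

#' Interchain salt bridges
#'
#' Basic-group nitrogens (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2 — histidine is
#' treated as charged) within `d_max` of acidic-group oxygens (Asp OD1/OD2,
#' Glu OE1/OE2). By default one record is reported per residue pair, using
#' the minimum-distance atom pair, matching how salt-bridge networks are
#' conventionally counted; `per_atom = TRUE` expands to all atom pairs.
#'
#' @param complex a [structure3d()].
#' @param chain_A,chain_B chain identifiers.
#' @param d_max distance cutoff in Angstrom (default 4.0).
#' @param per_atom report every qualifying atom pair instead of one per
#'   residue pair.
#' @return data.frame of contact records.
#' @export
find_salt_bridges <- function(complex, chain_A, chain_B, d_max = 4.0,
                              per_atom = FALSE) {
  p <- cross_chain_pairs(complex, chain_A, chain_B, d_max)
  a <- p$atoms
  ok <- ((is_basic_n(a)[p$ia] & is_acidic_o(a)[p$ib]) |
           (is_acidic_o(a)[p$ia] & is_basic_n(a)[p$ib])) & p$dist > 0
  out <- contact_record(a, p$ia[ok], p$ib[ok], p$dist[ok], "salt_bridge")
  if (!per_atom && nrow(out) > 0) {
    key <- paste(out$chain_A, out$resno_A, out$chain_B, out$resno_B)
    out <- do.call(rbind, lapply(split(out, key), function(g) {
      g[which.min(g$distance), , drop = FALSE]
    }))
    out <- out[order(out$resno_A, out$resno_B), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Minimum interchain heavy-atom distance per cross-chain domain pair
#'
#' @param complex a domain-annotated [structure3d()] (see
#'   [assign_domains()]).
#' @param chain_A,chain_B chain identifiers; default first two chains.
#' @return data.frame with one row per cross-chain domain pair: the minimum
#'   interchain heavy-atom distance and the realizing atom pair.
#' @export
min_domain_distances <- function(complex, chain_A = NULL, chain_B = NULL) {
  stopifnot(inherits(complex, "structure3d"))
  if (is.null(chain_A)) chain_A <- complex$chains[1L]
  if (is.null(chain_B)) chain_B <- complex$chains[2L]
  a <- complex$atoms
  if (all(is.na(a$domain)))
    stop("structure is not domain-annotated; call assign_domains() first")
  iA <- which(a$chain == chain_A)
  iB <- which(a$chain == chain_B)
  out <- NULL
  for (dA in sort(unique(a$domain[iA]))) {
    for (dB in sort(unique(a$domain[iB]))) {
      sA <- iA[a$domain[iA] == dA]
      sB <- iB[a$domain[iB] == dB]
      md <- .min_dist_cpp(as.matrix(a[sA, c("x", "y", "z")]),
                          as.matrix(a[sB, c("x", "y", "z")]))
      ia <- sA[md[2]]; ib <- sB[md[3]]
      out <- rbind(out, data.frame(
        domain_A = dA, domain_B = dB, min_distance = md[1],
        chain_A = chain_A, resno_A = a$resno[ia], resid_A = a$resid[ia],
        elety_A = a$elety[ia],
        chain_B = chain_B, resno_B = a$resno[ib], resid_B = a$resid[ib],
        elety_B = a$elety[ib], stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Select atoms of a structure by chain, residue and atom-name predicates
#'
#' @param struct a [structure3d()].
#' @param chain,resno,resid,elety,domain optional vectors restricting the
#'   selection; `NULL` leaves the field unconstrained.
#' @return Integer vector of atom-row indices.
#' @export
atom_select <- function(struct, chain = NULL, resno = NULL, resid = NULL,
                        elety = NULL, domain = NULL) {
  a <- struct$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  if (!is.null(resno)) sel <- sel & a$resno %in% resno
  if (!is.null(resid)) sel <- sel & a$resid %in% resid
  if (!is.null(elety)) sel <- sel & a$elety %in% elety
  if (!is.null(domain)) sel <- sel & !is.na(a$domain) & a$domain %in% domain
  which(sel)
}

#' Minimum distance between two atom selections
#'
#' Exact minimum over the cross-product of two selections, with the
#' realizing atom pair — e.g. a modeled phosphate's oxygens against an
#' arginine guanidinium group.
#'
#' @param struct a [structure3d()].
#' @param selection_A,selection_B either integer atom-row indices (from
#'   [atom_select()]) or named lists of predicates passed to [atom_select()].
#' @return list with `distance` (Angstrom), `atom_A`, `atom_B` (one-row
#'   data.frames).
#' @export
distance_query <- function(struct, selection_A, selection_B) {
  resolve <- function(sel, label) {
    if (is.list(sel)) sel <- do.call(atom_select, c(list(struct), sel))
    sel <- as.integer(sel)
    if (!length(sel)) stop("empty selection: ", label)
    sel
  }
  sA <- resolve(selection_A, "selection_A")
  sB <- resolve(selection_B, "selection_B")
  a <- struct$atoms
  md <- .min_dist_cpp(as.matrix(a[sA, c("x", "y", "z")]),
                      as.matrix(a[sB, c("x", "y", "z")]))
  list(distance = md[1],
       atom_A = a[sA[md[2]], , drop = FALSE],
       atom_B = a[sB[md[3]], , drop = FALSE])
}

#' Full interchain contact inventory
#'
#' Bundles hydrogen bonds, salt bridges and per-domain-pair minimum
#' distances into one report, with counts by kind and by domain pair.
#'
#' @param complex a domain-annotated [structure3d()].
#' @param chain_A,chain_B chain identifiers; default first two chains.
#' @param hbond_max,salt_max distance cutoffs in Angstrom.
#' @return An `interface_report` object: list with `contacts` (all records),
#'   `counts` (by kind), `pair_counts` (by domain pair and kind),
#'   `min_distances` (from [min_domain_distances()]) and the cutoffs used.
#' @export
interface_report <- function(complex, chain_A = NULL, chain_B = NULL,
                             hbond_max = 3.5, salt_max = 4.0) {
  stopifnot(inherits(complex, "structure3d"))
  if (is.null(chain_A)) chain_A <- complex$chains[1L]
  if (is.null(chain_B)) chain_B <- complex$chains[2L]
  hb <- find_hydrogen_bonds(complex, chain_A, chain_B, d_max = hbond_max)
  sb <- find_salt_bridges(complex, chain_A, chain_B, d_max = salt_max)
  contacts <- rbind(hb, sb)
  counts <- c(hbond = nrow(hb), salt_bridge = nrow(sb))
  pair_counts <- if (nrow(contacts)) {
    as.data.frame(table(domain_A = contacts$domain_A,
                        domain_B = contacts$domain_B,
                        kind = contacts$kind),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(domain_A = character(), domain_B = character(),
               kind = character(), Freq = integer())
  }
  md <- if (!all(is.na(complex$atoms$domain)))
    min_domain_distances(complex, chain_A, chain_B) else NULL
  structure(list(contacts = contacts, counts = counts,
                 pair_counts = pair_counts, min_distances = md,
                 chain_A = chain_A, chain_B = chain_B,
                 hbond_max = hbond_max, salt_max = salt_max),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("Interface %s:%s — %d hydrogen bonds (<= %.1f A), %d salt bridges (<= %.1f A)\n",
              x$chain_A, x$chain_B, x$counts[["hbond"]], x$hbond_max,
              x$counts[["salt_bridge"]], x$salt_max))
  invisible(x)
}

#' Contact-count sensitivity over cutoff grids
#'
#' Reruns the hydrogen-bond and salt-bridge inventories over grids of
#' distance cutoffs, the standard way to report how strongly the printed
#' counts depend on the (never fully published) criteria.
#'
#' @param complex a [structure3d()].
#' @param chain_A,chain_B chain identifiers.
#' @param hbond_grid,salt_grid numeric vectors of cutoffs (Angstrom).
#' @return data.frame with columns `kind`, `cutoff`, `count`.
#' @export
contact_cutoff_sensitivity <- function(complex, chain_A, chain_B,
                                       hbond_grid = seq(3.3, 3.9, by = 0.1),
                                       salt_grid = seq(3.8, 4.3, by = 0.1)) {
  hb <- data.frame(kind = "hbond", cutoff = hbond_grid,
                   count = vapply(hbond_grid, function(d)
                     nrow(find_hydrogen_bonds(complex, chain_A, chain_B,
                                              d_max = d)), numeric(1L)))
  sb <- data.frame(kind = "salt_bridge", cutoff = salt_grid,
                   count = vapply(salt_grid, function(d)
                     nrow(find_salt_bridges(complex, chain_A, chain_B,
                                            d_max = d)), numeric(1L)))
  rbind(hb, sb)
}
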