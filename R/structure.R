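#' Construct a structure3d object from an atom table
#'
#' The atom table is the package's working representation of a macromolecular
#' model: one row per heavy atom, author residue numbering, element-resolved
#' van der Waals radii.
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer, author
#'   numbering), `insert` (insertion code, "" when none), `resid` (3-letter
#'   residue name), `elety` (atom name), `element`, `x`, `y`, `z` (Angstrom),
#'   `is_het` (logical). A `radius` column is added from the radii table when
#'   absent; a `domain` column defaults to `NA` until [assign_domains()].
#' @param id character label for the structure.
#' @param metadata free-form list (parse warnings, source path, ...).
#' @param radii radii table, see [vdw_radii()].
#' @return An object of class `structure3d`: a list with elements `id`,
#'   `atoms`, `chains` and `metadata`.
#' @export
structure3d <- function(atoms, id = "structure", metadata = list(),
                        radii = vdw_radii()) {
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "is_het")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1L) stop("structure must contain at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    bad <- which(!apply(is.finite(xyz), 1L, all))[1L]
    stop(sprintf("non-finite coordinates for atom %s %s%d %s",
                 atoms$chain[bad], atoms$resid[bad], atoms$resno[bad],
                 atoms$elety[bad]))
  }
  if (!"radius" %in% names(atoms))
    atoms$radius <- element_radius(atoms$element, radii)
  if (any(atoms$radius <= 0)) stop("all van der Waals radii must be positive")
  if (!"domain" %in% names(atoms)) atoms$domain <- NA_character_
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, insertion, atom name) records: ",
         key[duplicated(key)][1L])
  ord <- order(atoms$chain, atoms$resno, atoms$insert,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms,
                 chains = sort(unique(atoms$chain)),
                 metadata = metadata),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d '%s': %d atoms, chains %s\n", x$id,
              nrow(x$atoms), paste(x$chains, collapse = ", ")))
  for (ch in x$chains) {
    a <- x$atoms[x$atoms$chain == ch, ]
    cat(sprintf("  chain %s: %d residues (%d-%d), %d hetero atoms\n", ch,
                length(unique(paste(a$resno, a$insert))),
                min(a$resno), max(a$resno), sum(a$is_het)))
  }
  if (!all(is.na(x$atoms$domain)))
    cat("  domains:", paste(setdiff(unique(stats::na.omit(x$atoms$domain)),
                                    "linker"), collapse = ", "), "\n")
  invisible(x)
}

#' Read a macromolecular structure from mmCIF or PDB
#'
#' Reads all ATOM and HETATM records of the first model. Waters are excluded
#' by default; calcium ions and glycan residues are retained and flagged
#' hetero. Hydrogens are dropped: deposited cadherin models at ~2.3 A carry
#' none and all downstream geometry is heavy-atom based. Alternate locations
#' are resolved to the highest-occupancy conformer (ties: first encountered).
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "mmcif".
#' @param keep_waters keep water molecules (default FALSE).
#' @param id structure label; defaults to the file base name.
#' @param radii radii table, see [vdw_radii()].
#' @return A [structure3d()] object. Multi-model files use model 1 and record
#'   a warning in `metadata$warnings`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_waters = FALSE, id = NULL,
                           radii = vdw_radii()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  warnings <- character()
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  if (format == "pdb") {
    n_models <- sum(grepl("^MODEL", readLines(path, warn = FALSE)))
    if (n_models > 1L)
      warnings <- c(warnings,
                    sprintf("file contains %d models; using model 1", n_models))
  }
  at <- pdb$atom
  # resolve altlocs: keep highest occupancy per (chain, resno, insert, elety)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- suppressWarnings(as.numeric(at$o))
  occ[is.na(occ)] <- 1
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    keep <- unlist(lapply(split(seq_along(key), key), function(ix) {
      ix[which.max(occ[ix])]    # which.max is stable: first of tied maxima
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  insert <- at$insert
  insert[is.na(insert)] <- ""
  is_het <- at$type == "HETATM"
  if (!keep_waters) {
    w <- toupper(at$resid) %in% c("HOH", "WAT", "DOD", "H2O")
    at <- at[!w, , drop = FALSE]; insert <- insert[!w]; is_het <- is_het[!w]
  }
  element <- toupper(trimws(at$elesy))
  blank <- is.na(element) | element == ""
  element[blank] <- guess_element(at$elety[blank], at$resid[blank],
                                  is_het[blank])
  h <- element == "H" | element == "D"
  at <- at[!h, , drop = FALSE]; insert <- insert[!h]
  is_het <- is_het[!h]; element <- element[!h]
  if (nrow(at) == 0L) stop("no heavy atoms parsed from ", path)
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(chain = chain, resno = as.integer(at$resno),
                      insert = insert, resid = toupper(at$resid),
                      elety = at$elety, element = element,
                      x = at$x, y = at$y, z = at$z, is_het = is_het,
                      stringsAsFactors = FALSE)
  structure3d(atoms, id = id %||% sub("\\.[^.]+$", "", basename(path)),
              metadata = list(source = path, format = format,
                              warnings = warnings),
              radii = radii)
}

#' Write a structure to a PDB file
#'
#' Fixture-quality PDB output (3-decimal coordinates); the inverse of
#' [read_structure()] up to coordinate rounding.
#'
#' @param struct a [structure3d()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  a <- struct$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(a$insert == "", NA,
                                                    a$insert),
                   type = ifelse(a$is_het, "HETATM", "ATOM"),
                   elesy = a$element)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define an EC-domain annotation
#'
#' @param entries data.frame with columns `chain`, `domain` (e.g. "EC1"),
#'   `start`, `end` (inclusive author residue numbers).
#' @return A `domain_annotation` object (validated data.frame).
#' @export
domain_annotation <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("chain", "domain", "start", "end")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("domain annotation is missing columns: ",
         paste(miss, collapse = ", "))
  entries$start <- as.integer(entries$start)
  entries$end <- as.integer(entries$end)
  if (any(entries$end < entries$start))
    stop("domain ranges must have end >= start")
  for (ch in unique(entries$chain)) {
    e <- entries[entries$chain == ch, ]
    if (anyDuplicated(e$domain))
      stop("duplicate domain names on chain ", ch)
    e <- e[order(e$start), ]
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stop("overlapping domain ranges on chain ", ch)
  }
  class(entries) <- c("domain_annotation", "data.frame")
  entries
}

#' Read a domain annotation from a JSON or YAML config file
#'
#' The config is a list of records `{chain, domain, start, end}` with
#' inclusive author residue numbers.
#'
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) file.
#' @return A [domain_annotation()] object.
#' @export
read_domain_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path,
                                                  simplifyDataFrame = TRUE)
  if (is.list(recs) && !is.data.frame(recs))
    recs <- do.call(rbind, lapply(recs, as.data.frame,
                                  stringsAsFactors = FALSE))
  domain_annotation(recs)
}

#' Label residues of a structure with EC-domain names
#'
#' Every residue inside an annotated range gets its domain label; residues
#' outside all ranges — interdomain linkers and hetero groups such as the
#' calcium ions that occupy the linker-binding sites — are labeled
#' `"linker"`.  Partial resolution is tolerated: a range extending past the
#' resolved residues labels what is present, but a range containing no
#' resolved residue at all is an error.
#'
#' @param struct a [structure3d()] object.
#' @param domain_defs a [domain_annotation()] (or coercible data.frame).
#' @return The structure with its `atoms$domain` column filled.
#' @export
assign_domains <- function(struct, domain_defs) {
  stopifnot(inherits(struct, "structure3d"))
  defs <- if (inherits(domain_defs, "domain_annotation")) domain_defs
          else domain_annotation(domain_defs)
  a <- struct$atoms
  absent <- setdiff(unique(defs$chain), struct$chains)
  if (length(absent))
    stop("domain annotation references absent chain(s): ",
         paste(absent, collapse = ", "))
  lab <- rep("linker", nrow(a))
  for (i in seq_len(nrow(defs))) {
    sel <- a$chain == defs$chain[i] & !a$is_het &
      a$resno >= defs$start[i] & a$resno <= defs$end[i]
    if (!any(sel))
      stop(sprintf("domain range %s %s (%d-%d) contains no resolved residue",
                   defs$chain[i], defs$domain[i], defs$start[i], defs$end[i]))
    lab[sel] <- defs$domain[i]
  }
  struct$atoms$domain <- lab
  struct$metadata$domain_annotation <- defs
  struct
}

# atom coordinate matrix helper
coords <- function(struct, sel = TRUE) {
  as.matrix(struct$atoms[sel, c("x", "y", "z"), drop = FALSE])
}
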