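AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a multiple sequence alignment object
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths; gaps as "-" or "."). At least two rows.
#' @return An `msa` object: list with `ids`, `seqs` (uppercase, gaps as
#'   "-"), `length`.
#' @export
msa <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    names(sequences) <- paste0("seq", seq_along(sequences))
  seqs <- toupper(gsub("\\.", "-", as.character(sequences)))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences differ in length")
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 c(AA20, "-", "X"))
  if (length(bad))
    stop("invalid alignment characters: ", paste(bad, collapse = ", "))
  structure(list(ids = names(sequences), seqs = unname(seqs),
                 length = nchar(seqs[1L])), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x$seqs), x$length))
  invisible(x)
}

#' Read a multiple sequence alignment (FASTA or Stockholm)
#'
#' @param path alignment file; format from extension (`.sto`/`.stk` =
#'   Stockholm, otherwise FASTA) unless given.
#' @param format "auto", "fasta" or "stockholm".
#' @return An [msa()] object.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm" else "fasta"
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    return(msa(setNames(as.character(ss), names(ss))))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|//|\\s*$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[[`, "", 1L)
  segs <- vapply(parts, `[[`, "", 2L)
  msa(vapply(split(segs, factor(ids, levels = unique(ids))),
             paste0, "", collapse = ""))
}

#' Per-column conservation of an alignment
#'
#' Two scorers, both on [0, 1]:
#' * `entropy` (default): `1 - H(column)/log(20)` with Shannon entropy `H`
#'   over the 20 amino-acid frequencies, gaps excluded from the counts. 1 =
#'   invariant column, 0 = maximally variable.
#' * `sop_blosum`: mean BLOSUM62 substitution score over all row pairs
#'   (gap pairs skipped), min-max normalised across columns.
#'
#' Scores are binned into 9 equal-width conservation grades (category 9 =
#' most conserved), the convention used for structure "painting". Columns
#' that are entirely gaps are flagged and carry `NA` scores; columns more
#' than 50% gap are flagged low-confidence.
#'
#' @param aln an [msa()] object.
#' @param method "entropy" or "sop_blosum".
#' @param reference_row id or index of the row used to map columns onto a
#'   structure (default 1).
#' @return A `conservation_profile`: data.frame-bearing list with
#'   `score`, `category`, `gap_fraction`, `low_confidence`, plus
#'   `reference_row` and `ref_position` (ungapped position of each column
#'   in the reference row; NA at reference gaps).
#' @export
column_conservation <- function(aln, method = c("entropy", "sop_blosum"),
                                reference_row = 1L) {
  stopifnot(inherits(aln, "msa"))
  method <- match.arg(method)
  if (is.character(reference_row))
    reference_row <- match(reference_row, aln$ids)
  if (is.na(reference_row) || reference_row < 1L ||
      reference_row > length(aln$seqs))
    stop("reference row not found in alignment")
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  L <- ncol(m)
  gap_fraction <- colMeans(m == "-")
  score <- numeric(L)
  if (method == "entropy") {
    for (j in seq_len(L)) {
      col <- m[, j]
      col <- col[col %in% AA20]
      if (!length(col)) { score[j] <- NA_real_; next }
      p <- table(col) / length(col)
      H <- -sum(p * log(p))
      score[j] <- 1 - H / log(20)
    }
  } else {
    B <- blosum62_matrix()
    raw <- rep(NA_real_, L)
    for (j in seq_len(L)) {
      col <- m[, j]
      keep <- col %in% rownames(B)
      col <- col[keep]
      n <- length(col)
      if (n < 2L) next
      pairs <- combn(n, 2L)
      raw[j] <- mean(B[cbind(col[pairs[1L, ]], col[pairs[2L, ]])])
    }
    rng <- range(raw, na.rm = TRUE)
    score <- if (diff(rng) > 0) (raw - rng[1L]) / diff(rng)
             else ifelse(is.na(raw), NA_real_, 1)
  }
  category <- ifelse(is.na(score), NA_integer_,
                     pmin(9L, 1L + as.integer(floor(score * 9))))
  ref_chars <- m[reference_row, ]
  ref_position <- rep(NA_integer_, L)
  ref_position[ref_chars != "-"] <- seq_len(sum(ref_chars != "-"))
  structure(list(score = score, category = category,
                 gap_fraction = gap_fraction,
                 gap_only = gap_fraction == 1,
                 low_confidence = gap_fraction > 0.5,
                 method = method,
                 reference_row = aln$ids[reference_row],
                 ref_position = ref_position,
                 ref_residue = ref_chars),
            class = "conservation_profile")
}

# BLOSUM62 from Biostrings, restricted to the 20 standard residues
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA20, AA20]
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("Conservation profile (%s): %d columns, median score %.3f\n",
              x$method, length(x$score),
              stats::median(x$score, na.rm = TRUE)))
  invisible(x)
}

#' Scan a sequence for the Four-jointed phosphorylation motif
#'
#' The Four-jointed (Fj) kinase recognition motif is D-X-N-D-[X]7-S/T: an
#' aspartate, any residue, asparagine, aspartate, seven unconstrained
#' residues, then the phosphoacceptor serine/threonine at position 12 of
#' the window. All (possibly overlapping) matches are reported.
#'
#' @param sequence ungapped amino-acid string (>= 12 residues).
#' @return data.frame with `start` (1-based), `matched_span` (12 residues)
#'   and `phospho_site_position` (`start + 11`); zero rows when no match.
#' @examples
#' scan_fj_motif("DANDAAAAAAAT")
#' @export
scan_fj_motif <- function(sequence) {
  s <- toupper(gsub("[-. ]", "", sequence))
  bad <- setdiff(unique(strsplit(s, "")[[1]]), AA20)
  if (length(bad))
    stop("invalid amino-acid characters: ", paste(bad, collapse = ", "))
  if (nchar(s) < 12L)
    return(data.frame(start = integer(), matched_span = character(),
                      phospho_site_position = integer()))
  hits <- gregexpr("(?=D.ND.{7}[ST])", s, perl = TRUE)[[1L]]
  if (hits[1L] == -1L)
    return(data.frame(start = integer(), matched_span = character(),
                      phospho_site_position = integer()))
  start <- as.integer(hits)
  data.frame(start = start,
             matched_span = substring(s, start, start + 11L),
             phospho_site_position = start + 11L)
}

#' Paint interface residues with conservation grades
#'
#' Projects a conservation profile onto a structure's residues via the
#' profile's reference row: ungapped reference position `i` maps to author
#' residue number `i + offset`. Interface residues are those appearing in
#' the contact inventory (either chain) or, optionally, in a caller-
#' supplied buried-residue set.
#'
#' @param profile a [column_conservation()] result.
#' @param struct a [structure3d()].
#' @param interface an [interface_report()], or NULL to paint without
#'   interface flags.
#' @param chain chain of `struct` the reference row maps onto.
#' @param offset author numbering offset: residue number = ungapped
#'   reference position + offset (default 0; e.g. 42 when the construct
#'   starts at residue 43).
#' @param buried_resno optional integer vector of additional residue
#'   numbers to flag as interface (e.g. a burial footprint).
#' @return data.frame (one row per resolved residue of `chain`):
#'   `resno`, `resid`, `domain`, `is_interface`, `score`, `category`.
#'   Residues without a mapped alignment column carry NA scores.
#' @export
paint_interface <- function(profile, struct, interface = NULL, chain,
                            offset = 0L, buried_resno = integer()) {
  stopifnot(inherits(profile, "conservation_profile"),
            inherits(struct, "structure3d"))
  a <- struct$atoms[struct$atoms$chain == chain & !struct$atoms$is_het, ]
  if (!nrow(a)) stop("chain not found or empty: ", chain)
  res <- unique(a[, c("resno", "insert", "resid", "domain")])
  res <- res[order(res$resno, res$insert), ]
  map_resno <- profile$ref_position + offset
  idx <- match(res$resno, map_resno)
  if (all(is.na(idx)))
    stop(sprintf(
      "reference row maps onto no residue of chain %s (first structure residue %d, first mapped residue %d); check `offset`",
      chain, res$resno[1L], map_resno[which(!is.na(map_resno))[1L]]))
  iface <- res$resno %in% buried_resno
  if (!is.null(interface)) {
    cc <- interface$contacts
    iface <- iface |
      (res$resno %in% cc$resno_A[cc$chain_A == chain]) |
      (res$resno %in% cc$resno_B[cc$chain_B == chain])
  }
  data.frame(resno = res$resno, resid = res$resid, domain = res$domain,
             is_interface = iface,
             score = profile$score[idx],
             category = profile$category[idx])
}

#' Write a per-residue conservation attribute file
#'
#' Plain two-column attribute table (residue number, conservation grade)
#' consumable by molecular viewers for surface colouring, plus the full
#' per-residue TSV.
#'
#' @param painting result of [paint_interface()].
#' @param tsv_path output TSV path.
#' @return `tsv_path`, invisibly.
#' @export
write_conservation_tsv <- function(painting, tsv_path) {
  utils::write.table(painting, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}
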