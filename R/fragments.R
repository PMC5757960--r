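#' Helix fragments and rigid bundles
#'
#' A `Fragment` is an ordered set of residues with per-atom coordinates in
#' nm; a `Bundle` is one or more fragments treated as a rigid unit (all
#' relative C-alpha positions fixed). These are the building blocks for
#' two-bundle association systems.
#'
#' @name fragments
NULL

#' Construct a Fragment
#'
#' @param residue_ids integer vector, strictly increasing, one per residue
#' @param sequence one-letter amino-acid string (length = number of residues)
#' @param atom_names character vector, one per atom (e.g. "CA", "CB")
#' @param elements character vector of element symbols, one per atom
#' @param coords numeric matrix n_atoms x 3, nm
#' @param atom_resno integer vector mapping each atom to its residue id
#' @return object of class `hp_fragment`
#' @export
new_fragment <- function(residue_ids, sequence, atom_names, elements, coords,
                         atom_resno) {
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) == 0L) stop("fragment must contain residues")
  if (any(diff(residue_ids) <= 0L))
    stop("residue_ids must be strictly increasing")
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("coords must be finite")
  n_atoms <- nrow(coords)
  stopifnot(length(atom_names) == n_atoms, length(elements) == n_atoms,
            length(atom_resno) == n_atoms)
  if (nchar(sequence) != length(residue_ids))
    stop("sequence length must equal number of residues")
  # every residue has exactly one C-alpha
  ca <- atom_names == "CA"
  ca_per_res <- table(factor(atom_resno[ca], levels = residue_ids))
  if (any(ca_per_res != 1L))
    stop("every residue must have exactly one CA atom; offending residue(s): ",
         paste(residue_ids[ca_per_res != 1L], collapse = ", "))
  calpha_index <- vapply(residue_ids, function(r)
    which(ca & atom_resno == r), integer(1))
  structure(list(residue_ids = residue_ids, sequence = sequence,
                 atom_names = as.character(atom_names),
                 elements = toupper(as.character(elements)),
                 coords = unname(coords),
                 atom_resno = as.integer(atom_resno),
                 calpha_index = calpha_index),
            class = "hp_fragment")
}

#' @export
print.hp_fragment <- function(x, ...) {
  cat(sprintf("<hp_fragment> %d residues (%d-%d), %d atoms\n",
              length(x$residue_ids), min(x$residue_ids),
              max(x$residue_ids), nrow(x$coords)))
  invisible(x)
}

#' C-alpha coordinates of a fragment (n_res x 3, nm)
#' @param fragment an `hp_fragment`
#' @export
calpha_coords <- function(fragment) {
  fragment$coords[fragment$calpha_index, , drop = FALSE]
}

#' Construct a Bundle from fragments
#'
#' @param fragments list of `hp_fragment`; names are used as fragment ids
#'   (defaults to "F1", "F2", ...)
#' @param rigid logical; relative C-alpha positions treated as fixed
#' @return object of class `hp_bundle`
#' @export
new_bundle <- function(fragments, rigid = TRUE) {
  if (!length(fragments)) stop("bundle needs at least one fragment")
  stopifnot(all(vapply(fragments, inherits, logical(1), "hp_fragment")))
  if (is.null(names(fragments)) || any(names(fragments) == ""))
    names(fragments) <- paste0("F", seq_along(fragments))
  all_res <- unlist(lapply(fragments, `[[`, "residue_ids"))
  if (anyDuplicated(all_res))
    stop("duplicated residue id(s) across fragments: ",
         paste(unique(all_res[duplicated(all_res)]), collapse = ", "))
  structure(list(fragments = fragments, rigid = isTRUE(rigid)),
            class = "hp_bundle")
}

#' @export
print.hp_bundle <- function(x, ...) {
  cat(sprintf("<hp_bundle> %d fragment(s): %s; %s\n",
              length(x$fragments), paste(names(x$fragments), collapse = ", "),
              if (x$rigid) "rigid" else "flexible"))
  invisible(x)
}

#' All atom coordinates of a bundle stacked into one matrix (nm)
#' @param bundle an `hp_bundle`
#' @export
bundle_coords <- function(bundle) {
  do.call(rbind, lapply(bundle$fragments, `[[`, "coords"))
}

#' C-alpha center of mass of a bundle (unweighted centroid, nm)
#' @param bundle an `hp_bundle`
#' @export
bundle_com <- function(bundle) {
  ca <- do.call(rbind, lapply(bundle$fragments, calpha_coords))
  colMeans(ca)
}

#' Extract rigid helix fragments from a parsed PDB model
#'
#' Reads residue ranges out of a `bio3d` pdb object (first model of
#' multi-model files) and returns them as a rigid bundle with coordinates
#' converted from Angstrom to nm. Insertion codes are not supported.
#'
#' @param pdb a `bio3d::read.pdb()` object
#' @param ranges list of length-2 integer vectors, residue intervals
#'   (inclusive), e.g. `list(c(12, 23), c(30, 44))`
#' @param chain optional chain identifier; default first chain present
#' @return an `hp_bundle` with one fragment per range
#' @export
extract_fragments <- function(pdb, ranges, chain = NULL) {
  if (!length(ranges)) stop("empty range list")
  atom <- pdb$atom
  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- atom$chain[1]
  atom <- atom[atom$chain %in% chain, , drop = FALSE]
  ins <- atom$insert
  if (!is.null(ins) && any(!is.na(ins) & ins != ""))
    stop("insertion codes are not supported")
  frags <- lapply(ranges, function(rg) {
    stopifnot(length(rg) == 2L)
    wanted <- seq.int(rg[1], rg[2])
    sel <- atom[atom$resno %in% wanted, , drop = FALSE]
    present <- unique(sel$resno)
    missing <- setdiff(wanted, present)
    if (length(missing))
      stop("residue(s) missing from structure: ",
           paste(missing, collapse = ", "))
    elements <- sel$elesy
    if (is.null(elements) || all(is.na(elements)) || all(elements == ""))
      elements <- substr(gsub("[0-9]", "", sel$elety), 1, 1)
    seq1 <- vapply(present, function(r) {
      aa3 <- sel$resid[sel$resno == r][1]
      aa <- bio3d::aa321(aa3)
      if (is.na(aa)) "X" else aa
    }, character(1))
    new_fragment(residue_ids = present,
                 sequence = paste(seq1, collapse = ""),
                 atom_names = sel$elety,
                 elements = elements,
                 coords = cbind(sel$x, sel$y, sel$z) / 10,  # A -> nm
                 atom_resno = sel$resno)
  })
  new_bundle(frags)
}

#' Write a bundle (or several) to a PDB file for inspection
#'
#' Coordinates are converted back from nm to Angstrom. Fragments are
#' emitted in order with their original residue numbering.
#'
#' @param bundles named list of `hp_bundle` (each gets its own chain A, B, ...)
#' @param file output path
#' @return `file`, invisibly
#' @export
write_bundles_pdb <- function(bundles, file) {
  if (inherits(bundles, "hp_bundle")) bundles <- list(bundles)
  chains <- LETTERS[seq_along(bundles)]
  rows <- list(); serial <- 0L
  for (b in seq_along(bundles)) {
    for (fr in bundles[[b]]$fragments) {
      for (i in seq_len(nrow(fr$coords))) {
        serial <- serial + 1L
        res_i <- match(fr$atom_resno[i], fr$residue_ids)
        aa1 <- substr(fr$sequence, res_i, res_i)
        aa3 <- bio3d::aa123(aa1)
        if (is.na(aa3)) aa3 <- "UNK"
        rows[[length(rows) + 1L]] <- sprintf(
          "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, fr$atom_names[i], aa3, chains[b], fr$atom_resno[i],
          fr$coords[i, 1] * 10, fr$coords[i, 2] * 10, fr$coords[i, 3] * 10,
          fr$elements[i])
      }
    }
  }
  writeLines(c(unlist(rows), "END"), file)
  invisible(file)
}
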