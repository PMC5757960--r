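#' Structure-level diagnostics
#'
#' Solvent-accessible surface areas by deterministic sphere quadrature,
#' buried interface areas, residue contact probabilities over coordinate
#' frames, and steric-clash scans for rotated orientations.
#'
#' @name struct_analysis
NULL

# Deterministic golden-spiral point set on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

assign_radii <- function(elements, radii = vdw_radii()) {
  r <- radii[toupper(elements)]
  if (anyNA(r))
    stop("unknown element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley quadrature)
#'
#' Rolls a probe over each atom's expanded sphere sampled at a
#' deterministic golden-spiral point set; a point is accessible if it is
#' outside every neighbouring atom's expanded sphere.
#'
#' @param coords n_atoms x 3 matrix, nm
#' @param elements element symbol per atom
#' @param probe probe radius, nm (default 0.14, water)
#' @param n_points quadrature points per atom (default 960)
#' @param atom_resno optional residue id per atom, for per-residue areas
#' @return object of class `hp_sasa`: `total` (nm^2), `per_atom`,
#'   `per_residue`, `probe`, `n_points`
#' @export
sasa <- function(coords, elements, probe = 0.14, n_points = 960,
                 atom_resno = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(elements) == n)
  r <- assign_radii(elements) + probe
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)
  # neighbour lists via distance cutoff on expanded radii
  rmax <- max(r)
  for (i in seq_len(n)) {
    dv <- sweep(coords, 2, coords[i, ])
    dist2 <- rowSums(dv^2)
    nb <- which(dist2 < (r[i] + rmax)^2 & seq_len(n) != i)
    nb <- nb[dist2[nb] < (r[i] + r[nb])^2]
    surf <- sweep(pts * r[i], 2, coords[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- sweep(surf[acc, , drop = FALSE], 2, coords[j, ])
      acc[acc] <- rowSums(dj^2) >= r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  per_res <- NULL
  if (!is.null(atom_resno))
    per_res <- tapply(per_atom, atom_resno, sum)
  structure(list(total = sum(per_atom), per_atom = per_atom,
                 per_residue = per_res, probe = probe,
                 n_points = n_points),
            class = "hp_sasa")
}

#' @export
print.hp_sasa <- function(x, ...) {
  cat(sprintf("<hp_sasa> total %.3f nm^2 (probe %.2f nm, %d points/atom)\n",
              x$total, x$probe, x$n_points))
  invisible(x)
}

bundle_atoms <- function(bundle, heavy_only = TRUE) {
  coords <- bundle_coords(bundle)
  elements <- unlist(lapply(bundle$fragments, `[[`, "elements"))
  resno <- unlist(lapply(bundle$fragments, `[[`, "atom_resno"))
  if (heavy_only) {
    keep <- elements != "H"
    coords <- coords[keep, , drop = FALSE]
    elements <- elements[keep]; resno <- resno[keep]
  }
  list(coords = coords, elements = elements, resno = resno)
}

#' SASA of a bundle's heavy atoms
#' @param bundle an `hp_bundle`
#' @inheritParams sasa
#' @export
bundle_sasa <- function(bundle, probe = 0.14, n_points = 960) {
  at <- bundle_atoms(bundle)
  sasa(at$coords, at$elements, probe, n_points, at$resno)
}

#' Buried surface area between two bundles
#'
#' `buried = SASA(A) + SASA(B) - SASA(A union B)`; the percentage is of
#' the summed isolated areas. Each bundle's area is computed in
#' isolation.
#'
#' @param bundle_a,bundle_b `hp_bundle`s in their complexed coordinates
#' @inheritParams sasa
#' @return list `buried_nm2`, `percent`, `sasa_a`, `sasa_b`, `sasa_ab`
#' @export
buried_area <- function(bundle_a, bundle_b, probe = 0.14, n_points = 960) {
  at_a <- bundle_atoms(bundle_a); at_b <- bundle_atoms(bundle_b)
  # overlapping-atom check across bundles
  for (i in seq_len(nrow(at_a$coords))) {
    dv <- sweep(at_b$coords, 2, at_a$coords[i, ])
    if (any(rowSums(dv^2) < 0.01^2)) {
      warning("overlapping atoms (< 0.01 nm) between bundles")
      break
    }
  }
  sa <- sasa(at_a$coords, at_a$elements, probe, n_points)$total
  sb <- sasa(at_b$coords, at_b$elements, probe, n_points)$total
  sab <- sasa(rbind(at_a$coords, at_b$coords),
              c(at_a$elements, at_b$elements), probe, n_points)$total
  buried <- sa + sb - sab
  list(buried_nm2 = buried,
       percent = 100 * buried / (sa + sb),
       sasa_a = sa, sasa_b = sb, sasa_ab = sab)
}

#' Residue-residue contact probabilities over coordinate frames
#'
#' A contact exists between two residues in a frame when at least
#' `min_pairs` heavy-atom pairs (one atom from each residue) are within
#' `cutoff`. The reported probability is the fraction of frames with a
#' contact.
#'
#' @param frames list of coordinate matrices (n_atoms x 3, nm) sharing
#'   the atom ordering of `bundle_a` stacked on `bundle_b`
#' @param bundle_a,bundle_b the two fragments' bundles (metadata source)
#' @param cutoff nm (default 0.45)
#' @param min_pairs minimum heavy-atom pairs (default 2)
#' @return object of class `hp_contact_map`: probability matrix
#'   (residues of A x residues of B), `cutoff`, `min_pairs`
#' @export
contact_probability <- function(frames, bundle_a, bundle_b,
                                cutoff = 0.45, min_pairs = 2) {
  at_a <- bundle_atoms(bundle_a); at_b <- bundle_atoms(bundle_b)
  res_a <- sort(unique(at_a$resno)); res_b <- sort(unique(at_b$resno))
  if (!length(at_a$resno) || !length(at_b$resno))
    stop("a bundle has no heavy atoms")
  n_a <- nrow(at_a$coords)
  el_all <- c(unlist(lapply(bundle_a$fragments, `[[`, "elements")),
              unlist(lapply(bundle_b$fragments, `[[`, "elements")))
  heavy <- el_all != "H"
  prob <- matrix(0, length(res_a), length(res_b),
                 dimnames = list(res_a, res_b))
  for (fr in frames) {
    fr <- as.matrix(fr)
    if (nrow(fr) != length(el_all))
      stop("frame atom count does not match the bundles")
    hv <- fr[heavy, , drop = FALSE]
    ca <- hv[seq_len(n_a), , drop = FALSE]
    cb <- hv[-seq_len(n_a), , drop = FALSE]
    for (ia in seq_along(res_a)) {
      rows_a <- at_a$resno == res_a[ia]
      pa <- ca[rows_a, , drop = FALSE]
      for (ib in seq_along(res_b)) {
        pb <- cb[at_b$resno == res_b[ib], , drop = FALSE]
        d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) -
          2 * pa %*% t(pb)
        if (sum(d2 <= cutoff^2) >= min_pairs)
          prob[ia, ib] <- prob[ia, ib] + 1
      }
    }
  }
  prob <- prob / length(frames)
  structure(list(probability = prob, cutoff = cutoff,
                 min_pairs = min_pairs,
                 residues_a = res_a, residues_b = res_b),
            class = "hp_contact_map")
}

#' Steric-clash scan between two bundles
#'
#' Lists inter-bundle heavy-atom pairs closer than the sum of their van
#' der Waals radii minus `tolerance`.
#'
#' @param bundle_a,bundle_b `hp_bundle`s in a common coordinate frame
#' @param tolerance nm subtracted from the radius sum (default 0.05)
#' @return data.frame `res_a`, `atom_a`, `res_b`, `atom_b`,
#'   `distance_nm`, `criterion_nm`
#' @export
clash_scan <- function(bundle_a, bundle_b, tolerance = 0.05) {
  at_a <- bundle_atoms(bundle_a); at_b <- bundle_atoms(bundle_b)
  names_a <- unlist(lapply(bundle_a$fragments, function(f)
    f$atom_names[f$elements != "H"]))
  names_b <- unlist(lapply(bundle_b$fragments, function(f)
    f$atom_names[f$elements != "H"]))
  r_a <- assign_radii(at_a$elements); r_b <- assign_radii(at_b$elements)
  out <- list()
  for (i in seq_len(nrow(at_a$coords))) {
    dv <- sweep(at_b$coords, 2, at_a$coords[i, ])
    dist <- sqrt(rowSums(dv^2))
    crit <- r_a[i] + r_b - tolerance
    hits <- which(dist < crit)
    if (length(hits))
      out[[length(out) + 1L]] <- data.frame(
        res_a = at_a$resno[i], atom_a = names_a[i],
        res_b = at_b$resno[hits], atom_b = names_b[hits],
        distance_nm = dist[hits], criterion_nm = crit[hits])
  }
  if (!length(out))
    return(data.frame(res_a = integer(), atom_a = character(),
                      res_b = integer(), atom_b = character(),
                      distance_nm = numeric(), criterion_nm = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
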