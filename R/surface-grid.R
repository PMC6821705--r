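## Lattice grid placement around a protein and the alpha-sphere surface
## filter used to mark buried and solvent-exposed surface regions.

#' Generate a cubic lattice around a protein
#'
#' Places grid points on a cubic lattice (default 1 A spacing) covering the
#' protein bounding box padded by 5 A, anchored at the padded bounding-box
#' minimum corner so the lattice is translation-covariant and deterministic.
#' Each point is annotated with its minimum distance to any protein heavy
#' atom and the identity of the nearest protein residue.
#'
#' @param structure A `complex_structure` with at least one protein atom.
#' @param spacing Lattice spacing in Angstrom (> 0).
#' @param padding Bounding-box padding in Angstrom.
#' @param max_dist Points farther than this from every protein atom are
#'   dropped early (they can never enter the surface band); `Inf` keeps all.
#' @return Tibble with one row per grid point: `x`, `y`, `z`,
#'   `min_protein_dist`, `nearest_chain`, `nearest_resno`.
#' @export
generate_lattice <- function(structure, spacing = 1, padding = 5,
                             max_dist = padding) {
  if (spacing <= 0) abort("spacing must be > 0")
  prot <- protein_atoms(structure)
  if (nrow(prot) == 0) abort("structure has no protein atoms")
  pxyz <- atom_xyz(prot)
  lo <- apply(pxyz, 2, min) - padding
  hi <- apply(pxyz, 2, max) + padding
  ax <- lapply(1:3, function(i) seq(lo[i], hi[i], by = spacing))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  nd <- min_dist_to(pts, pxyz)
  keep <- nd$dist <= max_dist
  tibble::tibble(
    x = pts[keep, 1], y = pts[keep, 2], z = pts[keep, 3],
    min_protein_dist = nd$dist[keep],
    nearest_chain = prot$chain[nd$index[keep]],
    nearest_resno = prot$resno[nd$index[keep]]
  )
}

#' Keep grid points in the surface distance band
#'
#' Retains exactly the points whose minimum protein distance lies in the
#' closed interval `[lo, hi]` (default 2.5-5.0 A, the surface band in which
#' binding-site locations are defined).
#'
#' @param points Grid tibble from [generate_lattice()].
#' @param lo,hi Band bounds in Angstrom, `lo < hi`.
#' @return The filtered grid tibble (a subset of the input rows).
#' @export
filter_surface_band <- function(points, lo = 2.5, hi = 5.0) {
  if (!(lo < hi)) abort("lo must be < hi")
  dplyr::filter(points, .data$min_protein_dist >= lo,
                .data$min_protein_dist <= hi)
}

## Circumsphere of four points; NULL when (near-)degenerate.
circumsphere <- function(q) {
  a <- 2 * (q[2:4, , drop = FALSE] -
              matrix(q[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(q[2:4, , drop = FALSE]^2) - sum(q[1, ]^2)
  det_a <- det(a)
  if (!is.finite(det_a) || abs(det_a) < 1e-8) return(NULL)
  center <- solve(a, b)
  list(center = center, radius = sqrt(sum((q[1, ] - center)^2)))
}

#' Detect alpha spheres on a protein surface
#'
#' An alpha sphere is a sphere tangent to four protein atoms with no fifth
#' atom strictly inside; spheres with radii between `r_min` and `r_max` trace
#' both buried pockets and solvent-exposed surface regions. Candidate
#' atom quadruples come from a k-nearest-neighbor search (a Delaunay-style
#' neighborhood); degenerate (coplanar) quadruples are skipped, and duplicate
#' spheres found from different seeds are merged.
#'
#' @param structure A `complex_structure` with >= 4 protein atoms.
#' @param r_min,r_max Radius bounds in Angstrom (defaults 3.0-6.0).
#' @param k_neighbors Neighborhood size for candidate quadruples.
#' @param inside_tol A fifth atom counts as strictly inside when it is more
#'   than this far inside the sphere surface.
#' @return Tibble with one row per sphere: `x`, `y`, `z`, `radius`, and
#'   `contact_atoms` (list column of the four atom row indices).
#' @export
detect_alpha_spheres <- function(structure, r_min = 3.0, r_max = 6.0,
                                 k_neighbors = 8L, inside_tol = 1e-6) {
  prot <- protein_atoms(structure)
  if (nrow(prot) < 4) abort("need >= 4 protein atoms")
  xyz <- atom_xyz(prot)
  n <- nrow(xyz)
  d <- cross_dist(xyz, xyz)
  seen <- new.env(hash = TRUE)
  out <- list()
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:min(n, k_neighbors + 1L)]
    if (length(nb) < 3) next
    trips <- combn(nb, 3)
    for (t in seq_len(ncol(trips))) {
      quad <- sort(c(i, trips[, t]))
      key <- paste(quad, collapse = "-")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      cs <- circumsphere(xyz[quad, , drop = FALSE])
      if (is.null(cs)) next
      if (cs$radius < r_min || cs$radius > r_max) next
      dd <- sqrt(colSums((t(xyz) - cs$center)^2))
      if (any(dd[-quad] < cs$radius - inside_tol)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        x = cs$center[1], y = cs$center[2], z = cs$center[3],
        radius = cs$radius, contact_atoms = list(quad))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          radius = numeric(), contact_atoms = list()))
  }
  dplyr::bind_rows(out)
}

## TRUE for points strictly inside any alpha sphere.
inside_any_sphere <- function(points_xyz, spheres) {
  if (nrow(spheres) == 0) return(rep(FALSE, nrow(points_xyz)))
  d <- cross_dist(points_xyz, cbind(spheres$x, spheres$y, spheres$z))
  rowSums(d < matrix(spheres$radius, nrow(points_xyz), nrow(spheres),
                     byrow = TRUE)) > 0
}

#' Write a grid to delimited text
#'
#' @param grid Grid tibble.
#' @param path Output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
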