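## Maximal-clique alignment of coarse-grained trinucleotide models against
## predicted binding-site points via a correspondence (product) graph:
## vertices pair same-class model nodes with site points, edges require
## distance consistency within a tolerance, and Bron-Kerbosch enumeration
## with pivoting finds maximal cliques. Placements are kept when the clique
## has >= 7 nodes, every consecutive base pair is guided by enough backbone
## matches, and the superposed full-atom model does not clash with the
## protein.

#' Enumerate all maximal cliques of an undirected graph
#'
#' Bron-Kerbosch with pivoting on an adjacency matrix.
#'
#' @param adj Logical or 0/1 symmetric adjacency matrix (no self loops).
#' @return List of integer vectors, each a maximal clique (singletons
#'   included for isolated vertices).
#' @export
max_cliques_bk <- function(adj) {
  adj <- adj > 0
  diag(adj) <- FALSE
  n <- nrow(adj)
  nb <- lapply(seq_len(n), function(i) which(adj[i, ]))
  out <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      out[[length(out) + 1L]] <<- r
      return(invisible())
    }
    ## pivot: vertex of P union X with most neighbors in P
    px <- c(p, x)
    deg <- vapply(px, function(u) length(intersect(nb[[u]], p)), integer(1))
    u <- px[which.max(deg)]
    for (v in setdiff(p, nb[[u]])) {
      bk(c(r, v), intersect(p, nb[[v]]), intersect(x, nb[[v]]))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  if (n > 0) bk(integer(0), seq_len(n), integer(0))
  lapply(out, sort)
}

## Correspondence graph between model nodes and same-class site points.
correspondence_graph <- function(nodes, sites, tau) {
  pairs <- which(outer(nodes$kind, sites$kind, "=="), arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    return(list(pairs = pairs, adj = matrix(FALSE, 0, 0)))
  }
  dn <- cross_dist(cbind(nodes$x, nodes$y, nodes$z),
                   cbind(nodes$x, nodes$y, nodes$z))
  ds <- cross_dist(cbind(sites$x, sites$y, sites$z),
                   cbind(sites$x, sites$y, sites$z))
  nv <- nrow(pairs)
  adj <- matrix(FALSE, nv, nv)
  for (a in seq_len(nv)) {
    i <- pairs[a, 1]; j <- pairs[a, 2]
    for (b in seq_len(nv)) {
      if (b == a) next
      k <- pairs[b, 1]; l <- pairs[b, 2]
      if (i == k || j == l) next
      adj[a, b] <- abs(dn[i, k] - ds[j, l]) <= tau
    }
  }
  adj <- adj & t(adj)
  list(pairs = pairs, adj = adj)
}

#' Align coarse-grained trinucleotide models to predicted site points
#'
#' Builds, for each 9-node model, the correspondence graph against
#' same-class site points with distance-consistency edges (tolerance `tau`),
#' enumerates maximal cliques by Bron-Kerbosch with pivoting, and retains
#' placements that (i) have clique size at least `min_clique`, (ii) match at
#' least `min_backbone_guides` backbone (P/R) nodes for every consecutive
#' base pair whose base nodes are both matched, and (iii) show no heavy atom
#' of the superposed model within `clash_dist` of any protein atom.
#'
#' @param top_sites Tibble of predicted site points: `x`, `y`, `z`, `kind`
#'   (P/R/A/G/C/U).
#' @param models List whose elements each carry `nodes` (a [coarse_grain()]
#'   tibble) and optionally `atoms` (full-atom set for the clash check) and
#'   `sequence`.
#' @param protein A `complex_structure` (protein atoms used for clashes),
#'   or NULL to skip the clash check.
#' @param tau Distance-consistency tolerance (A, default 1.5).
#' @param clash_dist Heavy-atom clash distance (A, default 2.5).
#' @param min_clique Minimum clique size (default 7).
#' @param min_backbone_guides Minimum matched backbone nodes per consecutive
#'   base pair (default 5).
#' @return Tibble of accepted placements: `model`, `sequence`,
#'   `clique_size`, `rmsd`, `matched` (list of node/site index pairs),
#'   `aligned_nodes` (list; all model nodes in the site frame).
#' @export
align_cliques <- function(top_sites, models, protein = NULL, tau = 1.5,
                          clash_dist = 2.5, min_clique = 7L,
                          min_backbone_guides = 5L) {
  empty <- tibble::tibble(model = integer(), sequence = character(),
                          clique_size = integer(), rmsd = numeric(),
                          matched = list(), aligned_nodes = list())
  if (nrow(top_sites) == 0 || length(models) == 0) return(empty)
  pxyz <- if (!is.null(protein)) atom_xyz(protein_atoms(protein)) else NULL
  out <- list()
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    nodes <- model$nodes
    cg <- correspondence_graph(nodes, top_sites, tau)
    if (nrow(cg$pairs) == 0) next
    cliques <- Filter(function(cl) length(cl) >= min_clique,
                      max_cliques_bk(cg$adj))
    for (cl in cliques) {
      ni <- cg$pairs[cl, 1]; si <- cg$pairs[cl, 2]
      ## consecutive-base guidance: both base nodes matched -> require
      ## enough matched backbone constituents
      matched_kinds <- nodes$kind[ni]
      matched_res <- nodes$resno[ni]
      base_res <- sort(matched_res[matched_kinds %in% BASES])
      n_backbone <- sum(matched_kinds %in% c("P", "R"))
      ok_guides <- TRUE
      if (length(base_res) >= 2) {
        for (j in seq_len(length(base_res) - 1)) {
          if (base_res[j + 1] == base_res[j] + 1 &&
              n_backbone < min_backbone_guides) ok_guides <- FALSE
        }
      }
      if (!ok_guides) next
      from <- cbind(nodes$x[ni], nodes$y[ni], nodes$z[ni])
      to <- cbind(top_sites$x[si], top_sites$y[si], top_sites$z[si])
      tr <- kabsch(from, to)
      fitted <- apply_kabsch(from, tr)
      rmsd <- sqrt(mean(rowSums((fitted - to)^2)))
      if (!is.null(pxyz) && !is.null(model$atoms)) {
        placed <- apply_kabsch(model$atoms$xyz, tr)
        if (min(cross_dist(placed, pxyz)) < clash_dist) next
      }
      aligned <- nodes
      axyz <- apply_kabsch(cbind(nodes$x, nodes$y, nodes$z), tr)
      aligned$x <- axyz[, 1]; aligned$y <- axyz[, 2]; aligned$z <- axyz[, 3]
      seq_label <- model$sequence %||% NA_character_
      out[[length(out) + 1L]] <- tibble::tibble(
        model = mi,
        sequence = seq_label,
        clique_size = length(cl),
        rmsd = rmsd,
        matched = list(tibble::tibble(node = ni, site = si)),
        aligned_nodes = list(aligned))
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}
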