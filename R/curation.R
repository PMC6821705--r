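## Labeling of grid points with the seven binding classes, negative sampling,
## class balancing, homology clustering and homology-disjoint fold building.

## Tie priority when a point is equidistant from several constituent
## centroids: backbone contact is geometrically enclosing, so P > R > base.
KIND_PRIORITY <- c(P = 1, R = 2, A = 3, G = 3, C = 3, U = 3)

#' Label surface grid points by nearby constituent centroids
#'
#' Assigns to each grid point within `max_centroid_dist` (default 3 A) of at
#' least one constituent centroid the class of its nearest centroid; points
#' farther than `max_protein_dist` from the protein are never labeled
#' positive. Ties between equidistant centroids resolve by the priority
#' P > R > base. Points with no qualifying centroid keep label `NA`
#' (unlabeled candidates).
#'
#' @param grid Grid tibble from [filter_surface_band()].
#' @param centroids Constituent centroid tibble from
#'   [decompose_structure()].
#' @param max_centroid_dist Labeling radius around centroids (A).
#' @param max_protein_dist Maximum protein distance for positives (A).
#' @return The grid tibble with added columns `label` (factor over
#'   X/P/R/A/G/C/U, `NA` = candidate), `centroid_dist`, `source_chain`,
#'   `source_resno`.
#' @export
label_positives <- function(grid, centroids, max_centroid_dist = 3,
                            max_protein_dist = 5) {
  grid$label <- factor(rep(NA_character_, nrow(grid)), levels = CLASSES7)
  grid$centroid_dist <- NA_real_
  grid$source_chain <- NA_character_
  grid$source_resno <- NA_integer_
  if (nrow(grid) == 0 || nrow(centroids) == 0) return(grid)
  d <- cross_dist(cbind(grid$x, grid$y, grid$z),
                  cbind(centroids$x, centroids$y, centroids$z))
  pr <- KIND_PRIORITY[centroids$kind]
  for (i in seq_len(nrow(grid))) {
    if (grid$min_protein_dist[i] > max_protein_dist) next
    ok <- which(d[i, ] <= max_centroid_dist)
    if (length(ok) == 0) next
    ## nearest centroid wins; exact distance ties resolve by kind priority
    best <- ok[order(d[i, ok], pr[ok])][1]
    grid$label[i] <- centroids$kind[best]
    grid$centroid_dist[i] <- d[i, best]
    grid$source_chain[i] <- centroids$chain[best]
    grid$source_resno[i] <- centroids$resno[best]
  }
  grid
}

#' Sample non-site (X) grid points
#'
#' Draws `n` negative examples from the unlabeled grid points that are more
#' than `rna_exclusion` (default 3 A) away from every RNA atom and outside
#' every alpha sphere. Deterministic under `seed`. When fewer than `n`
#' admissible points exist, all of them are returned with a warning.
#'
#' @param grid Labeled grid tibble from [label_positives()].
#' @param rna_atoms_xyz Matrix (or tibble) of RNA atom coordinates; may have
#'   zero rows for a stripped structure.
#' @param spheres Alpha-sphere tibble from [detect_alpha_spheres()].
#' @param n Number of negatives requested (>= 0).
#' @param seed Integer seed.
#' @param rna_exclusion Exclusion radius around RNA atoms (A).
#' @return The grid tibble with `n` previously unlabeled rows relabeled `X`.
#' @export
sample_negatives <- function(grid, rna_atoms_xyz, spheres, n, seed = 1L,
                             rna_exclusion = 3) {
  if (n < 0) abort("n must be >= 0")
  cand <- which(is.na(grid$label))
  if (length(cand) > 0) {
    pts <- cbind(grid$x[cand], grid$y[cand], grid$z[cand])
    ok <- rep(TRUE, length(cand))
    rna_atoms_xyz <- as.matrix(rna_atoms_xyz)
    if (nrow(rna_atoms_xyz) > 0) {
      ok <- ok & (min_dist_to(pts, rna_atoms_xyz)$dist > rna_exclusion)
    }
    ok <- ok & !inside_any_sphere(pts, spheres)
    cand <- cand[ok]
  }
  if (n > length(cand)) {
    warn(sprintf("only %d admissible negative points for n = %d",
                 length(cand), n))
    n <- length(cand)
  }
  pick <- with_seed(seed, sample_from(cand, n))
  grid$label[pick] <- "X"
  grid
}

#' Balance positive and negative grid points
#'
#' Subsamples the negative (X) points so that the ratio of positives to
#' negatives equals `ratio_pos_to_neg` (default 2, the 2:1 training balance)
#' within integer rounding. Positives are never touched; when negatives are
#' already at or below the target count the grid is returned unchanged.
#'
#' @param labeled Grid tibble with a `label` column.
#' @param ratio_pos_to_neg Target #positives / #negatives.
#' @param seed Integer seed for the subsample.
#' @return The grid tibble restricted to positives, the retained negatives,
#'   and any unlabeled candidate rows.
#' @export
balance_classes <- function(labeled, ratio_pos_to_neg = 2, seed = 1L) {
  is_pos <- !is.na(labeled$label) & labeled$label != "X"
  is_neg <- !is.na(labeled$label) & labeled$label == "X"
  n_pos <- sum(is_pos)
  if (n_pos == 0) abort("no positive points to balance against")
  target_neg <- round(n_pos / ratio_pos_to_neg)
  neg_idx <- which(is_neg)
  if (length(neg_idx) <= target_neg) return(labeled)
  keep <- with_seed(seed, sample_from(neg_idx, target_neg))
  drop <- setdiff(neg_idx, keep)
  labeled[-drop, , drop = FALSE]
}

#' Global pairwise sequence identity
#'
#' Identity between two sequences under a global alignment with match +1,
#' mismatch 0 and affine gap penalties (open -2, extend -1); identity is the
#' number of matched positions divided by the alignment length.
#'
#' @param a,b Character scalars (one-letter sequences).
#' @return Identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global",
    substitutionMatrix = identity_substitution_matrix(),
    gapOpening = 2, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(al))
  ps <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(ps, "")[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}

identity_substitution_matrix <- function() {
  letters <- c(Biostrings::AA_ALPHABET)
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

#' Cluster chains by sequence identity (single linkage)
#'
#' Single-linkage clusters over pairwise global identity at or above
#' `threshold` (default 0.9): two chains land in the same cluster whenever a
#' chain of pairwise links at `>= threshold` connects them.
#'
#' @param chains Named character vector of sequences (names = structure or
#'   chain ids).
#' @param threshold Identity threshold in (0, 1].
#' @return Object of class `homology_clusters`: a list with `members`
#'   (tibble `id`, `cluster`), `threshold`, and the `identity` matrix.
#' @export
cluster_by_identity <- function(chains, threshold = 0.9) {
  if (!(threshold > 0 && threshold <= 1)) abort("threshold must be in (0, 1]")
  n <- length(chains)
  ids <- names(chains) %||% as.character(seq_len(n))
  if (n == 0) {
    return(structure(list(members = tibble::tibble(id = character(),
                                                   cluster = integer()),
                          threshold = threshold,
                          identity = matrix(numeric(), 0, 0)),
                     class = "homology_clusters"))
  }
  idm <- diag(1, n)
  dimnames(idm) <- list(ids, ids)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <- pairwise_identity(chains[[i]], chains[[j]])
    }
  }
  ## connected components of the >= threshold graph (single linkage)
  cluster <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (idm[i, j] >= threshold && cluster[j] != cluster[i]) {
        cluster[cluster == cluster[j]] <- cluster[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cluster <- as.integer(factor(cluster, levels = unique(cluster)))
  structure(list(members = tibble::tibble(id = ids, cluster = cluster),
                 threshold = threshold, identity = idm),
            class = "homology_clusters")
}

#' @export
print.homology_clusters <- function(x, ...) {
  cat("<homology_clusters> ", nrow(x$members), " chain(s) in ",
      length(unique(x$members$cluster)), " cluster(s) at identity >= ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

#' Select the representative structure of a homology cluster
#'
#' Picks the entry with the numerically best (lowest) global resolution;
#' entries without a resolution (e.g. NMR models) are treated as worst, and
#' exact resolution ties break toward the lower mean protein B-factor.
#'
#' @param cluster_ids Character vector of structure ids in the cluster.
#' @param structures_meta Tibble with columns `id`, `resolution` (A, `NA`
#'   allowed) and optionally `mean_protein_b`.
#' @return The representative structure id.
#' @export
select_representative <- function(cluster_ids, structures_meta) {
  if (length(cluster_ids) == 0) abort("empty cluster")
  meta <- structures_meta[match(cluster_ids, structures_meta$id), ]
  res <- ifelse(is.na(meta$resolution), Inf, meta$resolution)
  bfac <- if ("mean_protein_b" %in% names(meta)) {
    ifelse(is.na(meta$mean_protein_b), Inf, meta$mean_protein_b)
  } else rep(0, nrow(meta))
  meta$id[order(res, bfac)][1]
}

#' Pick the best locally resolved RNA copy within a structure
#'
#' Among duplicate RNA chains of one entry, keeps the copy with the lowest
#' mean B-factor over its atoms (local resolution).
#'
#' @param structure A `complex_structure`.
#' @return The chain id of the best-resolved RNA chain (`NA` when none).
#' @export
best_rna_chain <- function(structure) {
  ra <- rna_atoms(structure)
  if (nrow(ra) == 0) return(NA_character_)
  means <- ra |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(mean_b = mean(.data$b_factor), .groups = "drop") |>
    dplyr::arrange(.data$mean_b, .data$chain)
  means$chain[1]
}

#' Assign homology clusters to disjoint cross-validation folds
#'
#' Distributes whole clusters over `k` folds so that homologous structures
#' are never split across folds; fold sizes (in structures) are balanced
#' greedily, largest clusters first, onto the currently smallest fold.
#'
#' @param clusters A `homology_clusters` object.
#' @param k Number of folds (>= 2, <= number of clusters).
#' @param seed Integer seed (shuffles equal-size clusters).
#' @return Tibble `id`, `cluster`, `fold`.
#' @export
make_folds <- function(clusters, k, seed = 1L) {
  stopifnot(inherits(clusters, "homology_clusters"))
  if (k < 2) abort("k must be >= 2")
  mem <- clusters$members
  sizes <- table(mem$cluster)
  if (k > length(sizes)) {
    abort(sprintf("k = %d exceeds the number of clusters (%d)",
                  k, length(sizes)))
  }
  ord <- with_seed(seed, {
    ids <- sample(names(sizes))        # shuffle, then stable sort by size
    ids[order(-sizes[ids])]
  })
  fold_sizes <- numeric(k)
  assignment <- integer(length(sizes))
  names(assignment) <- ord
  for (cl in ord) {
    f <- which.min(fold_sizes)
    assignment[cl] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[[cl]]
  }
  mem$fold <- assignment[as.character(mem$cluster)]
  mem
}
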