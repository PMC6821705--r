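## Synthetic desk-scale fixtures: toy ribonucleoprotein complexes with known
## constituent geometry, and class-conditional Gaussian feature vectors for
## classifier parameter-recovery tests. All randomness flows from the single
## seed in the spec; no global RNG state is consumed.

#' Specify a synthetic ribonucleoprotein fixture
#'
#' @param n_protein_residues Number of poly-alanine residues (>= 1).
#' @param n_nucleotides Number of RNA nucleotides placed near the protein
#'   surface (0 gives a protein-only structure).
#' @param rng_seed Integer seed fixing all randomness in the fixture.
#' @param geometry `"helix"` (protein backbone on an ideal alpha-helical
#'   curve) or `"extended"` (a stretched, sheet-like trace).
#' @param noise_sd Gaussian jitter (Angstrom) added to every placed atom.
#' @param sequence Optional RNA sequence (letters A/G/C/U); random when NULL.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_protein_residues, n_nucleotides, rng_seed = 1L,
                         geometry = c("helix", "extended"), noise_sd = 0.05,
                         sequence = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(n_protein_residues >= 1, n_nucleotides >= 0, noise_sd >= 0)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (length(sequence) == 1 && nchar(sequence) > 1) {
      sequence <- strsplit(sequence, "")[[1]]
    }
    bad <- setdiff(sequence, BASES)
    if (length(bad)) abort(paste0("invalid RNA letters: ",
                                  paste(bad, collapse = ", ")))
    if (length(sequence) != n_nucleotides) {
      abort("sequence length must equal n_nucleotides")
    }
  }
  structure(list(n_protein_residues = as.integer(n_protein_residues),
                 n_nucleotides = as.integer(n_nucleotides),
                 rng_seed = as.integer(rng_seed), geometry = geometry,
                 noise_sd = noise_sd, sequence = sequence),
            class = "fixture_spec")
}

## Poly-alanine backbone atoms (N, CA, C, O, CB) along an idealized curve
## with 3.8 A consecutive-CA spacing.
poly_ala_atoms <- function(n_res, geometry) {
  if (geometry == "helix") {
    ## Ideal alpha-helical CA trace: radius 2.3 A, rise 1.5 A, 100 deg/res.
    i <- seq_len(n_res)
    ang <- (i - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (i - 1))
  } else {
    i <- seq_len(n_res)
    ca <- cbind(3.8 * (i - 1), 0.5 * ((i %% 2) * 2 - 1), 0)
  }
  rows <- list()
  for (j in seq_len(n_res)) {
    prev_dir <- if (j > 1) ca[j, ] - ca[j - 1, ] else ca[min(j + 1, n_res), ] - ca[j, ]
    next_dir <- if (j < n_res) ca[j + 1, ] - ca[j, ] else prev_dir
    u <- prev_dir / sqrt(sum(prev_dir^2))
    v <- next_dir / sqrt(sum(next_dir^2))
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    if (sqrt(sum(w^2)) < 1e-8) w <- c(0, 0, 1) else w <- w / sqrt(sum(w^2))
    radial <- ca[j, ] - c(mean(ca[, 1]), mean(ca[, 2]), ca[j, 3])
    nr <- sqrt(sum(radial^2))
    radial <- if (nr > 1e-8) radial / nr else c(1, 0, 0)
    ## off-axis N/C offsets keep backbone dihedrals well defined
    pos <- rbind(N = ca[j, ] - 1.35 * u + 0.55 * w,
                 CA = ca[j, ],
                 C = ca[j, ] + 1.35 * v - 0.55 * w,
                 O = ca[j, ] + 1.35 * v - 0.55 * w + 1.23 * radial,
                 CB = ca[j, ] + 1.53 * radial)
    rows[[j]] <- tibble::tibble(
      name = rownames(pos), element = substr(rownames(pos), 1, 1),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      residue_name = "ALA", chain = "A", resno = j, insert = "",
      b_factor = 20, occupancy = 1, altloc = "")
  }
  dplyr::bind_rows(rows)
}

#' Build a synthetic ribonucleoprotein complex with known ground truth
#'
#' Places a poly-alanine protein backbone on an idealized curve (3.8 A
#' consecutive-CA spacing) and, when requested, an RNA strand whose
#' nucleotides sit 3-6 A from the protein surface with bases pointing toward
#' the protein. Returns both the structure and the true constituent
#' centroids of the placed nucleotides. Deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return List with `structure` (a `complex_structure`), `centroids`
#'   (ground-truth constituent centroid tibble) and `sequence`.
#' @export
make_complex_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$rng_seed, {
    prot <- poly_ala_atoms(spec$n_protein_residues, spec$geometry)
    seq <- spec$sequence %||%
      sample(BASES, spec$n_nucleotides, replace = TRUE)
    rna_rows <- list()
    if (spec$n_nucleotides > 0) {
      prot_xyz <- cbind(prot$x, prot$y, prot$z)
      center <- colMeans(prot_xyz)
      max_r <- max(sqrt(rowSums(sweep(prot_xyz[, 1:2, drop = FALSE], 2,
                                      center[1:2])^2)))
      strand_r <- max_r + 6.5   # keeps base centroids 3-6 A from the surface
      zspan <- range(prot_xyz[, 3])
      for (j in seq_len(spec$n_nucleotides)) {
        frac <- if (spec$n_nucleotides == 1) 0.5 else (j - 1) / (spec$n_nucleotides - 1)
        ang <- 2 * pi * 0.08 * (j - 1) + pi / 7
        origin <- c(center[1] + strand_r * cos(ang),
                    center[2] + strand_r * sin(ang),
                    zspan[1] + frac * diff(zspan))
        inward <- c(center[1] - origin[1], center[2] - origin[2], 0)
        inward <- inward / sqrt(sum(inward^2))
        axis_z <- c(0, 0, 1)
        side <- c(inward[2], -inward[1], 0)
        basis <- cbind(side, axis_z, -inward)
        atoms <- place_nucleotide(seq[j], origin, basis,
                                  base_direction = inward,
                                  with_phosphate = TRUE)
        atoms <- atoms + matrix(rnorm(length(atoms), 0, spec$noise_sd),
                                ncol = 3)
        rna_rows[[j]] <- tibble::tibble(
          name = rownames(atoms),
          element = element_from_name(rownames(atoms)),
          x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
          residue_name = seq[j], chain = "B", resno = j, insert = "",
          b_factor = 25, occupancy = 1, altloc = "")
      }
    }
    all_atoms <- dplyr::bind_rows(c(list(prot), rna_rows))
    st <- new_complex_structure(all_atoms)
    if (spec$n_nucleotides > 0) {
      d <- cross_dist(atom_xyz(rna_atoms(st)), atom_xyz(protein_atoms(st)))
      if (min(d) < 1.5) {
        abort("infeasible fixture geometry: unavoidable protein-RNA clash")
      }
    }
    list(structure = st,
         centroids = decompose_structure(st),
         sequence = if (spec$n_nucleotides > 0) seq else character())
  })
}

#' Draw feature vectors from class-conditional spherical Gaussians
#'
#' Generates balanced, labeled feature vectors for classifier
#' parameter-recovery tests: `n_per_class` draws per class from an isotropic
#' Gaussian around each class mean.
#'
#' @param n_per_class Draws per class (>= 1).
#' @param class_means Numeric matrix, one row per class (rownames = class
#'   labels), typically 7 x 480.
#' @param sd Common standard deviation (> 0).
#' @param seed Integer seed.
#' @return List with `features` (numeric matrix) and `labels` (factor with
#'   levels in the row order of `class_means`).
#' @export
sample_feature_vectors <- function(n_per_class, class_means, sd, seed = 1L) {
  if (n_per_class < 1) abort("n_per_class must be >= 1")
  if (sd <= 0) abort("sd must be > 0")
  class_means <- as.matrix(class_means)
  k <- nrow(class_means)
  lv <- rownames(class_means) %||% as.character(seq_len(k))
  with_seed(seed, {
    feats <- matrix(0, n_per_class * k, ncol(class_means))
    labels <- character(n_per_class * k)
    for (i in seq_len(k)) {
      idx <- (i - 1) * n_per_class + seq_len(n_per_class)
      feats[idx, ] <- matrix(rnorm(n_per_class * ncol(class_means),
                                   0, sd), n_per_class) +
        matrix(class_means[i, ], n_per_class, ncol(class_means),
               byrow = TRUE)
      labels[idx] <- lv[i]
    }
    list(features = feats, labels = factor(labels, levels = lv))
  })
}

#' Orthogonal class means for synthetic classification problems
#'
#' Places each class mean at `separation` along its own coordinate axis, so
#' pairwise mean distances are `separation * sqrt(2)` and the Bayes rate of
#' the resulting Gaussian mixture has a simple Monte Carlo estimate.
#'
#' @param classes Character vector of class labels.
#' @param d Feature dimension (default 480).
#' @param separation Distance from the origin to each mean.
#' @return Matrix with `length(classes)` rows and rownames `classes`.
#' @export
class_means_orthogonal <- function(classes = CLASSES7, d = 480,
                                   separation = 1) {
  k <- length(classes)
  stopifnot(d >= k)
  m <- matrix(0, k, d, dimnames = list(classes, NULL))
  m[cbind(seq_len(k), seq_len(k))] <- separation
  m
}

#' Monte Carlo Bayes accuracy for an equal-prior spherical Gaussian mixture
#'
#' The Bayes classifier for equal-prior isotropic Gaussians is the
#' nearest-class-mean rule; its accuracy is estimated by simulation from the
#' generative model itself.
#'
#' @inheritParams sample_feature_vectors
#' @param n_mc Draws per class for the estimate.
#' @return Scalar accuracy in [0, 1].
#' @export
bayes_rate_gaussian <- function(class_means, sd, n_mc = 2000, seed = 1L) {
  smp <- sample_feature_vectors(n_mc, class_means, sd, seed = seed)
  d <- cross_dist(smp$features, as.matrix(class_means))
  pred <- max.col(-d, ties.method = "first")
  mean(rownames(class_means)[pred] == as.character(smp$labels))
}
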