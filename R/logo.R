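## Sequence logos from per-location score vectors at known base positions:
## averaged class probabilities per position, information content in bits,
## and letter heights obtained by proportioning the information content by
## the class probabilities (bases only; P, R and X carry probability mass
## but are omitted from the displayed logo).

#' Average score vectors around a base centroid
#'
#' Arithmetic mean of the score vectors on grid points within `radius`
#' (default 3 A) of a base centroid, renormalized. An empty neighborhood is
#' flagged undefined (uniform placeholder, `n_points = 0`).
#'
#' @param point_scores Tibble with `prob_*` columns aligned with `grid`.
#' @param grid Grid tibble with `x`, `y`, `z`.
#' @param base_centroid Numeric length-3 coordinate.
#' @param radius Averaging radius (A).
#' @return One-row tibble of `prob_*` columns plus `n_points`.
#' @export
average_scores_at_base <- function(point_scores, grid, base_centroid,
                                   radius = 3) {
  d <- sqrt(colSums((t(cbind(grid$x, grid$y, grid$z)) -
                       as.numeric(base_centroid))^2))
  take <- which(d <= radius)
  if (length(take) == 0) {
    p <- setNames(rep(1 / 7, 7), prob_cols())
    out <- tibble::as_tibble(as.list(p))
    out$n_points <- 0L
    return(out)
  }
  m <- score_matrix(point_scores[take, , drop = FALSE])
  p <- colMeans(m)
  p <- p / sum(p)
  out <- tibble::as_tibble(as.list(setNames(p, prob_cols())))
  out$n_points <- length(take)
  out
}

#' Information content of a 7-class probability vector
#'
#' Bits of deviation from the uniform distribution over the seven classes:
#' `log2(7) + sum(p * log2(p))`, with `0 * log 0 = 0`. Zero at the uniform
#' distribution; `log2(7)` (about 2.807 bits) when all mass sits on one
#' class.
#'
#' @param p Normalized probability vector of length 7.
#' @return Information content in bits, in `[0, log2(7)]`.
#' @export
information_content <- function(p) {
  if (!is_prob_vector(p) || length(p) != 7) {
    abort("p must be a normalized 7-class probability vector")
  }
  nz <- p > 0
  ic <- log2(7) + sum(p[nz] * log2(p[nz]))
  max(ic, 0)
}

#' Build a sequence-logo matrix from surface scores at base positions
#'
#' For each base centroid (ordered 5' to 3') the score vectors within 3 A
#' are averaged, the information content is computed, and letter heights for
#' A/G/C/U are the information content proportioned by the raw class
#' probabilities (P/R/X mass is omitted from display, so heights sum to at
#' most the information content). A gap is assigned when the centroid is at
#' least `gap_dist` (default 5 A) from the protein, or when no grid point
#' lies within the averaging radius.
#'
#' @param point_scores Tibble with `prob_*` columns aligned with `grid`.
#' @param grid Grid tibble.
#' @param base_centroids Tibble of base constituent centroids in strand
#'   order (rows of [decompose_structure()] with `kind` in A/G/C/U).
#' @param structure A `complex_structure` (for the gap rule).
#' @param radius Averaging radius (A).
#' @param gap_dist Protein-distance threshold for gaps (A).
#' @return An `rnasurf_logo` tibble: `position`, `kind`, `prob_A` ...
#'   `prob_U` (full 7-class averages), `height_A` ... `height_U`,
#'   `info_bits`, `gap`, `n_points`.
#' @export
build_logo <- function(point_scores, grid, base_centroids, structure,
                       radius = 3, gap_dist = 5) {
  stopifnot(all(base_centroids$kind %in% BASES))
  pxyz <- atom_xyz(protein_atoms(structure))
  rows <- lapply(seq_len(nrow(base_centroids)), function(i) {
    ctr <- c(base_centroids$x[i], base_centroids$y[i], base_centroids$z[i])
    avg <- average_scores_at_base(point_scores, grid, ctr, radius)
    prot_dist <- min(sqrt(colSums((t(pxyz) - ctr)^2)))
    gap <- prot_dist >= gap_dist || avg$n_points == 0
    p <- as.numeric(avg[1, prob_cols()])
    ic <- if (gap) 0 else information_content(p)
    heights <- if (gap) rep(0, 4) else
      ic * p[match(BASES, CLASSES7)]
    out <- avg
    out$position <- i
    out$kind <- base_centroids$kind[i]
    for (b in seq_along(BASES)) out[[paste0("height_", BASES[b])]] <- heights[b]
    out$info_bits <- ic
    out$gap <- gap
    out
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("position", "kind", prob_cols(),
                 paste0("height_", BASES), "info_bits", "gap", "n_points")]
  class(out) <- c("rnasurf_logo", class(out))
  out
}

#' Write a logo matrix as delimited text
#'
#' Columns: position, A, C, G, U (letter heights), info_bits, gap.
#'
#' @param logo An `rnasurf_logo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo <- function(logo, path) {
  out <- tibble::tibble(position = logo$position,
                        A = logo$height_A, C = logo$height_C,
                        G = logo$height_G, U = logo$height_U,
                        info_bits = logo$info_bits, gap = logo$gap)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the base probabilities of a logo as a MEME motif
#'
#' Per-position probabilities renormalized over A/C/G/U, in MEME minimal
#' motif format (alphabet ACGU); gap positions are written as uniform rows.
#'
#' @param logo An `rnasurf_logo`.
#' @param path Output path.
#' @param name Motif name.
#' @return `path`, invisibly.
#' @export
write_meme <- function(logo, path, name = "rnasurf_motif") {
  probs <- as.matrix(logo[, paste0("prob_", c("A", "C", "G", "U"))])
  s <- rowSums(probs)
  probs[s > 0, ] <- probs[s > 0, , drop = FALSE] / s[s > 0]
  probs[s == 0 | logo$gap, ] <- 1 / 4
  lines <- c("MEME version 4", "", "ALPHABET= ACGU", "",
             "strands: +", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 U 0.25", "",
             paste("MOTIF", name),
             sprintf("letter-probability matrix: alength= 4 w= %d",
                     nrow(probs)),
             apply(probs, 1, function(r)
               paste(sprintf("%.6f", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Plot a sequence-logo matrix
#'
#' Stacked-bar rendering of letter heights (bits) per position; gap
#' positions are blank.
#'
#' @param object An `rnasurf_logo`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rnasurf_logo
#' @export
autoplot.rnasurf_logo <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("position", paste0("height_", BASES))],
    cols = -"position", names_to = "base", values_to = "height",
    names_prefix = "height_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$height,
                                     fill = .data$base)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::scale_fill_manual(values = c(A = "#1f77b4", G = "#17becf",
                                          C = "#d62728", U = "#9467bd")) +
    ggplot2::labs(x = "base position (5' to 3')", y = "bits",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
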