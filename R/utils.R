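## Internal helpers shared across modules.

## Run `expr` under a fixed RNG state without disturbing the caller's
## .Random.seed (all randomness in the package flows from explicit seeds).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

## sample() resizes a length-one x to seq_len(x); this keeps set semantics.
sample_from <- function(x, n) {
  if (length(x) <= 1 || n >= length(x)) return(x[seq_len(min(n, length(x)))])
  sample(x, n)
}

## Euclidean distances from each row of `a` (n x 3) to each row of `b` (m x 3).
## Returns n x m matrix.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Minimum distance from each row of `a` to any row of `b`, with the index of
## the nearest row. Chunked so that huge lattices do not allocate n x m at once.
min_dist_to <- function(a, b, chunk = 2000L) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  dmin <- numeric(n)
  imin <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d <- cross_dist(a[s:e, , drop = FALSE], b)
    imin[s:e] <- max.col(-d, ties.method = "first")
    dmin[s:e] <- d[cbind(seq_len(e - s + 1L), imin[s:e])]
  }
  list(dist = dmin, index = imin)
}

## Normalize rows of a non-negative matrix to sum to one; all-zero rows stay 0.
row_normalize <- function(m) {
  s <- rowSums(m)
  pos <- s > 0
  m[pos, ] <- m[pos, , drop = FALSE] / s[pos]
  m
}

is_prob_vector <- function(p, tol = 1e-6) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol) && abs(sum(p) - 1) <= tol
}

## Kabsch superposition: rigid transform (rotation + translation) taking the
## rows of `from` onto `to` in the least-squares sense.
kabsch <- function(from, to) {
  from <- as.matrix(from); to <- as.matrix(to)
  cf <- colMeans(from); ct <- colMeans(to)
  a <- sweep(from, 2, cf); b <- sweep(to, 2, ct)
  s <- svd(crossprod(a, b))
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = rot, from_center = cf, to_center = ct)
}

apply_kabsch <- function(xyz, tr) {
  sweep(sweep(as.matrix(xyz), 2, tr$from_center) %*% t(tr$rotation), 2,
        tr$to_center, "+")
}

## Dihedral angle (degrees, in (-180, 180]) defined by four points; NA when
## three consecutive points are (near-)collinear.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  if (sqrt(sum(cr(b1, b2)^2)) < 1e-6 * sqrt(sum(b1^2) * sum(b2^2)) ||
      sqrt(sum(cr(b2, b3)^2)) < 1e-6 * sqrt(sum(b2^2) * sum(b3^2))) {
    return(NA_real_)
  }
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## Score-vector tibble helpers: per-point class probabilities live in columns
## prob_X, prob_P, ..., prob_U.
prob_cols <- function(classes = CLASSES7) paste0("prob_", classes)

score_matrix <- function(scores, classes = CLASSES7) {
  m <- as.matrix(scores[, prob_cols(classes), drop = FALSE])
  colnames(m) <- classes
  m
}
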