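## Idealized nucleotide geometry, built programmatically: planar nucleobase
## templates (regular-polygon rings, standard-ish bond lengths) and a ribose +
## phosphate backbone template. Chemical realism beyond correct atom
## inventories, moiety connectivity and sensible bond distances is not
## attempted; downstream code only relies on centroids and distances.

RING_BOND <- 1.38   # aromatic ring bond length, Angstrom
EXO_BOND <- 1.30    # exocyclic substituent bond length
GLYCOSIDIC_BOND <- 1.47

polygon_coords <- function(n, edge, start_angle = 0) {
  r <- edge / (2 * sin(pi / n))
  ang <- start_angle + 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(ang), r * sin(ang))
}

## Planar heavy-atom template for one nucleobase, as a matrix with rownames =
## atom names and columns (x, y, z). The glycosidic nitrogen sits at the
## origin with the ring extending along +x; z is the base-plane normal (0).
base_template <- function(base) {
  base <- match.arg(base, BASES)
  if (base %in% c("C", "U")) {
    ring_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
    hex <- polygon_coords(6, RING_BOND, start_angle = pi) # N1 at (-r, 0)
    rownames(hex) <- ring_names
    exo <- function(at) {
      v <- hex[at, ]
      v + EXO_BOND * v / sqrt(sum(v^2))
    }
    xy <- rbind(hex,
                O2 = exo("C2"),
                if (base == "C") rbind(N4 = exo("C4")) else rbind(O4 = exo("C4")))
    glyc <- "N1"
  } else {
    ring_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
    hex <- polygon_coords(6, RING_BOND, start_angle = 0)
    rownames(hex) <- ring_names
    ## Fuse the imidazole ring on the C4-C5 edge, on the far side from the
    ## hexagon center.
    m <- (hex["C4", ] + hex["C5", ]) / 2
    dir <- m / sqrt(sum(m^2))
    rp <- RING_BOND / (2 * sin(pi / 5))
    ap <- rp * cos(pi / 5)
    pc <- m + ap * dir
    a4 <- atan2(hex["C4", 2] - pc[2], hex["C4", 1] - pc[1])
    a5 <- atan2(hex["C5", 2] - pc[2], hex["C5", 1] - pc[1])
    ## Walk the pentagon from C4 away from C5: N9, C8, N7.
    step <- 2 * pi / 5
    d5 <- ((a5 - a4) %% (2 * pi))
    sgn <- if (abs(d5 - step) < abs(d5 - (2 * pi - step))) -1 else 1
    pent <- t(vapply(1:3, function(k) {
      a <- a4 + sgn * k * step
      pc + rp * c(cos(a), sin(a))
    }, numeric(2)))
    rownames(pent) <- c("N9", "C8", "N7")
    exo <- function(at) {
      v <- hex[at, ]
      v + EXO_BOND * v / sqrt(sum(v^2))
    }
    xy <- rbind(hex, pent,
                if (base == "A") rbind(N6 = exo("C6"))
                else rbind(O6 = exo("C6"), N2 = exo("C2")))
    glyc <- "N9"
  }
  ## Shift the glycosidic nitrogen to the origin and orient the ring along +x.
  xy <- sweep(xy, 2, xy[glyc, ])
  centroid <- colMeans(xy)
  ang <- atan2(centroid[2], centroid[1])
  rot <- matrix(c(cos(-ang), -sin(-ang), sin(-ang), cos(-ang)), 2, 2,
                byrow = TRUE)
  xy <- xy %*% t(rot)
  cbind(xy, z = 0)
}

GLYCOSIDIC_ATOM <- c(A = "N9", G = "N9", C = "N1", U = "N1")

## Ribose + phosphate backbone template in a local frame: planar ribose
## pentagon (pucker ignored) with exocyclic oxygens and the 5' arm.
backbone_template <- function() {
  ring <- polygon_coords(5, 1.52, start_angle = 0)
  rownames(ring) <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  ring <- cbind(ring, z = 0)
  out_of_plane <- c(0, 0, 1)
  radial <- function(at, d) {
    v <- ring[at, 1:2]
    c(v + d * v / sqrt(sum(v^2)), 0)
  }
  o2p <- radial("C2'", 1.41) + 0.4 * out_of_plane
  o3p <- radial("C3'", 1.41) - 0.4 * out_of_plane
  c5p <- radial("C4'", 1.51) + 0.9 * out_of_plane
  o5p <- c5p + c(0.4, 0.4, 1.2)
  p <- o5p + c(0.2, 0.2, 1.4)
  op1 <- p + c(1.3, 0.6, 0.3)
  op2 <- p + c(-0.6, -1.3, 0.3)
  rbind(ring,
        "O2'" = o2p, "O3'" = o3p, "C5'" = c5p, "O5'" = o5p,
        "P" = p, "OP1" = op1, "OP2" = op2)
}

## Place one full nucleotide (backbone + base) in a world frame given by an
## origin and an orthonormal 3x3 basis (columns = local x, y, z). The base is
## attached at C1' along the local base_direction (unit vector, world frame).
place_nucleotide <- function(base, origin, basis, base_direction = NULL,
                             with_phosphate = TRUE) {
  bb <- backbone_template()
  if (!with_phosphate) {
    bb <- bb[!(rownames(bb) %in% PHOSPHATE_ATOMS), , drop = FALSE]
  }
  world_bb <- sweep(bb %*% t(basis), 2, origin, "+")
  c1 <- world_bb["C1'", ]
  ribose_centroid <- colMeans(world_bb[rownames(world_bb) %in% RIBOSE_ATOMS,
                                       , drop = FALSE])
  u <- if (is.null(base_direction)) c1 - ribose_centroid else base_direction
  u <- u / sqrt(sum(u^2))
  ## Build an orthonormal frame (u, v, w) for the base plane.
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  frame <- cbind(u, v, w)
  tmpl <- base_template(base)
  n_pos <- c1 + GLYCOSIDIC_BOND * u
  world_base <- sweep(tmpl %*% t(frame), 2, n_pos, "+")
  rbind(world_bb, world_base)
}
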