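## Trinucleotide conformer machinery: a synthetic backbone conformer library
## binned over pseudo-torsion parameters, sequence expansion to all 64 base
## assignments with idealized base placement, and coarse-graining to 9-node
## (3 x {P, R, base}) models for clique alignment.

## Compact atom container used for conformers (cheaper than a tibble when
## tens of thousands of variants are materialized).
conformer_atoms <- function(xyz, name, resno, resname) {
  list(xyz = xyz, name = name, resno = resno, resname = resname)
}

#' Generate a synthetic trinucleotide backbone conformer library
#'
#' Builds `n_conformers` backbone-only trinucleotide conformations (no base
#' atoms) by sweeping helical placement parameters (twist, rise, radius) over
#' a 15-degree-style binned grid with seeded jitter, emulating a
#' pseudo-torsion-binned conformer library at desk scale. Synthetic: the
#' geometries are idealized placements, not PDB-derived conformers.
#'
#' @param n_conformers Number of conformers (default 296).
#' @param seed Integer seed.
#' @return A `conformer_library`: tibble with `conformer_id`, `source_bin`
#'   and `atoms` (list column of backbone atom sets, 36 heavy atoms each).
#' @export
synthetic_conformer_library <- function(n_conformers = 296L, seed = 1L) {
  stopifnot(n_conformers >= 1)
  rotz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                               0, 0, 1), 3, byrow = TRUE)
  rotx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a),
                               0, sin(a), cos(a)), 3, byrow = TRUE)
  tmpl <- backbone_template()
  with_seed(seed, {
    rows <- vector("list", n_conformers)
    for (i in seq_len(n_conformers)) {
      twist_bin <- (i - 1) %% 24                    # 15-degree twist bins
      tilt_bin <- ((i - 1) %/% 24) %% 5
      twist <- (twist_bin * 15 + runif(1, -5, 5)) * pi / 180
      tilt <- (tilt_bin * 15 - 30 + runif(1, -5, 5)) * pi / 180
      xyz <- NULL; nm <- NULL; resno <- NULL
      prev <- NULL
      for (j in 0:2) {
        rot <- rotz(j * twist) %*% rotx(j * tilt)
        bb <- tmpl %*% t(rot)
        if (is.null(prev)) {
          offset <- c(0, 0, 0)
        } else {
          ## chain the backbone: P of this nucleotide bonds to the previous
          ## O3' at 1.6 A along the C3'-O3' direction
          u <- prev["O3'", ] - prev["C3'", ]
          u <- u / sqrt(sum(u^2))
          offset <- prev["O3'", ] + 1.6 * u - bb["P", ]
        }
        bb <- sweep(bb, 2, offset, "+")
        prev <- bb
        xyz <- rbind(xyz, bb)
        nm <- c(nm, rownames(tmpl))
        resno <- c(resno, rep(j + 1L, nrow(bb)))
      }
      rows[[i]] <- tibble::tibble(
        conformer_id = i,
        source_bin = sprintf("t%02d_r%d", twist_bin, tilt_bin),
        atoms = list(conformer_atoms(xyz, nm, resno,
                                     rep(NA_character_, length(nm)))))
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("conformer_library", class(out))
    out
  })
}

## All 64 trinucleotide sequences, in a fixed order.
all_trinucleotide_sequences <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

## Base placements for one backbone conformer: a list indexed [[resno]][[base]]
## of world-frame base-atom blocks.
base_blocks_for_conformer <- function(atoms) {
  blocks <- vector("list", 3)
  for (j in 1:3) {
    sel <- atoms$resno == j
    nm <- atoms$name[sel]
    xyz <- atoms$xyz[sel, , drop = FALSE]
    c1 <- xyz[nm == "C1'", ]
    ribose <- xyz[nm %in% RIBOSE_ATOMS, , drop = FALSE]
    u <- c1 - colMeans(ribose)
    u <- u / sqrt(sum(u^2))
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- ref - sum(ref * u) * u; v <- v / sqrt(sum(v^2))
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    frame <- cbind(u, v, w)
    n_pos <- c1 + GLYCOSIDIC_BOND * u
    blocks[[j]] <- lapply(setNames(BASES, BASES), function(b) {
      tmpl <- base_template(b)
      list(xyz = sweep(tmpl %*% t(frame), 2, n_pos, "+"),
           name = rownames(tmpl))
    })
  }
  blocks
}

#' Expand a backbone conformer library over all trinucleotide sequences
#'
#' Instantiates every backbone conformer with all 4^3 = 64 base assignments:
#' base heavy atoms are placed by standard glycosidic geometry (idealized
#' planar base templates attached at C1'), standing in for force-field
#' refinement at desk scale; the `regularized` flag records that placed
#' bases carry idealized internal geometry. The result has exactly
#' `64 * nrow(library)` variants with no duplicate (conformer, sequence)
#' pair.
#'
#' @param library A `conformer_library`.
#' @param sequences Optional character vector of 3-letter sequences to
#'   instantiate (default: all 64).
#' @return Tibble with `conformer_id`, `source_bin`, `sequence`, `atoms`
#'   (list column; full heavy atoms of the trinucleotide) and `regularized`.
#' @export
expand_conformer_sequences <- function(library, sequences = NULL) {
  if (nrow(library) == 0) abort("conformer library is empty")
  sequences <- sequences %||% all_trinucleotide_sequences()
  bad <- sequences[!grepl("^[AGCU]{3}$", sequences)]
  if (length(bad)) abort(paste0("invalid trinucleotide sequences: ",
                                paste(bad, collapse = ", ")))
  n_var <- nrow(library) * length(sequences)
  conformer_id <- integer(n_var); source_bin <- character(n_var)
  sequence <- character(n_var); atoms <- vector("list", n_var)
  pos <- 0L
  for (i in seq_len(nrow(library))) {
    bb <- library$atoms[[i]]
    if (is.null(bb$xyz) || nrow(bb$xyz) == 0 ||
        !all(c("C1'", "O4'", "C2'") %in% bb$name)) {
      warn(sprintf("skipping malformed conformer %s",
                   library$conformer_id[i]))
      next
    }
    blocks <- base_blocks_for_conformer(bb)
    for (sq in sequences) {
      letters3 <- strsplit(sq, "")[[1]]
      xyz <- rbind(bb$xyz,
                   blocks[[1]][[letters3[1]]]$xyz,
                   blocks[[2]][[letters3[2]]]$xyz,
                   blocks[[3]][[letters3[3]]]$xyz)
      nm <- c(bb$name,
              blocks[[1]][[letters3[1]]]$name,
              blocks[[2]][[letters3[2]]]$name,
              blocks[[3]][[letters3[3]]]$name)
      resno <- c(bb$resno,
                 rep(1L, length(blocks[[1]][[letters3[1]]]$name)),
                 rep(2L, length(blocks[[2]][[letters3[2]]]$name)),
                 rep(3L, length(blocks[[3]][[letters3[3]]]$name)))
      resname <- letters3[resno]
      pos <- pos + 1L
      conformer_id[pos] <- library$conformer_id[i]
      source_bin[pos] <- library$source_bin[i]
      sequence[pos] <- sq
      atoms[[pos]] <- conformer_atoms(xyz, nm, resno, resname)
    }
  }
  tibble::tibble(conformer_id = conformer_id[seq_len(pos)],
                 source_bin = source_bin[seq_len(pos)],
                 sequence = sequence[seq_len(pos)],
                 atoms = atoms[seq_len(pos)],
                 regularized = TRUE)
}

#' Coarse-grain a trinucleotide conformer to its 9-node model
#'
#' Reduces a full-atom trinucleotide to the centroids of its constituents:
#' per nucleotide one phosphate (P), one ribose (R) and one base node
#' (labeled with the base letter). A 5'-terminal nucleotide without
#' phosphate yields an 8-node model, flagged via the `complete` attribute.
#'
#' @param variant One row of [expand_conformer_sequences()] output (or a
#'   list with `atoms` and `sequence`).
#' @return Tibble of nodes: `resno`, `kind`, `x`, `y`, `z`, with attribute
#'   `complete` (TRUE when all 9 nodes are present).
#' @export
coarse_grain <- function(variant) {
  at <- if (!is.null(variant$atoms) && !is.null(variant$atoms$xyz)) {
    variant$atoms
  } else variant$atoms[[1]]
  seq3 <- strsplit(variant$sequence[[1]], "")[[1]]
  rows <- list()
  for (j in sort(unique(at$resno))) {
    sel <- at$resno == j
    nm <- normalize_atom_name(at$name[sel])
    xyz <- at$xyz[sel, , drop = FALSE]
    moiety <- ifelse(nm %in% PHOSPHATE_ATOMS, "P",
                     ifelse(nm %in% RIBOSE_ATOMS, "R", "base"))
    for (m in c("P", "R", "base")) {
      msel <- moiety == m
      if (!any(msel)) next
      kind <- if (m == "base") seq3[j] else m
      rows[[paste(j, m)]] <- tibble::tibble(
        resno = j, kind = kind,
        x = mean(xyz[msel, 1]), y = mean(xyz[msel, 2]),
        z = mean(xyz[msel, 3]))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "complete") <- nrow(out) == 9
  out
}

#' Write a conformer library as a multi-model PDB file
#'
#' @param library A `conformer_library` (all conformers must share an atom
#'   inventory, as backbone-only conformers do).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conformer_library <- function(library, path) {
  first <- library$atoms[[1]]
  xyz <- t(vapply(library$atoms, function(a) as.numeric(t(a$xyz)),
                  numeric(3 * nrow(first$xyz))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(first$xyz)),
                   resno = first$resno,
                   resid = rep("BBN", nrow(first$xyz)),
                   chain = rep("A", nrow(first$xyz)),
                   elety = first$name,
                   o = rep(1, nrow(first$xyz)),
                   b = rep(0, nrow(first$xyz)),
                   elesy = element_from_name(first$name))
  invisible(path)
}

#' Read a multi-model PDB conformer library
#'
#' @param path Path to a multi-model PDB of backbone trinucleotides.
#' @return A `conformer_library` tibble.
#' @export
read_conformer_library <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  nm <- normalize_atom_name(pdb$atom$elety)
  resno <- pdb$atom$resno
  rows <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    tibble::tibble(conformer_id = m, source_bin = NA_character_,
                   atoms = list(conformer_atoms(xyz, nm, resno,
                                                rep(NA_character_,
                                                    length(nm)))))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("conformer_library", class(out))
  out
}
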