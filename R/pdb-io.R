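## Structure input/output and nucleotide decomposition.

normalize_atom_name <- function(name) {
  name <- gsub("\\*", "'", trimws(name))
  name[name == "O1P"] <- "OP1"
  name[name == "O2P"] <- "OP2"
  name[name == "O3P"] <- "OP3"
  name
}

element_from_name <- function(name) {
  stripped <- sub("^[0-9']*", "", trimws(name))
  two <- toupper(substr(stripped, 1, 2))
  el <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"),
               two, toupper(substr(stripped, 1, 1)))
  el
}

classify_chain <- function(resnames, rna_fraction = 0.8) {
  n <- length(resnames)
  if (n == 0) return("other")
  if (mean(resnames %in% AA3) >= rna_fraction) return("protein")
  if (mean(resnames %in% RNA_RESNAMES) >= rna_fraction) return("rna")
  "other"
}

#' Parse a PDB-format structure into a tidy complex structure
#'
#' Reads the ATOM/HETATM records of one model of a PDB file, resolves
#' alternate locations (highest occupancy wins; ties go to the first altloc
#' alphabetically), optionally drops hydrogens, and classifies each chain as
#' protein, RNA or other by its residue alphabet (a chain is protein/RNA when
#' at least 80% of its residues match the respective alphabet; DNA chains
#' fall into "other" and are excluded from downstream analysis).
#'
#' @param path Path to a PDB-format file.
#' @param model_index 1-based model to read from a multi-model file.
#' @param drop_hydrogens Drop hydrogen atoms (heavy atoms only are used
#'   throughout the pipeline).
#' @return An object of class `complex_structure`: a list with `atoms`
#'   (a tibble with one row per atom: `name`, `element`, `x`, `y`, `z`,
#'   `residue_name`, `chain`, `resno`, `insert`, `b_factor`, `occupancy`,
#'   `altloc`, `molecule_class`) and `chains` (chain id and molecule class).
#' @export
parse_structure <- function(path, model_index = 1L, drop_hydrogens = TRUE) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("Failed to parse PDB file '", path,
                                     "': ", conditionMessage(e)))
  )
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models)) n_models <- 1L
  if (model_index < 1L || model_index > n_models) {
    abort(sprintf("model_index %d out of range: file has %d model(s)",
                  model_index, n_models))
  }
  at <- pdb$atom
  if (nrow(at) == 0) abort("empty model: no ATOM/HETATM records parsed")
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)

  atoms <- tibble::tibble(
    name = normalize_atom_name(at$elety),
    element = ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
                     element_from_name(at$elety), toupper(trimws(at$elesy))),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    residue_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )
  if (drop_hydrogens) atoms <- atoms[!(atoms$element %in% c("H", "D")), ]
  if (nrow(atoms) == 0) abort("empty model: no heavy atoms in selection")

  ## Altloc resolution: per physical atom keep the highest-occupancy record.
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)

  new_complex_structure(atoms)
}

new_complex_structure <- function(atoms) {
  chains <- atoms |>
    dplyr::distinct(.data$chain, .data$resno, .data$insert,
                    .data$residue_name) |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(molecule_class = classify_chain(.data$residue_name),
                     n_residues = dplyr::n(), .groups = "drop")
  atoms$molecule_class <-
    chains$molecule_class[match(atoms$chain, chains$chain)]
  structure(list(atoms = atoms, chains = chains),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure> ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$chains), " chain(s): ",
      paste0(x$chains$chain, " (", x$chains$molecule_class, ", ",
             x$chains$n_residues, " res)", collapse = ", "), "\n", sep = "")
  invisible(x)
}

protein_atoms <- function(structure) {
  dplyr::filter(structure$atoms, .data$molecule_class == "protein")
}

rna_atoms <- function(structure) {
  dplyr::filter(structure$atoms, .data$molecule_class == "rna")
}

atom_xyz <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

#' Decompose a ribonucleotide into constituent centroids
#'
#' Splits the heavy atoms of one standard ribonucleotide (A/G/C/U) into the
#' three chemical moieties — phosphate, ribose and nucleobase — at the
#' phosphodiester and glycosidic bonds, and returns the geometric centroid of
#' each moiety. The phosphate moiety is `P, OP1, OP2, OP3, O5'`; the ribose is
#' `C1'-C5', O4', O2', O3'`; every remaining heavy atom belongs to the base.
#' A 5'-terminal nucleotide without a phosphate yields two centroids.
#'
#' @param residue_atoms Tibble of the atoms of a single residue (rows of a
#'   `complex_structure` `atoms` tibble).
#' @return Tibble with one row per constituent: `kind` (`"P"`, `"R"`, or the
#'   base letter), `x`, `y`, `z`, `chain`, `resno`, `residue_name`. Modified
#'   or unknown nucleotides return an empty tibble with a warning.
#' @export
decompose_nucleotide <- function(residue_atoms) {
  empty <- tibble::tibble(kind = character(), x = numeric(), y = numeric(),
                          z = numeric(), chain = character(),
                          resno = integer(), residue_name = character())
  resname <- unique(residue_atoms$residue_name)
  if (length(resname) != 1 || !(resname %in% RNA_RESNAMES)) {
    warn(paste0("skipping non-standard nucleotide: ",
                paste(resname, collapse = "/")))
    return(empty)
  }
  nm <- normalize_atom_name(residue_atoms$name)
  heavy <- !(residue_atoms$element %in% c("H", "D"))
  residue_atoms <- residue_atoms[heavy, ]
  nm <- nm[heavy]
  moiety <- ifelse(nm %in% PHOSPHATE_ATOMS, "P",
                   ifelse(nm %in% RIBOSE_ATOMS, "R", "base"))
  out <- list()
  for (m in c("P", "R", "base")) {
    sel <- moiety == m
    if (!any(sel)) next
    kind <- if (m == "base") resname else m
    out[[m]] <- tibble::tibble(
      kind = kind,
      x = mean(residue_atoms$x[sel]),
      y = mean(residue_atoms$y[sel]),
      z = mean(residue_atoms$z[sel]),
      chain = residue_atoms$chain[1],
      resno = residue_atoms$resno[1],
      residue_name = resname
    )
  }
  dplyr::bind_rows(out)
}

#' Decompose every RNA nucleotide of a structure into constituent centroids
#'
#' @param structure A `complex_structure`.
#' @return Tibble of constituent centroids (see [decompose_nucleotide()]),
#'   ordered by chain and residue number.
#' @export
decompose_structure <- function(structure) {
  ra <- rna_atoms(structure)
  if (nrow(ra) == 0) {
    return(tibble::tibble(kind = character(), x = numeric(), y = numeric(),
                          z = numeric(), chain = character(),
                          resno = integer(), residue_name = character()))
  }
  ra |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert) |>
    dplyr::group_map(~ decompose_nucleotide(.x |>
      dplyr::mutate(chain = .y$chain, resno = .y$resno))) |>
    dplyr::bind_rows()
}

#' Write a complex structure to a PDB-format file
#'
#' @param structure A `complex_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(atom_xyz(a))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$residue_name,
                   chain = a$chain, elety = a$name,
                   o = a$occupancy, b = a$b_factor, elesy = a$element)
  invisible(path)
}

PSEUDOATOM_RESNAMES <- c(P = "PHO", R = "RIB", A = "ADE", G = "GUA",
                         C = "CYT", U = "URA")

#' Export top-scoring grid points as PDB pseudo-atoms
#'
#' Writes, for each of the six binding classes, the grid points whose class
#' score falls in the top fraction (at most `ceiling(top_fraction * n)` points
#' per class) as pseudo-atoms with the class score in the B-factor column,
#' so predictions can be rendered in any molecular viewer. Pseudo-atoms use
#' element "X" and residue names PHO/RIB/ADE/GUA/CYT/URA.
#'
#' @param grid Grid tibble with `x`, `y`, `z` columns.
#' @param scores Score tibble with `prob_*` columns, one row per grid point.
#' @param path Output PDB path.
#' @param top_fraction Fraction of points kept per class (default 0.1, the
#'   visualization default).
#' @return `path`, invisibly.
#' @export
write_pseudoatom_scores <- function(grid, scores, path, top_fraction = 0.1) {
  if (nrow(grid) != nrow(scores)) {
    abort("grid and scores must have one row per grid point")
  }
  rows <- list()
  if (nrow(grid) > 0) {
    keep_n <- ceiling(top_fraction * nrow(grid))
    for (cls in names(PSEUDOATOM_RESNAMES)) {
      p <- scores[[paste0("prob_", cls)]]
      ord <- order(p, decreasing = TRUE)[seq_len(min(keep_n, length(p)))]
      ord <- ord[p[ord] > 0]
      if (length(ord) == 0) next
      rows[[cls]] <- tibble::tibble(
        x = grid$x[ord], y = grid$y[ord], z = grid$z[ord],
        resid = PSEUDOATOM_RESNAMES[[cls]], b = p[ord])
    }
  }
  if (length(rows) == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  all <- dplyr::bind_rows(rows)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(cbind(all$x, all$y, all$z))),
                   type = rep("HETATM", nrow(all)),
                   resno = seq_len(nrow(all)), resid = all$resid,
                   chain = rep("Z", nrow(all)),
                   elety = rep("X", nrow(all)),
                   o = rep(1, nrow(all)), b = round(all$b, 2),
                   elesy = rep("X", nrow(all)))
  invisible(path)
}
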