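## FEATURE-style radial-shell encoding: the physicochemical environment of a
## location is a 6-shell x 80-property tensor accumulated over protein heavy
## atoms within 7.5 A. The 80-slot default registry is an in-package
## approximation of the classic per-atom property list (elements, atom
## functional classes, residue identity and classes, charges, hydrogen-bond
## roles, backbone-dihedral secondary structure, hydropathy, solvent
## accessibility, size/electronic constants, mobility), padded with
## documented non-protein slots that evaluate to zero because only protein
## atoms are featurized.

KD_HYDROPATHY <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5,
                   CYS = 2.5, GLN = -3.5, GLU = -3.5, GLY = -0.4,
                   HIS = -3.2, ILE = 4.5, LEU = 3.8, LYS = -3.9,
                   MET = 1.9, PHE = 2.8, PRO = -1.6, SER = -0.8,
                   THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

RES_CLASS <- list(
  hydrophobic = c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "CYS"),
  polar = c("SER", "THR", "ASN", "GLN", "TYR", "HIS"),
  charged_pos = c("LYS", "ARG", "HIS"),
  charged_neg = c("ASP", "GLU"),
  aromatic = c("PHE", "TYR", "TRP", "HIS"),
  aliphatic = c("ALA", "VAL", "LEU", "ILE"),
  small = c("GLY", "ALA", "SER", "CYS", "THR"),
  proline = "PRO")

VDW_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
COV_RADIUS <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07)
ELECTRONEG <- c(C = 2.55, N = 3.04, O = 3.44, S = 2.58, P = 2.19)
ATOMIC_MASS <- c(C = 12.01, N = 14.01, O = 16.00, S = 32.06, P = 30.97)
elem_const <- function(el, table, default) {
  out <- unname(table[el]); out[is.na(out)] <- default; out
}

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

res_atom_in <- function(residue_name, name, table) {
  idx <- match(residue_name, names(table))
  out <- logical(length(name))
  has <- which(!is.na(idx))
  if (length(has)) {
    out[has] <- vapply(has, function(j) name[j] %in% table[[idx[j]]],
                       logical(1))
  }
  out
}

## Simplified per-atom partial charges: specific values for charged and
## backbone groups, generic element fallback elsewhere.
PARTIAL_CHARGE_TABLE <- c(
  "N" = -0.47, "CA" = 0.07, "C" = 0.51, "O" = -0.51, "OXT" = -0.67,
  "ASP:OD1" = -0.76, "ASP:OD2" = -0.76, "ASP:CG" = 0.62,
  "GLU:OE1" = -0.76, "GLU:OE2" = -0.76, "GLU:CD" = 0.62,
  "LYS:NZ" = -0.30, "ARG:CZ" = 0.64,
  "ARG:NH1" = -0.80, "ARG:NH2" = -0.80, "ARG:NE" = -0.70,
  "HIS:ND1" = -0.36, "HIS:NE2" = -0.70,
  "SER:OG" = -0.66, "THR:OG1" = -0.66, "TYR:OH" = -0.53,
  "CYS:SG" = -0.23, "MET:SD" = -0.09)
GENERIC_CHARGE <- c(C = -0.05, N = -0.40, O = -0.50, S = -0.20, P = 1.0)

partial_charge <- function(residue_name, name) {
  key <- paste0(residue_name, ":", name)
  q <- PARTIAL_CHARGE_TABLE[key]
  bb <- is.na(q) & name %in% names(PARTIAL_CHARGE_TABLE)
  q[bb] <- PARTIAL_CHARGE_TABLE[name[bb]]
  q
}

formal_charge <- function(residue_name, name) {
  fc <- numeric(length(name))
  fc[residue_name == "ASP" & name %in% c("OD1", "OD2")] <- -0.5
  fc[residue_name == "GLU" & name %in% c("OE1", "OE2")] <- -0.5
  fc[residue_name == "LYS" & name == "NZ"] <- 1
  fc[residue_name == "ARG" & name %in% c("NH1", "NH2")] <- 0.5
  fc
}

hb_donor_atom <- function(residue_name, name) {
  (name == "N" & residue_name != "PRO") |
    res_atom_in(residue_name, name, list(
      LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
      TRP = "NE1", SER = "OG", THR = "OG1", TYR = "OH",
      ASN = "ND2", GLN = "NE2", CYS = "SG"))
}

hb_acceptor_atom <- function(residue_name, name) {
  name %in% c("O", "OXT") |
    res_atom_in(residue_name, name, list(
      ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
      GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
      HIS = c("ND1", "NE2"), MET = "SD"))
}

## Secondary structure from backbone dihedrals: Ramachandran-region rules
## (helix and sheet boxes; everything else, including chain termini and
## residues with missing backbone atoms, is coil).
secondary_structure <- function(structure) {
  prot <- protein_atoms(structure)
  res <- prot |>
    dplyr::distinct(.data$chain, .data$resno) |>
    dplyr::arrange(.data$chain, .data$resno)
  res$ss <- "coil"
  get_atom <- function(chain, resno, nm) {
    row <- prot[prot$chain == chain & prot$resno == resno & prot$name == nm, ]
    if (nrow(row) == 0) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  for (i in seq_len(nrow(res))) {
    ch <- res$chain[i]; rn <- res$resno[i]
    c_prev <- get_atom(ch, rn - 1, "C")
    n_i <- get_atom(ch, rn, "N"); ca_i <- get_atom(ch, rn, "CA")
    c_i <- get_atom(ch, rn, "C"); n_next <- get_atom(ch, rn + 1, "N")
    if (is.null(c_prev) || is.null(n_i) || is.null(ca_i) ||
        is.null(c_i) || is.null(n_next)) next
    phi <- dihedral(c_prev, n_i, ca_i, c_i)
    psi <- dihedral(n_i, ca_i, c_i, n_next)
    if (is.na(phi) || is.na(psi)) next
    if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5) {
      res$ss[i] <- "helix"
    } else if (phi >= -180 && phi <= -60 &&
               (psi >= 90 || psi <= -150)) {
      res$ss[i] <- "sheet"
    }
  }
  res
}

## Shrake-Rupley rolling-probe solvent accessibility on heavy atoms.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_sasa <- function(structure, probe = 1.4, n_points = 64L) {
  prot <- protein_atoms(structure)
  xyz <- atom_xyz(prot)
  n <- nrow(xyz)
  radii <- elem_const(prot$element, VDW_RADIUS, 1.6) + probe
  sphere <- fibonacci_sphere(n_points)
  d <- cross_dist(xyz, xyz)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < radii[i] + radii & seq_len(n) != i)
    pts <- sweep(sphere * radii[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      dd <- cross_dist(pts, xyz[nb, , drop = FALSE])
      buried <- rowSums(dd < matrix(radii[nb], n_points, length(nb),
                                    byrow = TRUE)) > 0
      frac <- mean(!buried)
    } else frac <- 1
    sasa[i] <- 4 * pi * radii[i]^2 * frac
  }
  sasa
}

REGISTRY_CATEGORIES <- list(
  element = c("el_C", "el_N", "el_O", "el_S", "el_P", "el_other"),
  density = "atom_count",
  functional_group = c("fg_hydroxyl", "fg_amide_n", "fg_carbonyl_o",
                       "fg_carboxyl_o", "fg_amine_n", "fg_guanidinium_n",
                       "fg_imidazole_n", "fg_sulfur", "fg_aromatic_ring",
                       "fg_ring"),
  topology = c("top_backbone", "top_sidechain", "top_calpha", "top_cbeta"),
  residue = paste0("res_", AA3),
  residue_class = paste0("cls_", names(RES_CLASS)),
  charge = c("charge_formal", "charge_partial", "charge_partial_abs"),
  hbond = c("hb_donor", "hb_acceptor"),
  secondary_structure = c("ss_helix", "ss_sheet", "ss_coil"),
  hydropathy = c("hydropathy_kd", "hydropathy_sign"),
  solvent = c("sasa_area", "sasa_exposed"),
  size_electronic = c("vdw_radius", "covalent_radius", "electronegativity",
                      "atomic_mass"),
  mobility = c("b_factor", "occupancy"),
  non_protein = c("np_water", "np_nucleic_base", "np_nucleic_backbone",
                  "np_ion_pos", "np_ion_neg", "np_metal", "np_halogen",
                  "np_ligand_c", "np_ligand_n", "np_ligand_o",
                  "np_ligand_s", "np_ligand_p", "np_other"))

#' The default 80-slot physicochemical property registry
#'
#' Returns the versioned ordered list of the 80 per-atom properties used to
#' encode physicochemical environments. Slots cover element indicators, a
#' heavy-atom count, functional-group flags, backbone/sidechain topology, the
#' 20 residue-type indicators, residue-class indicators, formal and
#' simplified partial charges, hydrogen-bond donor/acceptor flags,
#' dihedral-based secondary structure of the possessing residue,
#' Kyte-Doolittle hydropathy, rolling-probe solvent accessibility,
#' size/electronic constants and crystallographic mobility, padded to exactly
#' 80 by documented non-protein slots (water / nucleic acid / ion / ligand)
#' that evaluate to zero because only protein atoms are featurized.
#'
#' @return Object of class `property_registry` with fields `version`, `slots`
#'   (tibble: `slot`, `name`, `category`) and `n` (always 80).
#' @export
default_registry <- function() {
  slots <- tibble::tibble(
    name = unlist(REGISTRY_CATEGORIES, use.names = FALSE),
    category = rep(names(REGISTRY_CATEGORIES),
                   lengths(REGISTRY_CATEGORIES)))
  slots$slot <- seq_len(nrow(slots))
  stopifnot(nrow(slots) == 80)
  structure(list(version = "rnasurf-80-v1",
                 slots = slots[, c("slot", "name", "category")],
                 n = nrow(slots)),
            class = "property_registry")
}

#' @export
print.property_registry <- function(x, ...) {
  cat("<property_registry> ", x$version, ": ", x$n,
      " per-atom property slots\n", sep = "")
  print(table(x$slots$category))
  invisible(x)
}

## Evaluate all registry properties on every protein atom of a structure.
## Returns an n_protein_atoms x 80 matrix, column order = registry order.
atom_property_matrix <- function(structure, registry = default_registry()) {
  prot <- protein_atoms(structure)
  n <- nrow(prot)
  m <- matrix(0, n, registry$n,
              dimnames = list(NULL, registry$slots$name))
  if (n == 0) return(m)
  el <- prot$element; nm <- prot$name; rn <- prot$residue_name
  m[, "el_C"] <- el == "C"; m[, "el_N"] <- el == "N"
  m[, "el_O"] <- el == "O"; m[, "el_S"] <- el == "S"
  m[, "el_P"] <- el == "P"
  m[, "el_other"] <- !(el %in% c("C", "N", "O", "S", "P"))
  m[, "atom_count"] <- 1
  m[, "fg_hydroxyl"] <- res_atom_in(rn, nm, list(SER = "OG", THR = "OG1",
                                                 TYR = "OH"))
  m[, "fg_amide_n"] <- (nm == "N") |
    res_atom_in(rn, nm, list(ASN = "ND2", GLN = "NE2"))
  m[, "fg_carbonyl_o"] <- (nm == "O") |
    res_atom_in(rn, nm, list(ASN = "OD1", GLN = "OE1"))
  m[, "fg_carboxyl_o"] <- (nm == "OXT") |
    res_atom_in(rn, nm, list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")))
  m[, "fg_amine_n"] <- res_atom_in(rn, nm, list(LYS = "NZ"))
  m[, "fg_guanidinium_n"] <- res_atom_in(rn, nm,
                                         list(ARG = c("NE", "NH1", "NH2")))
  m[, "fg_imidazole_n"] <- res_atom_in(rn, nm, list(HIS = c("ND1", "NE2")))
  m[, "fg_sulfur"] <- res_atom_in(rn, nm, list(CYS = "SG", MET = "SD"))
  m[, "fg_aromatic_ring"] <- res_atom_in(rn, nm, AROMATIC_RING_ATOMS)
  m[, "fg_ring"] <- m[, "fg_aromatic_ring"] |
    res_atom_in(rn, nm, list(PRO = c("N", "CA", "CB", "CG", "CD")))
  bb <- nm %in% BACKBONE_NAMES
  m[, "top_backbone"] <- bb
  m[, "top_sidechain"] <- !bb
  m[, "top_calpha"] <- nm == "CA"
  m[, "top_cbeta"] <- nm == "CB"
  for (aa in AA3) m[, paste0("res_", aa)] <- rn == aa
  for (cl in names(RES_CLASS)) {
    m[, paste0("cls_", cl)] <- rn %in% RES_CLASS[[cl]]
  }
  m[, "charge_formal"] <- formal_charge(rn, nm)
  q <- partial_charge(rn, nm)
  q[is.na(q)] <- elem_const(el[is.na(q)], GENERIC_CHARGE, 0)
  m[, "charge_partial"] <- q
  m[, "charge_partial_abs"] <- abs(q)
  m[, "hb_donor"] <- hb_donor_atom(rn, nm)
  m[, "hb_acceptor"] <- hb_acceptor_atom(rn, nm)
  ss <- secondary_structure(structure)
  key <- paste(prot$chain, prot$resno)
  ss_res <- ss$ss[match(key, paste(ss$chain, ss$resno))]
  m[, "ss_helix"] <- ss_res == "helix"
  m[, "ss_sheet"] <- ss_res == "sheet"
  m[, "ss_coil"] <- ss_res == "coil"
  kd <- unname(KD_HYDROPATHY[rn]); kd[is.na(kd)] <- 0
  m[, "hydropathy_kd"] <- kd
  m[, "hydropathy_sign"] <- kd > 0
  sasa <- atom_sasa(structure)
  m[, "sasa_area"] <- sasa
  m[, "sasa_exposed"] <- sasa > 2
  m[, "vdw_radius"] <- elem_const(el, VDW_RADIUS, 1.6)
  m[, "covalent_radius"] <- elem_const(el, COV_RADIUS, 0.9)
  m[, "electronegativity"] <- elem_const(el, ELECTRONEG, 2.2)
  m[, "atomic_mass"] <- elem_const(el, ATOMIC_MASS, 20)
  m[, "b_factor"] <- prot$b_factor
  m[, "occupancy"] <- prot$occupancy
  ## non_protein slots remain 0: only protein atoms are featurized
  storage.mode(m) <- "double"
  m
}

#' Assign a distance to its concentric shell
#'
#' The space around a grid point is divided into `n_shells` equal-width
#' concentric shells within `radius` (defaults: 6 shells within 7.5 A, shell
#' width 1.25 A). The outer bound is half-open: a distance equal to `radius`
#' falls in no shell.
#'
#' @param distance Non-negative distance(s) in Angstrom.
#' @param n_shells Number of shells.
#' @param radius Outer radius in Angstrom (> 0).
#' @return Integer shell indices in `0:(n_shells-1)`, `NA` outside `radius`.
#' @export
assign_shell <- function(distance, n_shells = 6L, radius = 7.5) {
  if (radius <= 0) abort("radius must be > 0")
  stopifnot(all(distance >= 0))
  idx <- floor(distance / (radius / n_shells))
  idx[distance >= radius] <- NA_integer_
  as.integer(idx)
}

#' Encode the physicochemical environment of one location
#'
#' Accumulates, for every protein heavy atom within `radius` of `center`,
#' the atom's 80 property values into the row of its concentric shell,
#' producing a 6 x 80 tensor (480 scalars). RNA, solvent, ion and other
#' non-protein atoms are excluded; an empty environment gives an all-zero
#' tensor.
#'
#' @param center Numeric length-3 coordinate (Angstrom).
#' @param structure A `complex_structure`.
#' @param registry A `property_registry` (default [default_registry()]).
#' @param n_shells,radius Shell geometry (defaults 6 within 7.5 A).
#' @param property_cache Optional precomputed [atom_property_matrix()] for
#'   `structure` (used by [featurize_grid()] to avoid recomputation).
#' @return A `feature_tensor`: 6 x 80 numeric matrix with attributes
#'   `center` and `registry_version`.
#' @export
featurize_point <- function(center, structure, registry = default_registry(),
                            n_shells = 6L, radius = 7.5,
                            property_cache = NULL) {
  props <- property_cache %||% atom_property_matrix(structure, registry)
  prot <- protein_atoms(structure)
  tensor <- matrix(0, n_shells, registry$n,
                   dimnames = list(paste0("shell", seq_len(n_shells) - 1),
                                   registry$slots$name))
  if (nrow(prot) > 0) {
    d <- sqrt(colSums((t(atom_xyz(prot)) - center)^2))
    sh <- assign_shell(d, n_shells, radius)
    ok <- !is.na(sh)
    if (any(ok)) {
      acc <- rowsum(props[ok, , drop = FALSE], group = sh[ok])
      tensor[as.integer(rownames(acc)) + 1L, ] <- acc
    }
  }
  structure(tensor, center = center, registry_version = registry$version,
            class = c("feature_tensor", "matrix", "array"))
}

#' Featurize every point of a grid
#'
#' @param grid Grid tibble with `x`, `y`, `z`.
#' @inheritParams featurize_point
#' @return Numeric matrix with one row per grid point and
#'   `n_shells * 80` columns (shell-major flattening), with attribute
#'   `registry_version`.
#' @export
featurize_grid <- function(grid, structure, registry = default_registry(),
                           n_shells = 6L, radius = 7.5) {
  props <- atom_property_matrix(structure, registry)
  out <- matrix(0, nrow(grid), n_shells * registry$n)
  for (i in seq_len(nrow(grid))) {
    tensor <- featurize_point(c(grid$x[i], grid$y[i], grid$z[i]), structure,
                              registry, n_shells, radius,
                              property_cache = props)
    out[i, ] <- as.numeric(t(tensor))  # shell-major
  }
  colnames(out) <- paste0(rep(paste0("s", seq_len(n_shells) - 1),
                              each = registry$n),
                          "_", rep(registry$slots$name, n_shells))
  attr(out, "registry_version") <- registry$version
  out
}
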