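# Property registry, shell assignment, and the radial-shell tensor encoder.

test_that("the default registry has exactly 80 versioned slots", {
  reg <- default_registry()
  expect_equal(reg$n, 80)
  expect_equal(nrow(reg$slots), 80)
  expect_false(anyDuplicated(reg$slots$name) > 0)
  expect_match(reg$version, "v1")
})

test_that("residue indicators and charged-group slots evaluate correctly", {
  gly <- atoms_tbl(c("N", "CA", "C", "O"), c(0, 1.4, 2, 1.2),
                   c(0, 0, 1.4, 2.4), 0, "GLY")
  lys <- atoms_tbl(c("N", "CA", "C", "O", "CB", "NZ"),
                   10 + c(0, 1.4, 2, 1.2, 1.9, 3),
                   c(0, 0, 1.4, 2.4, -0.8, -2), 0, "LYS", resno = 2L)
  st <- structure_from_atoms(dplyr::bind_rows(gly, lys))
  m <- rnasurf:::atom_property_matrix(st, default_registry())
  ca_gly <- which(st$atoms$name == "CA" & st$atoms$residue_name == "GLY")
  expect_equal(unname(m[ca_gly, "res_GLY"]), 1)
  expect_equal(sum(m[ca_gly, paste0("res_", rnasurf:::AA3)]), 1)
  nz <- which(st$atoms$name == "NZ")
  expect_equal(unname(m[nz, "charge_formal"]), 1)
  expect_equal(unname(m[nz, "hb_donor"]), 1)
  expect_equal(unname(m[nz, "fg_amine_n"]), 1)
  expect_equal(unname(m[nz, "cls_charged_pos"]), 1)
  # non-protein reserved slots are all zero
  np <- grep("^np_", colnames(m))
  expect_true(all(m[, np] == 0))
})

test_that("shell assignment is floor(d / width) with a half-open outer bound", {
  expect_equal(assign_shell(0.5), 0L)
  expect_equal(assign_shell(7.4), 5L)
  expect_true(is.na(assign_shell(7.5)))
  expect_equal(assign_shell(c(0, 1.24, 1.25, 6.24, 6.25)),
               c(0L, 0L, 1L, 4L, 5L))
  expect_error(assign_shell(1, radius = 0), "radius")
})

test_that("an empty environment gives the all-zero 6 x 80 tensor", {
  fx <- shared_fixture()$fx
  t0 <- featurize_point(c(500, 500, 500), fx$structure)
  expect_equal(dim(t0), c(6, 80))
  expect_true(all(t0 == 0))
  expect_equal(length(as.numeric(t0)), 480)
})

test_that("a single atom contributes exactly its properties to its shell", {
  st <- structure_from_atoms(atoms_tbl("CB", 1, 0, 0, "ALA"))
  reg <- default_registry()
  props <- rnasurf:::atom_property_matrix(st, reg)
  tensor <- featurize_point(c(0, 0, 0), st, reg)
  expect_equal(unname(tensor[1, ]), unname(props[1, ]))
  expect_true(all(tensor[2:6, ] == 0))
  # distance 1.0 lies in shell floor(1 / 1.25) = 0
  expect_equal(assign_shell(1.0), 0L)
})

test_that("featurization is additive in atoms", {
  at <- atoms_tbl(c("CA", "CB"), c(1, 3), 0, 0, "ALA")
  st1 <- structure_from_atoms(at)
  st2 <- structure_from_atoms(dplyr::bind_rows(at, at))
  t1 <- featurize_point(c(0, 0, 0), st1)
  t2 <- featurize_point(c(0, 0, 0), st2)
  # duplicated atoms double every accumulated value except the
  # environment-dependent solvent term, which is computed on the structure
  sasa_cols <- which(default_registry()$slots$name %in%
                       c("sasa_area", "sasa_exposed"))
  expect_equal(unname(t2[, -sasa_cols]), unname(2 * t1[, -sasa_cols]))
})

test_that("the tensor is invariant under rigid motion", {
  fx <- make_complex_fixture(fixture_spec(8, 0, rng_seed = 3))
  ctr <- c(5, 0, 5)
  t1 <- featurize_point(ctr, fx$structure)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
  shift <- c(11, -4, 2)
  at <- fx$structure$atoms
  xyz <- cbind(at$x, at$y, at$z) %*% t(rot) + matrix(shift, nrow(at), 3,
                                                     byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  st2 <- structure_from_atoms(at)
  t2 <- featurize_point(as.numeric(rot %*% ctr + shift), st2)
  # the solvent-accessibility slots use a fixed point-sphere sampling and are
  # only approximately rotation invariant; every other slot is exact
  reg <- default_registry()
  sasa_cols <- which(reg$slots$name %in% c("sasa_area", "sasa_exposed"))
  expect_equal(unname(t2[, -sasa_cols]), unname(t1[, -sasa_cols]),
               tolerance = 1e-9)
  expect_equal(sum(t2[, sasa_cols[1]]), sum(t1[, sasa_cols[1]]),
               tolerance = 0.05)
})

test_that("RNA atoms are excluded from the environment", {
  fx <- shared_fixture()$fx
  prot_only <- structure_from_atoms(rnasurf:::protein_atoms(fx$structure))
  cen <- fx$centroids[1, ]
  t_complex <- featurize_point(c(cen$x, cen$y, cen$z), fx$structure)
  t_prot <- featurize_point(c(cen$x, cen$y, cen$z), prot_only)
  expect_equal(unname(t_complex), unname(t_prot))
})

test_that("grid featurization flattens shell-major to 480 columns", {
  fx <- shared_fixture()$fx
  g <- shared_fixture()$grid[1:3, ]
  m <- featurize_grid(g, fx$structure)
  expect_equal(dim(m), c(3, 480))
  expect_equal(attr(m, "registry_version"), default_registry()$version)
  t1 <- featurize_point(c(g$x[1], g$y[1], g$z[1]), fx$structure)
  expect_equal(unname(m[1, ]), unname(as.numeric(t(t1))))
})
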