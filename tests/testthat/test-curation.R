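# Labeling, negative sampling, class balancing, homology clustering,
# representative selection and fold construction.

test_that("points label by the nearest qualifying centroid", {
  grid <- tibble::tibble(x = c(0, 0, 0), y = c(0, 0, 0), z = c(2.9, 3.1, 1),
                         min_protein_dist = c(4, 4, 4),
                         nearest_chain = "A", nearest_resno = 1L)
  cen <- tibble::tibble(kind = "U", x = 0, y = 0, z = 0, chain = "B",
                        resno = 1L, residue_name = "U")
  lab <- label_positives(grid, cen)
  expect_equal(as.character(lab$label), c("U", NA, "U"))
  # too far from protein: never positive
  grid$min_protein_dist <- 6
  lab2 <- label_positives(grid, cen)
  expect_true(all(is.na(lab2$label)))
})

test_that("centroid conflicts resolve to the nearest, ties by P > R > base", {
  grid <- tibble::tibble(x = 0, y = 0, z = 0, min_protein_dist = 4,
                         nearest_chain = "A", nearest_resno = 1L)
  cen <- tibble::tibble(kind = c("P", "R"), x = c(0, 0), y = c(0, 0),
                        z = c(2.0, 1.5), chain = "B", resno = 1:2,
                        residue_name = "A")
  expect_equal(as.character(label_positives(grid, cen)$label), "R")
  # exact tie: P beats R
  cen$z <- c(2.0, 2.0)
  expect_equal(as.character(label_positives(grid, cen)$label), "P")
  # brute-force nearest agreement on the shared fixture
  sf <- shared_fixture()
  lab <- label_positives(sf$grid, sf$fx$centroids)
  pos <- which(!is.na(lab$label))
  set.seed(3)
  for (i in sample(pos, min(20, length(pos)))) {
    d <- sqrt((sf$fx$centroids$x - lab$x[i])^2 +
                (sf$fx$centroids$y - lab$y[i])^2 +
                (sf$fx$centroids$z - lab$z[i])^2)
    expect_equal(lab$centroid_dist[i], min(d), tolerance = 1e-9)
  }
})

test_that("labeled positives re-verify the 3 A centroid condition", {
  sf <- shared_fixture()
  lab <- label_positives(sf$grid, sf$fx$centroids)
  pos <- lab[!is.na(lab$label), ]
  expect_gt(nrow(pos), 0)
  expect_true(all(pos$centroid_dist <= 3))
  expect_true(all(pos$min_protein_dist <= 5))
})

test_that("negative sampling respects RNA exclusion and alpha spheres", {
  grid <- tibble::tibble(x = c(0, 10, 20), y = 0, z = 0,
                         min_protein_dist = 4,
                         nearest_chain = "A", nearest_resno = 1L)
  grid <- label_positives(grid, tibble::tibble(kind = character(),
                                               x = numeric(), y = numeric(),
                                               z = numeric(),
                                               chain = character(),
                                               resno = integer(),
                                               residue_name = character()))
  rna <- matrix(c(0, 0, 2), 1)  # 2 A from the first point
  spheres <- tibble::tibble(x = 10, y = 0, z = 0, radius = 1,
                            contact_atoms = list(1:4))
  out <- sample_negatives(grid, rna, spheres, n = 1, seed = 1)
  expect_equal(which(!is.na(out$label)), 3L)
  # n = 0 adds nothing; too-large n warns
  out0 <- sample_negatives(grid, rna, spheres, n = 0)
  expect_true(all(is.na(out0$label)))
  expect_warning(sample_negatives(grid, rna, spheres, n = 5, seed = 1),
                 "admissible")
})

test_that("balancing subsamples negatives to the 2:1 ratio", {
  grid <- tibble::tibble(x = seq_len(300), y = 0, z = 0,
                         min_protein_dist = 4, nearest_chain = "A",
                         nearest_resno = 1L,
                         label = factor(rep(c("A", "X", "X"), each = 100),
                                        levels = rnasurf:::CLASSES7))
  bal <- balance_classes(grid, 2, seed = 1)
  expect_equal(sum(bal$label == "A", na.rm = TRUE), 100)
  expect_equal(sum(bal$label == "X", na.rm = TRUE), 50)
  # already balanced: unchanged; deterministic under the seed
  expect_identical(balance_classes(bal, 2, seed = 1), bal)
  expect_identical(balance_classes(grid, 2, seed = 7),
                   balance_classes(grid, 2, seed = 7))
  grid$label[] <- "X"
  expect_error(balance_classes(grid, 2), "positive")
})

test_that("identity clustering is single linkage over global identity", {
  base <- paste(rep(c("ACDEFGHIKLMNPQRSTVWY"), 5), collapse = "")
  mutate_at <- function(s, pos, to = "A") {
    v <- strsplit(s, "")[[1]]; v[pos] <- to; paste(v, collapse = "")
  }
  a <- base
  b <- mutate_at(base, 1:5, "G")        # ~0.95 to a
  c_ <- mutate_at(b, 6:10, "W")         # ~0.95 to b, ~0.90 to a
  cl <- cluster_by_identity(c(A = a, B = b, C = c_), threshold = 0.93)
  expect_equal(cl$identity["A", "B"], 0.95)
  expect_equal(cl$identity["B", "C"], 0.95)
  expect_equal(cl$identity["A", "C"], 0.90)
  expect_equal(length(unique(cl$members$cluster)), 1)  # linked via B

  # identical pair: one cluster; all-dissimilar: singletons
  cl2 <- cluster_by_identity(c(X = a, Y = a), threshold = 0.9)
  expect_equal(length(unique(cl2$members$cluster)), 1)
  cl3 <- cluster_by_identity(c(A = a, C = c_), threshold = 0.93)
  expect_equal(length(unique(cl3$members$cluster)), 2)
  expect_equal(nrow(cluster_by_identity(character())$members), 0)
  expect_error(cluster_by_identity(c(A = a), threshold = 0), "threshold")
})

test_that("representatives minimize resolution with B-factor tie-breaks", {
  meta <- tibble::tibble(id = c("s1", "s2", "s3"),
                         resolution = c(2.5, 1.8, NA),
                         mean_protein_b = c(30, 40, 10))
  expect_equal(select_representative(c("s1", "s2", "s3"), meta), "s2")
  expect_equal(select_representative("s3", meta), "s3")
  meta$resolution <- c(2.0, 2.0, NA)
  expect_equal(select_representative(c("s1", "s2"), meta), "s1")
  expect_error(select_representative(character(), meta), "empty")
})

test_that("the best locally resolved RNA copy wins by mean B-factor", {
  at <- rnasurf:::place_nucleotide("A", c(0, 0, 0), diag(3))
  a1 <- atoms_tbl(rownames(at), at[, 1], at[, 2], at[, 3], "A",
                  chain = "B", b = 30)
  a2 <- atoms_tbl(rownames(at), at[, 1] + 20, at[, 2], at[, 3], "A",
                  chain = "C", b = 45)
  st <- structure_from_atoms(dplyr::bind_rows(a1, a2))
  expect_equal(best_rna_chain(st), "B")
})

test_that("folds keep clusters whole and balance sizes", {
  seqs <- setNames(
    vapply(1:6, function(i) paste(rep(LETTERS[i], 30), collapse = ""), ""),
    paste0("s", 1:6))
  cl <- cluster_by_identity(seqs, threshold = 0.9)
  folds <- make_folds(cl, k = 3, seed = 1)
  expect_equal(as.integer(sort(table(folds$fold))), c(2L, 2L, 2L))
  expect_identical(make_folds(cl, 3, seed = 5), make_folds(cl, 3, seed = 5))
  expect_error(make_folds(cl, k = 7), "exceeds")
  expect_error(make_folds(cl, k = 1), "k must be")

  # homologous pair always co-assigned
  seqs2 <- seqs
  seqs2["s2"] <- seqs2["s1"]
  cl2 <- cluster_by_identity(seqs2, threshold = 0.9)
  for (seed in 1:10) {
    f <- make_folds(cl2, k = 2, seed = seed)
    expect_equal(f$fold[f$id == "s1"], f$fold[f$id == "s2"])
  }
})
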