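# Hierarchical classifier: backbone architecture, head training, the
# multiplicative combination of the two levels, surface prediction and
# residue voting.

score_matrix_of <- function(scores) {
  as.matrix(scores[, paste0("prob_", rnasurf:::CLASSES7)])
}

test_that("the default residual backbone reports 32 convolutional layers", {
  m <- build_backbone(backbone_spec("resnet"))
  expect_equal(m$n_conv_layers, 32)
  expect_equal(m$spec$n_residual_blocks, 16)
  expect_equal(m$spec$filters, 80)
  expect_equal(m$spec$kernel, c(1L, 2L, 80L))
  expect_length(m$layers, 16)
  expect_error(build_backbone(backbone_spec("resnet", n_residual_blocks = 0)),
               "n_residual_blocks")
})

test_that("forward passes give finite normalized probabilities", {
  set.seed(1)
  cm <- class_means_orthogonal(classes = c("X", "P", "R", "B"), d = 480,
                               separation = 2)
  smp <- sample_feature_vectors(10, cm, sd = 1, seed = 1)
  for (kind in c("baseline", "resnet")) {
    spec <- backbone_spec(kind, epochs = 3, seed = 2,
                          n_residual_blocks = if (kind == "resnet") 4 else 16)
    lev <- train_level(build_backbone(spec), smp$features, smp$labels)
    p <- predict(lev, smp$features)
    expect_true(all(is.finite(p)))
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-8)
    # zero-input tensor: finite, normalized, identical across such points
    pz <- predict(lev, matrix(0, 2, 480))
    expect_true(all(is.finite(pz)))
    expect_equal(pz[1, ], pz[2, ])
  }
})

test_that("training recovers well-separated Gaussian classes", {
  cm <- class_means_orthogonal(classes = c("X", "P", "R", "B"), d = 480,
                               separation = 2)
  train <- sample_feature_vectors(100, cm, sd = 0.1, seed = 3)
  test <- sample_feature_vectors(60, cm, sd = 0.1, seed = 4)
  spec <- backbone_spec("baseline", epochs = 80, learning_rate = 1e-2,
                        weight_decay = 1e-2, seed = 5)
  lev <- train_level(build_backbone(spec), train$features, train$labels)
  pred <- colnames(predict(lev, test$features))[
    max.col(predict(lev, test$features), ties.method = "first")]
  expect_gte(mean(pred == as.character(test$labels)), 0.95)
  # loss decreases from initialization
  expect_lt(lev$loss_trace[length(lev$loss_trace)], lev$loss_trace[1])
  # deterministic under the seed
  lev2 <- train_level(build_backbone(spec), train$features, train$labels)
  expect_equal(lev$w, lev2$w)
})

test_that("shuffled labels give chance-level held-out accuracy", {
  cm <- class_means_orthogonal(classes = c("X", "P", "R", "B"), d = 480,
                               separation = 2)
  train <- sample_feature_vectors(80, cm, sd = 0.1, seed = 6)
  test <- sample_feature_vectors(80, cm, sd = 0.1, seed = 7)
  shuffled <- with(train, labels[withr::with_seed(8, sample(length(labels)))])
  spec <- backbone_spec("baseline", epochs = 30, seed = 9)
  lev <- train_level(build_backbone(spec), train$features, shuffled)
  p <- predict(lev, test$features)
  acc <- mean(colnames(p)[max.col(p, ties.method = "first")] ==
                as.character(test$labels))
  # a model fit to permuted labels is not a uniform guesser (its class
  # proportions are skewed), so allow a band around the 1/4 chance rate,
  # far below the >= 0.95 achieved with true labels
  expect_gt(acc, 0.10)
  expect_lt(acc, 0.40)
})

test_that("single-class training is rejected", {
  spec <- backbone_spec("baseline", epochs = 2)
  feats <- matrix(rnorm(10 * 480), 10)
  expect_error(train_level(build_backbone(spec), feats, rep("X", 10)),
               "two classes")
})

test_that("combine_hierarchy multiplies the base prior through level 2", {
  out <- combine_hierarchy(c(X = .4, P = .3, R = .2, B = .1),
                           c(A = .5, G = .2, C = .2, U = .1))
  expect_equal(as.numeric(out),
               c(.4, .3, .2, .05, .02, .02, .01))
  expect_equal(sum(as.numeric(out)), 1)
  # degenerate priors
  z <- combine_hierarchy(c(.5, .3, .2, 0), c(.25, .25, .25, .25))
  expect_equal(as.numeric(z[, c("prob_A", "prob_G", "prob_C", "prob_U")]),
               rep(0, 4))
  one <- combine_hierarchy(c(0, 0, 0, 1), c(1, 0, 0, 0))
  expect_equal(one$prob_A, 1)
  expect_error(combine_hierarchy(c(.5, .5, .5, .5), c(.25, .25, .25, .25)),
               "normalized")
})

test_that("combined output sums to 1 on random simplex inputs", {
  set.seed(10)
  for (i in 1:50) {
    l1 <- as.numeric(rnasurf:::row_normalize(matrix(runif(4), 1)))
    l2 <- as.numeric(rnasurf:::row_normalize(matrix(runif(4), 1)))
    out <- combine_hierarchy(l1, l2)
    expect_equal(sum(as.numeric(out)), 1, tolerance = 1e-12)
    # class-merge consistency: base masses sum back to the level-1 prior
    expect_equal(sum(as.numeric(out[, paste0("prob_",
                                             c("A", "G", "C", "U"))])),
                 l1[4], tolerance = 1e-12)
  }
})

test_that("hierarchical accuracy approaches the Bayes rate with growing n", {
  cm <- class_means_orthogonal(separation = 6)
  sd <- 0.5
  test <- sample_feature_vectors(100, cm, sd = sd, seed = 20)
  accs <- vapply(c(30, 150), function(n) {
    tr <- sample_feature_vectors(n, cm, sd = sd, seed = 21)
    hm <- train_hierarchical(tr$features, tr$labels,
                             backbone_spec("baseline", epochs = 120,
                                           learning_rate = 1e-2,
                                           weight_decay = 1e-2, seed = 22))
    p <- score_matrix_of(predict_hierarchical(hm, test$features))
    mean(rnasurf:::CLASSES7[max.col(p, ties.method = "first")] ==
           as.character(test$labels))
  }, numeric(1))
  bayes <- bayes_rate_gaussian(cm, sd, n_mc = 1000, seed = 23)
  expect_gte(accs[2], accs[1] - 0.02)      # non-decreasing (within noise)
  expect_gte(accs[2], bayes - 0.05)
})

test_that("surface prediction is pure and checks the registry version", {
  sf <- shared_fixture()
  grid <- sf$grid[1:12, ]
  lab <- label_positives(sf$grid, sf$fx$centroids)
  lab$label[is.na(lab$label)] <- "X"
  idx <- c(which(lab$label != "X"), which(lab$label == "X")[1:80])
  feats <- featurize_grid(lab[idx, ], sf$fx$structure)
  hm <- train_hierarchical(feats, lab$label[idx],
                           backbone_spec("baseline", epochs = 10, seed = 1))
  s1 <- predict_surface(hm, sf$fx$structure, grid)
  s2 <- predict_surface(hm, sf$fx$structure, grid)
  expect_identical(s1, s2)
  expect_equal(rowSums(score_matrix_of(s1)), rep(1, nrow(grid)),
               tolerance = 1e-8)
  hm_bad <- hm; hm_bad$registry_version <- "other-registry"
  expect_error(predict_surface(hm_bad, sf$fx$structure, grid),
               "registry mismatch")
})

test_that("residue voting takes the 30 nearest points with a conservative tie", {
  st <- structure_from_atoms(atoms_tbl("CA", 0, 0, 0, "ALA"))
  grid <- tibble::tibble(x = seq_len(40) * 0.1, y = 0, z = 0)
  res <- list(chain = "A", resno = 1L)
  sc_x <- uniform_scores(40); sc_x$prob_X <- 0.9
  expect_equal(residue_vote(sc_x, grid, res, st), "non-site")
  # 20 site-leaning vs 10 non-site among the 30 nearest
  sc <- uniform_scores(40)
  sc$prob_X <- c(rep(0.1, 20), rep(0.9, 20))
  expect_equal(residue_vote(sc, grid, res, st), "site")
  # exactly 15/15: non-site
  sc2 <- uniform_scores(40)
  sc2$prob_X <- c(rep(0.1, 15), rep(0.9, 25))
  expect_equal(residue_vote(sc2, grid, res, st), "non-site")
  # fewer than 30 points: all vote
  expect_equal(residue_vote(sc_x[1:5, ], grid[1:5, ], res, st), "non-site")
})
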