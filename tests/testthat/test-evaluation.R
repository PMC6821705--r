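# Metrics and the homology-guarded cross-validation harness.

test_that("MCC reproduces the closed-form and its conventions", {
  expect_equal(mcc(c(tp = 5, tn = 5, fp = 0, fn = 0)), 1.0)
  # all predictions in one class: zero by the denominator convention
  expect_equal(mcc(c(tp = 5, tn = 0, fp = 5, fn = 0)), 0.0)
  tp <- 4; tn <- 3; fp <- 1; fn <- 2
  byhand <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(mcc(c(tp = tp, tn = tn, fp = fp, fn = fn)), byhand)
  # matrix form and class-swap symmetry (MCC is invariant under swapping
  # positive/negative labels in both truth and prediction)
  m <- matrix(c(tn, fp, fn, tp), 2, byrow = TRUE)
  expect_equal(mcc(m), byhand)
  swapped <- matrix(c(tp, fn, fp, tn), 2, byrow = TRUE)
  expect_equal(mcc(swapped), byhand)
  expect_error(mcc(diag(3)), "2x2")
})

test_that("AUROC separates, stays at chance, and matches trapezoids", {
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  set.seed(1)
  sc <- rnorm(1e4); lb <- rbinom(1e4, 1, 0.5)
  expect_lt(abs(auroc(sc, lb) - 0.5), 0.02)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  # trapezoidal ROC integration oracle on random instances
  trapezoid_auc <- function(scores, labels) {
    th <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), 0)
    fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), 0)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  for (i in 1:20) {
    set.seed(100 + i)
    n <- 40
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    sc <- rnorm(n) + lb * runif(1, 0, 2)
    sc <- round(sc, 1)               # induce ties
    expect_equal(auroc(sc, lb), trapezoid_auc(sc, lb), tolerance = 1e-10)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  sc <- rnorm(200); lb <- rbinom(200, 1, 0.4)
  expect_equal(auroc(sc, lb),
               as.numeric(suppressMessages(pROC::auc(lb, sc))),
               tolerance = 1e-10)
})

test_that("the multiclass report reproduces hand-worked arithmetic", {
  d <- diag(c(3L, 4L, 5L)); dimnames(d) <- list(letters[1:3], letters[1:3])
  rep_d <- multiclass_report(d)
  expect_true(all(rep_d$summary[1, ] == 1))
  # hand-worked 3-class table
  ct <- matrix(c(5, 2, 0,
                 1, 6, 1,
                 0, 3, 4), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  r <- multiclass_report(ct)
  expect_equal(r$summary$accuracy, 15 / 22)
  expect_equal(r$per_class$recall, c(5 / 7, 6 / 8, 4 / 7))
  expect_equal(r$per_class$precision, c(5 / 6, 6 / 11, 4 / 5))
  f1 <- 2 * r$per_class$precision * r$per_class$recall /
    (r$per_class$precision + r$per_class$recall)
  expect_equal(r$per_class$f1, f1)
  expect_equal(r$summary$f1_macro, mean(f1))
  # micro-F1 equals accuracy for single-label multiclass
  expect_equal(r$summary$f1_micro, r$summary$accuracy)
  expect_error(multiclass_report(matrix(0, 2, 2)), "counts")
})

test_that("uniform random predictions score near 1/7 accuracy", {
  set.seed(3)
  truth <- sample(rnasurf:::CLASSES7, 7000, replace = TRUE)
  pred <- sample(rnasurf:::CLASSES7, 7000, replace = TRUE)
  ct <- confusion_table(truth, pred, rnasurf:::CLASSES7)
  acc <- multiclass_report(ct)$summary$accuracy
  expect_lt(abs(acc - 1 / 7), 0.02)
})

test_that("per-class AUROC handles absent classes", {
  sc <- uniform_scores(10)
  sc$prob_A <- seq(0, 1, length.out = 10)
  labels <- c(rep("X", 5), rep("A", 5))
  pa <- per_class_auroc(sc, labels)
  expect_equal(pa$auroc[pa$class == "A"], 1.0)
  expect_true(is.na(pa$auroc[pa$class == "G"]))
})

# Small synthetic cross-validation dataset: three unrelated "structures",
# each contributing Gaussian feature vectors in all seven classes.
cv_dataset <- function() {
  cm <- class_means_orthogonal(separation = 6)
  parts <- lapply(1:3, function(i) {
    smp <- sample_feature_vectors(20, cm, sd = 0.3, seed = 30 + i)
    tibble::tibble(structure_id = paste0("s", i),
                   label = as.character(smp$labels),
                   features = smp$features)
  })
  dplyr::bind_rows(parts)
}

cv_sequences <- function() {
  setNames(vapply(c("A", "W", "M"), function(ch)
    paste(rep(ch, 40), collapse = ""), ""), paste0("s", 1:3))
}

test_that("cross-validation trains on k-1 folds and aggregates confusions", {
  ds <- cv_dataset()
  folds <- tibble::tibble(id = paste0("s", 1:3), cluster = 1:3, fold = 1:3)
  res <- crossvalidate(ds, folds,
                       backbone_spec("baseline", epochs = 120,
                                     learning_rate = 1e-2,
                                     weight_decay = 1e-2, seed = 1),
                       sequences = cv_sequences())
  expect_equal(nrow(res$per_fold), 3)
  expect_equal(sort(unique(res$per_structure$structure_id)),
               paste0("s", 1:3))
  # every structure is evaluated exactly once, never in its own training set
  expect_equal(res$per_structure$fold,
               folds$fold[match(res$per_structure$structure_id, folds$id)])
  # aggregate confusion counts all held-out points once
  expect_equal(sum(res$confusion), nrow(ds))
  expect_gt(res$report$summary$accuracy, 0.8)
})

test_that("a planted homologous pair across folds aborts cross-validation", {
  ds <- cv_dataset()
  folds <- tibble::tibble(id = paste0("s", 1:3), cluster = 1:3, fold = 1:3)
  seqs <- cv_sequences()
  seqs["s2"] <- seqs["s1"]           # identical chains in different folds
  expect_error(
    crossvalidate(ds, folds, backbone_spec("baseline", epochs = 5),
                  sequences = seqs),
    "homology leakage.*s1.*s2")
})

test_that("report export is one metric per line", {
  ct <- matrix(c(5, 1, 2, 6), 2, dimnames = list(c("X", "A"), c("X", "A")))
  tmp <- withr::local_tempfile()
  write_report(multiclass_report(ct), tmp)
  lines <- readLines(tmp)
  expect_equal(strsplit(lines[1], "\t")[[1]], c("metric", "class", "value"))
  expect_gt(length(lines), 8)
})
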