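## Evaluation metrics (MCC, rank-based AUROC, macro/micro classification
## report) and the homology-guarded cross-validation harness.

#' Matthews correlation coefficient of a 2x2 confusion table
#'
#' Rows are true classes, columns predicted (negative, positive order or a
#' named `c(tp=, tn=, fp=, fn=)` vector). A zero denominator (e.g. all
#' predictions in one class) returns 0 by convention.
#'
#' @param x A 2x2 integer matrix/table, or a named vector with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(x) {
  if (is.numeric(x) && !is.null(names(x)) &&
      all(c("tp", "tn", "fp", "fn") %in% names(x))) {
    tp <- x[["tp"]]; tn <- x[["tn"]]; fp <- x[["fp"]]; fn <- x[["fn"]]
  } else {
    x <- as.matrix(x)
    if (!all(dim(x) == c(2, 2))) abort("mcc needs a 2x2 confusion table")
    tn <- x[1, 1]; fp <- x[1, 2]; fn <- x[2, 1]; tp <- x[2, 2]
  }
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (denom == 0) return(0)
  unname((tp * tn - fp * fn) / denom)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random positive outscores a random negative, counting ties as one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (logical, 0/1, or a 2-level factor whose
#'   second level is positive).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to compute AUROC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion table from true and predicted labels
#'
#' @param truth,predicted Vectors coercible to factors over the same
#'   classes.
#' @param classes Class levels (default: union of observed).
#' @return Integer matrix, rows = true classes, columns = predicted.
#' @export
confusion_table <- function(truth, predicted, classes = NULL) {
  classes <- classes %||% sort(union(unique(as.character(truth)),
                                     unique(as.character(predicted))))
  tab <- table(factor(truth, classes), factor(predicted, classes))
  matrix(as.integer(tab), nrow(tab), dimnames = dimnames(tab))
}

#' Macro/micro classification report from a confusion table
#'
#' Macro metrics are unweighted means over classes; micro metrics pool
#' counts over classes (for single-label multiclass, micro F1 equals
#' categorical accuracy). Per-class precision/recall with empty
#' denominators count as 0.
#'
#' @param ct Confusion matrix (rows = truth, columns = predicted) with at
#'   least two classes.
#' @return List with `per_class` (tibble: class, support, precision,
#'   recall, f1) and `summary` (tibble: accuracy, macro/micro precision,
#'   recall, f1).
#' @export
multiclass_report <- function(ct) {
  ct <- as.matrix(ct)
  if (nrow(ct) < 2 || nrow(ct) != ncol(ct) || sum(ct) == 0) {
    abort("need a square confusion table with >= 2 classes and counts")
  }
  tp <- unname(diag(ct))
  support <- unname(rowSums(ct))
  pred_n <- unname(colSums(ct))
  prec <- ifelse(pred_n > 0, tp / pred_n, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  micro_tp <- sum(tp)
  micro_prec <- micro_tp / sum(pred_n)
  micro_rec <- micro_tp / sum(support)
  list(
    per_class = tibble::tibble(class = rownames(ct), support = support,
                               precision = prec, recall = rec, f1 = f1),
    summary = tibble::tibble(
      accuracy = sum(tp) / sum(ct),
      precision_macro = mean(prec), recall_macro = mean(rec),
      f1_macro = mean(f1),
      precision_micro = micro_prec, recall_micro = micro_rec,
      f1_micro = ifelse(micro_prec + micro_rec > 0,
                        2 * micro_prec * micro_rec /
                          (micro_prec + micro_rec), 0)))
}

#' Per-class one-vs-rest AUROC from 7-class score vectors
#'
#' @param scores Tibble with `prob_*` columns.
#' @param labels True class labels over X/P/R/A/G/C/U.
#' @return Tibble: class, auroc (NA when a class is absent).
#' @export
per_class_auroc <- function(scores, labels) {
  labels <- as.character(labels)
  out <- lapply(CLASSES7, function(cl) {
    y <- labels == cl
    a <- if (sum(y) == 0 || sum(!y) == 0) NA_real_ else
      auroc(scores[[paste0("prob_", cl)]], y)
    tibble::tibble(class = cl, auroc = a)
  })
  dplyr::bind_rows(out)
}

#' Homology-guarded cross-validation of the hierarchical classifier
#'
#' Trains on k-1 folds and evaluates on the held-out fold, once per fold.
#' Before any training the harness recomputes all cross-fold pairwise
#' identities and aborts, naming the offending pair, when two structures in
#' different folds share sequence identity at or above the threshold
#' (leakage). The cross-validation granularity is whole structures
#' (proteins), never individual points.
#'
#' @param dataset Tibble with columns `structure_id`, `label`, and a
#'   `features` matrix-column (or list column of numeric vectors).
#' @param folds Fold assignment tibble from [make_folds()] (`id`, `fold`).
#' @param spec A [backbone_spec()].
#' @param sequences Named character vector of chain sequences per structure
#'   id (for the leakage check).
#' @param identity_threshold Homology threshold (default 0.9).
#' @return List with `per_fold` (tibble: fold, n_test, accuracy),
#'   `per_structure` (tibble: structure_id, fold, n, accuracy),
#'   `confusion` (aggregate table over held-out predictions) and `report`
#'   (from [multiclass_report()]).
#' @export
crossvalidate <- function(dataset, folds, spec = backbone_spec(),
                          sequences = NULL, identity_threshold = 0.9) {
  fold_of <- setNames(folds$fold, folds$id)
  if (!all(dataset$structure_id %in% names(fold_of))) {
    abort("every structure in the dataset needs a fold assignment")
  }
  if (!is.null(sequences)) {
    ids <- intersect(names(sequences), names(fold_of))
    if (length(ids) > 1) {
      for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
        if (fold_of[[ids[i]]] == fold_of[[ids[j]]]) next
        ident <- pairwise_identity(sequences[[ids[i]]], sequences[[ids[j]]])
        if (ident >= identity_threshold) {
          abort(sprintf(
            "homology leakage across folds: %s (fold %d) vs %s (fold %d), identity %.2f",
            ids[i], fold_of[[ids[i]]], ids[j], fold_of[[ids[j]]], ident))
        }
      }
    }
  }
  feats <- if (is.list(dataset$features) && !is.matrix(dataset$features)) {
    do.call(rbind, dataset$features)
  } else as.matrix(dataset$features)
  labels <- as.character(dataset$label)
  fold_vec <- fold_of[dataset$structure_id]
  per_fold <- list(); per_struct <- list()
  truth_all <- character(0); pred_all <- character(0)
  for (f in sort(unique(folds$fold))) {
    test <- fold_vec == f
    if (!any(test) || !any(!test)) next
    model <- train_hierarchical(feats[!test, , drop = FALSE], labels[!test],
                                spec)
    probs <- predict_hierarchical(model, feats[test, , drop = FALSE])
    pred <- CLASSES7[max.col(score_matrix(probs), ties.method = "first")]
    truth <- labels[test]
    truth_all <- c(truth_all, truth); pred_all <- c(pred_all, pred)
    per_fold[[as.character(f)]] <- tibble::tibble(
      fold = f, n_test = sum(test), accuracy = mean(pred == truth))
    sid <- dataset$structure_id[test]
    per_struct[[as.character(f)]] <- tibble::tibble(
      structure_id = sid, fold = f, correct = pred == truth) |>
      dplyr::group_by(.data$structure_id, .data$fold) |>
      dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$correct),
                       .groups = "drop")
  }
  classes_seen <- sort(unique(c(truth_all, pred_all)))
  ct <- confusion_table(truth_all, pred_all, classes_seen)
  list(per_fold = dplyr::bind_rows(per_fold),
       per_structure = dplyr::bind_rows(per_struct),
       confusion = ct,
       report = multiclass_report(ct))
}

#' Write a metric report as machine-readable delimited text
#'
#' One metric per line: name, class (or "all"), value.
#'
#' @param report Output of [multiclass_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  lines <- dplyr::bind_rows(
    tidyr::pivot_longer(report$summary, dplyr::everything(),
                        names_to = "metric") |>
      dplyr::mutate(class = "all"),
    tidyr::pivot_longer(report$per_class, c("precision", "recall", "f1"),
                        names_to = "metric") |>
      dplyr::select("metric", "value", "class"))
  utils::write.table(lines[, c("metric", "class", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
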