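## Two-level hierarchical classifier over the 6 x 80 environment tensors:
## level 1 resolves {X, P, R, Base}, level 2 resolves {A, G, C, U}, and the
## 7-class score vector is the product of the level-2 output with the Base
## prior. Two interchangeable backbones: a residual network (16 blocks of
## two 1x2x80 convolutions with batch normalization, ReLU and identity
## shortcuts; 32 convolutional layers in total) and a multinomial baseline on
## the flattened 480-vector. Desk-scale training optimizes the softmax head
## with Adam under categorical cross-entropy and weight decay; for the
## residual backbone the convolutional stack acts as a fixed, seed-determined
## feature extractor.

#' Specify a classifier backbone
#'
#' @param kind `"baseline"` (multinomial softmax regression on the flattened
#'   480-vector) or `"resnet"` (residual network feature extractor with a
#'   trained softmax head).
#' @param n_residual_blocks Residual blocks (default 16; each block holds two
#'   convolutional layers, so the default stack has 32).
#' @param filters Convolution filters (default 80, preserving the 6 x 80
#'   shape together with zero padding).
#' @param learning_rate,batch_size,weight_decay,epochs Adam training
#'   hyperparameters for the softmax head (categorical cross-entropy loss).
#' @param seed Integer seed fixing weight initialization and batch order.
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(kind = c("baseline", "resnet"),
                          n_residual_blocks = 16L, filters = 80L,
                          learning_rate = 1e-3, batch_size = 256L,
                          weight_decay = 1e-4, epochs = 30L, seed = 1L) {
  kind <- match.arg(kind)
  if (n_residual_blocks < 1) abort("n_residual_blocks must be >= 1")
  structure(list(kind = kind,
                 n_residual_blocks = as.integer(n_residual_blocks),
                 filters = as.integer(filters),
                 kernel = c(1L, 2L, 80L),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "backbone_spec")
}

#' Instantiate a classifier backbone
#'
#' Builds the residual-network variant (per block: convolution -> batch norm
#' -> ReLU -> convolution -> batch norm, plus the identity shortcut and a
#' final ReLU; zero padding preserves the 6 x 80 spatial shape; a fully
#' connected layer with softmax follows the flattened output) or the
#' baseline variant. Weight initialization is deterministic under the spec
#' seed.
#'
#' @param spec A [backbone_spec()].
#' @param n_classes Output classes (4 at each hierarchy level).
#' @param n_shells,n_properties Input tensor shape (defaults 6 x 80).
#' @return An `rs_backbone` with element `n_conv_layers` reporting the
#'   convolutional layer count (2 per residual block; 0 for the baseline).
#' @export
build_backbone <- function(spec, n_classes = 4L, n_shells = 6L,
                           n_properties = 80L) {
  stopifnot(inherits(spec, "backbone_spec"))
  layers <- NULL
  if (spec$kind == "resnet") {
    layers <- with_seed(spec$seed, {
      lapply(seq_len(spec$n_residual_blocks), function(b) {
        init_conv <- function() {
          ## He-normal init for a 1 x 2 x n_properties kernel per filter
          sd <- sqrt(2 / (2 * n_properties))
          list(w1 = matrix(rnorm(spec$filters * n_properties, 0, sd),
                           spec$filters),
               w2 = matrix(rnorm(spec$filters * n_properties, 0, sd),
                           spec$filters),
               bn_gamma = rep(1, spec$filters),
               bn_beta = rep(0, spec$filters),
               bn_mean = rep(0, spec$filters),
               bn_var = rep(1, spec$filters))
        }
        list(conv1 = init_conv(), conv2 = init_conv())
      })
    })
  }
  structure(list(spec = spec, n_classes = as.integer(n_classes),
                 n_shells = as.integer(n_shells),
                 n_properties = as.integer(n_properties),
                 layers = layers,
                 n_conv_layers = if (spec$kind == "resnet")
                   2L * spec$n_residual_blocks else 0L),
            class = "rs_backbone")
}

#' @export
print.rs_backbone <- function(x, ...) {
  cat("<rs_backbone> ", x$spec$kind,
      if (x$spec$kind == "resnet")
        sprintf(": %d residual blocks, %d convolutional layers, %d filters",
                x$spec$n_residual_blocks, x$n_conv_layers, x$spec$filters)
      else ": multinomial softmax on flattened input",
      "\n", sep = "")
  invisible(x)
}

## One convolution with kernel 1 x 2 x C and zero padding at the far end,
## vectorized over samples: `a` has dim (n, n_shells, C).
conv_1x2 <- function(a, w1, w2) {
  n <- dim(a)[1]; s <- dim(a)[2]
  pad <- array(0, dim = c(n, s + 1, dim(a)[3]))
  pad[, 1:s, ] <- a
  m1 <- pad[, 1:s, , drop = FALSE];  dim(m1) <- c(n * s, dim(a)[3])
  m2 <- pad[, 2:(s + 1), , drop = FALSE]; dim(m2) <- c(n * s, dim(a)[3])
  out <- m1 %*% t(w1) + m2 %*% t(w2)
  dim(out) <- c(n, s, nrow(w1))
  out
}

batch_norm_inference <- function(a, layer) {
  n <- dim(a)[1]; s <- dim(a)[2]; f <- dim(a)[3]
  scale <- layer$bn_gamma / sqrt(layer$bn_var + 1e-5)
  shift <- layer$bn_beta - layer$bn_mean * scale
  sweep(sweep(a, 3, scale, "*"), 3, shift, "+")
}

## Forward pass through the residual stack; input and output are
## (n, n_shells * n_properties) shell-major matrices.
backbone_features <- function(model, x) {
  x <- as.matrix(x)
  if (model$spec$kind == "baseline") return(x)
  n <- nrow(x)
  a <- array(0, dim = c(n, model$n_shells, model$n_properties))
  for (s in seq_len(model$n_shells)) {
    a[, s, ] <- x[, (s - 1) * model$n_properties + seq_len(model$n_properties),
                  drop = FALSE]
  }
  for (block in model$layers) {
    inp <- a
    a <- conv_1x2(a, block$conv1$w1, block$conv1$w2)
    a <- batch_norm_inference(a, block$conv1)
    a[a < 0] <- 0
    a <- conv_1x2(a, block$conv2$w1, block$conv2$w2)
    a <- batch_norm_inference(a, block$conv2)
    a <- a + inp                      # identity shortcut
    a[a < 0] <- 0
  }
  out <- matrix(0, n, model$n_shells * model$n_properties)
  for (s in seq_len(model$n_shells)) {
    out[, (s - 1) * model$n_properties + seq_len(model$n_properties)] <-
      a[, s, ]
  }
  out
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Adam optimizer for multinomial softmax regression with weight decay and
## categorical cross-entropy; returns parameters and the per-epoch loss trace.
adam_softmax_train <- function(x, y_onehot, lr, batch_size, weight_decay,
                               epochs, seed) {
  n <- nrow(x); d <- ncol(x); k <- ncol(y_onehot)
  w <- matrix(0, d, k); b <- numeric(k)
  mw <- matrix(0, d, k); vw <- matrix(0, d, k)
  mb <- numeric(k); vb <- numeric(k)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0
  trace <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y_onehot[idx, , drop = FALSE]
        p <- softmax_rows(xb %*% w + matrix(b, length(idx), k, byrow = TRUE))
        gz <- (p - yb) / length(idx)
        gw <- crossprod(xb, gz) + weight_decay * w
        gb <- colSums(gz)
        t <- t + 1
        mw <- beta1 * mw + (1 - beta1) * gw
        vw <- beta2 * vw + (1 - beta2) * gw^2
        mb <- beta1 * mb + (1 - beta1) * gb
        vb <- beta2 * vb + (1 - beta2) * gb^2
        w <- w - lr * (mw / (1 - beta1^t)) / (sqrt(vw / (1 - beta2^t)) + eps)
        b <- b - lr * (mb / (1 - beta1^t)) / (sqrt(vb / (1 - beta2^t)) + eps)
      }
      p <- softmax_rows(x %*% w + matrix(b, n, k, byrow = TRUE))
      trace[ep] <- -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))
    }
  })
  list(w = w, b = b, loss_trace = trace)
}

#' Train one hierarchy level
#'
#' Trains the classifier head of a backbone on labeled feature vectors with
#' Adam under categorical cross-entropy and weight decay. For the residual
#' backbone the convolutional stack is applied as a fixed (seed-determined)
#' feature extractor and the fully connected softmax head is optimized; the
#' baseline optimizes the softmax regression directly on the flattened
#' input. Deterministic under the spec seed.
#'
#' @param model An `rs_backbone` from [build_backbone()].
#' @param features Numeric matrix, one row per example (shell-major
#'   flattened tensors).
#' @param labels Factor (or character) labels; at least two classes must be
#'   present.
#' @param registry_version Version string of the registry that produced the
#'   features (recorded in the trained model).
#' @return An `rs_trained_level` with the fitted head, the class levels, and
#'   `loss_trace` (per-epoch training loss).
#' @export
train_level <- function(model, features, labels,
                        registry_version = "rnasurf-80-v1") {
  stopifnot(inherits(model, "rs_backbone"))
  features <- as.matrix(features)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) abort("need at least two classes to train")
  if (nrow(features) != length(labels)) {
    abort("features and labels must have matching lengths")
  }
  spec <- model$spec
  feat <- backbone_features(model, features)
  ## center the features and rescale by one global factor: per-column
  ## standardization would amplify uninformative low-variance columns
  mu <- colMeans(feat)
  sdv <- rep(max(mean(apply(feat, 2, stats::sd)), 1e-8), ncol(feat))
  xs <- sweep(sweep(feat, 2, mu), 2, sdv, "/")
  y_onehot <- outer(labels, levels(labels), "==") * 1
  fit <- adam_softmax_train(xs, y_onehot, spec$learning_rate,
                            spec$batch_size, spec$weight_decay,
                            spec$epochs, spec$seed)
  structure(list(backbone = model, classes = levels(labels),
                 w = fit$w, b = fit$b, center = mu, scale = sdv,
                 loss_trace = fit$loss_trace,
                 registry_version = registry_version),
            class = "rs_trained_level")
}

#' @export
print.rs_trained_level <- function(x, ...) {
  cat("<rs_trained_level> ", x$backbone$spec$kind, " backbone, classes: ",
      paste(x$classes, collapse = "/"),
      sprintf(", final loss %.4f", x$loss_trace[length(x$loss_trace)]),
      "\n", sep = "")
  invisible(x)
}

#' @export
predict.rs_trained_level <- function(object, newdata, ...) {
  feat <- backbone_features(object$backbone, as.matrix(newdata))
  xs <- sweep(sweep(feat, 2, object$center), 2, object$scale, "/")
  p <- softmax_rows(xs %*% object$w +
                      matrix(object$b, nrow(xs), length(object$b),
                             byrow = TRUE))
  colnames(p) <- object$classes
  p
}

#' Combine the two hierarchy levels into a 7-class score vector
#'
#' Carries the X/P/R probabilities from level 1 and distributes the Base
#' prior over the four bases proportionally to the level-2 output:
#' `p(b) = p1(Base) * p2(b)`. Given normalized inputs the output sums to 1
#' exactly.
#'
#' @param level1_out Normalized 4-vector (or n x 4 matrix) over
#'   X, P, R, B.
#' @param level2_out Normalized 4-vector (or n x 4 matrix) over A, G, C, U.
#' @param tol Normalization tolerance beyond which inputs are rejected.
#' @return Tibble with columns `prob_X`, `prob_P`, `prob_R`, `prob_A`,
#'   `prob_G`, `prob_C`, `prob_U`.
#' @export
combine_hierarchy <- function(level1_out, level2_out, tol = 1e-6) {
  l1 <- if (is.null(dim(level1_out))) matrix(level1_out, 1) else
    as.matrix(level1_out)
  l2 <- if (is.null(dim(level2_out))) matrix(level2_out, 1) else
    as.matrix(level2_out)
  if (ncol(l1) != 4 || ncol(l2) != 4 || nrow(l1) != nrow(l2)) {
    abort("level outputs must be 4-class vectors of matching length")
  }
  if (any(abs(rowSums(l1) - 1) > tol) || any(abs(rowSums(l2) - 1) > tol) ||
      any(l1 < -tol) || any(l2 < -tol)) {
    abort("level outputs must be normalized probability vectors")
  }
  if (is.null(colnames(l1))) colnames(l1) <- CLASSES4_COARSE
  if (is.null(colnames(l2))) colnames(l2) <- BASES
  out <- cbind(l1[, c("X", "P", "R"), drop = FALSE],
               l2[, BASES, drop = FALSE] * l1[, "B"])
  colnames(out) <- prob_cols()
  tibble::as_tibble(out)
}

#' Train the full hierarchical model
#'
#' Level 1 is trained on all points with A/G/C/U merged into Base; level 2 is
#' trained on the base-labeled points only.
#'
#' @param features Numeric matrix of flattened tensors.
#' @param labels Factor/character labels over X/P/R/A/G/C/U.
#' @param spec A [backbone_spec()] shared by both levels.
#' @param registry_version Registry version recorded in the model.
#' @return An `rs_hierarchical` with elements `level1` and `level2`.
#' @export
train_hierarchical <- function(features, labels, spec = backbone_spec(),
                               registry_version = "rnasurf-80-v1") {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASSES7)
  if (length(bad)) abort(paste0("unknown labels: ", paste(bad, collapse = ", ")))
  coarse <- ifelse(labels %in% BASES, "B", labels)
  coarse <- factor(coarse, levels = CLASSES4_COARSE)
  m1 <- build_backbone(spec, n_classes = 4L)
  level1 <- train_level(m1, features, coarse, registry_version)
  is_base <- labels %in% BASES
  if (sum(is_base) == 0) abort("no base-labeled points for level 2")
  m2 <- build_backbone(spec, n_classes = 4L)
  level2 <- train_level(m2, as.matrix(features)[is_base, , drop = FALSE],
                        factor(labels[is_base], levels = BASES),
                        registry_version)
  structure(list(level1 = level1, level2 = level2,
                 registry_version = registry_version, spec = spec),
            class = "rs_hierarchical")
}

#' @export
print.rs_hierarchical <- function(x, ...) {
  cat("<rs_hierarchical> two-level classifier (", x$spec$kind,
      " backbone), registry ", x$registry_version, "\n", sep = "")
  invisible(x)
}

## Pad a level's probability matrix with zero columns for absent classes so
## the hierarchy can always be combined on the canonical class sets.
pad_classes <- function(p, classes) {
  out <- matrix(0, nrow(p), length(classes), dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  out
}

#' Predict 7-class score vectors for feature vectors
#'
#' @param model An `rs_hierarchical`.
#' @param features Numeric matrix of flattened tensors.
#' @return Tibble of `prob_*` columns, one row per input row; each row sums
#'   to 1.
#' @export
predict_hierarchical <- function(model, features) {
  stopifnot(inherits(model, "rs_hierarchical"))
  features <- as.matrix(features)
  p1 <- pad_classes(predict(model$level1, features), CLASSES4_COARSE)
  p2 <- pad_classes(predict(model$level2, features), BASES)
  ## guard against all-zero level-2 rows when classes were absent in training
  z <- rowSums(p2) == 0
  if (any(z)) p2[z, ] <- 1 / 4
  p2 <- p2 / rowSums(p2)
  combine_hierarchy(p1, p2)
}

#' Predict score vectors on a surface grid
#'
#' Featurizes every grid point of a structure and runs the hierarchical
#' model; a pure function of (structure, grid, model). The registry that
#' produced the model's training features must match the one used here.
#'
#' @param model An `rs_hierarchical`.
#' @param structure A `complex_structure`.
#' @param grid Grid tibble.
#' @param registry A `property_registry`.
#' @return The grid tibble with the seven `prob_*` columns appended.
#' @export
predict_surface <- function(model, structure, grid,
                            registry = default_registry()) {
  if (!identical(model$registry_version, registry$version)) {
    abort(sprintf("registry mismatch: model trained with '%s', got '%s'",
                  model$registry_version, registry$version))
  }
  feats <- featurize_grid(grid, structure, registry)
  dplyr::bind_cols(grid, predict_hierarchical(model, feats))
}

#' Vote a residue site / non-site from nearby grid-point scores
#'
#' Takes the `n_vote` grid points nearest to the residue (fewer when fewer
#' exist); each point votes "site" when its summed non-X probability exceeds
#' its X probability. The majority wins; an exact tie is called non-site
#' (conservative).
#'
#' @param point_scores Tibble with the seven `prob_*` columns (one row per
#'   grid point, aligned with `grid`).
#' @param grid Grid tibble with `x`, `y`, `z`.
#' @param residue List or tibble row with `chain` and `resno`.
#' @param structure A `complex_structure` (for the residue's atom
#'   coordinates).
#' @param n_vote Number of voting points (default 30).
#' @return `"site"` or `"non-site"`.
#' @export
residue_vote <- function(point_scores, grid, residue, structure,
                         n_vote = 30L) {
  if (nrow(grid) == 0) abort("need at least one grid point")
  res_atoms <- dplyr::filter(protein_atoms(structure),
                             .data$chain == residue$chain,
                             .data$resno == residue$resno)
  if (nrow(res_atoms) == 0) abort("residue has no protein atoms")
  d <- min_dist_to(cbind(grid$x, grid$y, grid$z), atom_xyz(res_atoms))$dist
  take <- order(d)[seq_len(min(n_vote, nrow(grid)))]
  px <- point_scores$prob_X[take]
  site_votes <- sum((1 - px) > px)
  if (site_votes > length(take) / 2) "site" else "non-site"
}
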