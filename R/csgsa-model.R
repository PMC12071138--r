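#' Build the fused CSGSA feature table
#'
#' Assembles the model input for one train/test split. Tumor markers enter
#' as log10 concentrations (shifted by half the smallest positive training
#' value per marker so zeros stay finite); the two marker glycopeptides
#' enter raw (they are already relative expressions); the EGP matrix is
#' centered and unit-scaled with training-fold statistics and compressed to
#' `k` principal-component scores whose loadings are fit on the training
#' fold only, the test fold being projected with those loadings. All columns
#' are finally standardized by training statistics. Fitting any statistic on
#' the full data before splitting leaks test information; the `leakyPCA`
#' switch exists only to reproduce that (incorrect) global-PCA variant.
#'
#' @param markerTable samples x 9 matrix of tumor-marker concentrations.
#' @param glycoValues samples x 2 matrix of marker-glycopeptide relative
#'   expressions (the AT271-FSG / MG70-FSG roles); ignored for model set 1.
#' @param egpMatrix samples x features EGP relative-expression matrix
#'   (zeros for missing); ignored for model sets 1 and 2.
#' @param modelSet 1 (markers only), 2 (+ marker glycopeptides) or
#'   3 (+ `k` EGP principal components).
#' @param k number of principal components for model set 3.
#' @param trainIndex integer or logical index of training samples.
#' @param leakyPCA fit scaling and PCA on all samples (leaky; for
#'   reproduction studies only).
#' @return list with `train` and `test` feature matrices and `roles`
#'   labelling each column as marker / glycopeptide / pc.
#' @export
buildFeatures <- function(markerTable, glycoValues = NULL, egpMatrix = NULL,
                          modelSet = 3, k = 100, trainIndex,
                          leakyPCA = FALSE) {
  stopifnot(modelSet %in% 1:3)
  markerTable <- as.matrix(markerTable)
  n <- nrow(markerTable)
  tr <- seq_len(n) %in% (if (is.logical(trainIndex)) which(trainIndex) else trainIndex)
  te <- !tr
  fit_rows <- if (leakyPCA) rep(TRUE, n) else tr

  # markers: log10 with a train-derived offset per column
  eps <- apply(markerTable[fit_rows, , drop = FALSE], 2, function(v) {
    pos <- v[v > 0]
    if (length(pos)) min(pos) * 0.5 else 1
  })
  lm10 <- log10(sweep(markerTable, 2, eps, `+`))
  blocks <- list(lm10)
  roles <- rep("marker", ncol(lm10))

  if (modelSet >= 2) {
    glycoValues <- as.matrix(glycoValues)
    stopifnot(nrow(glycoValues) == n)
    if (is.null(colnames(glycoValues)))
      colnames(glycoValues) <- paste0("MG", seq_len(ncol(glycoValues)))
    blocks <- c(blocks, list(glycoValues))
    roles <- c(roles, rep("glycopeptide", ncol(glycoValues)))
  }
  if (modelSet == 3) {
    egpMatrix <- as.matrix(egpMatrix)
    stopifnot(nrow(egpMatrix) == n)
    mu <- colMeans(egpMatrix[fit_rows, , drop = FALSE])
    sdev <- apply(egpMatrix[fit_rows, , drop = FALSE], 2, sd)
    sdev[sdev == 0] <- 1
    z <- sweep(sweep(egpMatrix, 2, mu), 2, sdev, `/`)
    max_k <- min(sum(fit_rows) - 1L, ncol(z))
    if (k > max_k)
      stop("k = ", k, " exceeds the feasible number of components (", max_k, ")")
    pc <- prcomp(z[fit_rows, , drop = FALSE], center = FALSE, scale. = FALSE)
    scores <- z %*% pc$rotation[, seq_len(k), drop = FALSE]
    colnames(scores) <- paste0("PC", seq_len(k))
    blocks <- c(blocks, list(scores))
    roles <- c(roles, rep("pc", k))
  }
  feat <- do.call(cbind, blocks)

  # final per-column standardization with training statistics
  mu <- colMeans(feat[fit_rows, , drop = FALSE])
  sdev <- apply(feat[fit_rows, , drop = FALSE], 2, sd)
  sdev[sdev == 0] <- 1
  feat <- sweep(sweep(feat, 2, mu), 2, sdev, `/`)
  list(train = feat[tr, , drop = FALSE], test = feat[te, , drop = FALSE],
       roles = setNames(roles, colnames(feat)))
}

# ---- compact feed-forward network --------------------------------------

.relu <- function(x) pmax(x, 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

# two dense+dropout blocks and a sigmoid output, trained with Adam on
# binary cross-entropy; early stopping on an inner validation split
.mlpFit <- function(x, y, hidden = c(64, 64), dropout = 0.3, epochs = 150,
                    batch = 64, lr = 2e-3, val_frac = 0.1, patience = 15) {
  n <- nrow(x); d <- ncol(x)
  # shuffle, then carve a stratified inner validation split off the front
  perm <- sample.int(n)
  x <- x[perm, , drop = FALSE]; y <- y[perm]
  vmask <- logical(n)
  for (ix in split(seq_len(n), y))
    vmask[ix[seq_len(max(1L, floor(length(ix) * val_frac)))]] <- TRUE
  xv <- x[vmask, , drop = FALSE]; yv <- y[vmask]
  xt <- x[!vmask, , drop = FALSE]; yt <- y[!vmask]

  sizes <- c(d, hidden, 1L)
  W <- lapply(seq_len(3), function(l)
    matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(3), function(l) numeric(sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8; t_step <- 0

  fwd <- function(xx) {
    h1 <- .relu(sweep(xx %*% W[[1]], 2, b[[1]], `+`))
    h2 <- .relu(sweep(h1 %*% W[[2]], 2, b[[2]], `+`))
    .sigmoid(h2 %*% W[[3]] + b[[3]])[, 1]
  }
  bce <- function(p, yy) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(yy * log(p) + (1 - yy) * log(1 - p))
  }

  best <- list(loss = Inf, W = W, b = b)
  wait <- 0
  nt <- nrow(xt)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nt)
    for (start in seq(1, nt, by = batch)) {
      ix <- ord[start:min(start + batch - 1, nt)]
      xb <- xt[ix, , drop = FALSE]; yb <- yt[ix]
      m <- length(ix)
      a1 <- sweep(xb %*% W[[1]], 2, b[[1]], `+`); h1 <- .relu(a1)
      d1 <- matrix(rbinom(m * ncol(h1), 1, 1 - dropout) / (1 - dropout),
                   m, ncol(h1))
      h1d <- h1 * d1
      a2 <- sweep(h1d %*% W[[2]], 2, b[[2]], `+`); h2 <- .relu(a2)
      d2 <- matrix(rbinom(m * ncol(h2), 1, 1 - dropout) / (1 - dropout),
                   m, ncol(h2))
      h2d <- h2 * d2
      p <- .sigmoid(h2d %*% W[[3]] + b[[3]])[, 1]
      # gradients of mean BCE wrt pre-sigmoid: (p - y)/m
      g3 <- (p - yb) / m
      gW3 <- crossprod(h2d, g3); gb3 <- sum(g3)
      gh2 <- (g3 %*% t(W[[3]])) * d2 * (a2 > 0)
      gW2 <- crossprod(h1d, gh2); gb2 <- colSums(gh2)
      gh1 <- (gh2 %*% t(W[[2]])) * d1 * (a1 > 0)
      gW1 <- crossprod(xb, gh1); gb1 <- colSums(gh1)
      gW <- list(gW1, gW2, gW3); gb <- list(gb1, gb2, gb3)
      t_step <- t_step + 1
      for (l in 1:3) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        mhW <- mW[[l]] / (1 - beta1^t_step); vhW <- vW[[l]] / (1 - beta2^t_step)
        mhb <- mb[[l]] / (1 - beta1^t_step); vhb <- vb[[l]] / (1 - beta2^t_step)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + aeps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + aeps)
      }
    }
    vloss <- bce(fwd(xv), yv)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, W = W, b = b)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  list(W = best$W, b = best$b, val_loss = best$loss, epochs_run = ep)
}

.mlpPredict <- function(fit, x) {
  h1 <- .relu(sweep(x %*% fit$W[[1]], 2, fit$b[[1]], `+`))
  h2 <- .relu(sweep(h1 %*% fit$W[[2]], 2, fit$b[[2]], `+`))
  .sigmoid(h2 %*% fit$W[[3]] + fit$b[[3]])[, 1]
}

.asBinary <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.numeric(labels))
  pos <- if ("cancer" %in% labels) "cancer" else sort(unique(as.character(labels)))[2]
  as.numeric(labels == pos)
}

#' Train a CSGSA classifier
#'
#' Two learner families with a common probability-scorer contract: a
#' feed-forward network (`"nn"`: input, two dense+dropout blocks, sigmoid
#' output; binary cross-entropy minimized by adaptive-moment gradient
#' descent with early stopping on an inner 10% validation split) and
#' gradient-boosted decision trees (`"gbt"`: additive trees fit on logistic
#' loss via xgboost). All randomness is governed by `seed`; repeated calls
#' with the same seed give identical predictions.
#'
#' @param x samples x features numeric matrix.
#' @param labels class labels ("cancer" positive) or 0/1 numeric.
#' @param learner `"nn"` or `"gbt"`.
#' @param seed integer RNG seed.
#' @param params optional overrides: for `"nn"` any of `hidden`, `dropout`,
#'   `epochs`, `batch`, `lr`, `val_frac`, `patience`; for `"gbt"` any of
#'   `nrounds` (200), `max_depth` (3), `eta` (0.1).
#' @return a `csgsaClassifier` object; score new samples with `predict()`.
#' @export
trainClassifier <- function(x, labels, learner = c("nn", "gbt"), seed = 1L,
                            params = list()) {
  learner <- match.arg(learner)
  x <- as.matrix(x)
  y <- .asBinary(labels)
  if (length(unique(y)) < 2) stop("training fold contains a single class")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  center <- scale_ <- NULL
  fit <- withSeed(seed, {
    if (learner == "nn") {
      center <- colMeans(x)
      scale_ <- apply(x, 2, sd); scale_[scale_ == 0] <- 1
      xs <- sweep(sweep(x, 2, center), 2, scale_, `/`)
      do.call(.mlpFit, c(list(x = xs, y = y), params))
    } else {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 3,
                      eta = params$eta %||% 0.1, nthread = 1),
        data = dtrain, nrounds = params$nrounds %||% 200, verbose = 0)
    }
  })
  structure(list(learner = learner, fit = fit, center = center,
                 scale = scale_, feature_names = colnames(x)),
            class = "csgsaClassifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname trainClassifier
#' @param object a fitted `csgsaClassifier`.
#' @param newdata samples x features matrix with the training columns.
#' @param ... unused.
#' @return `predict`: predicted class-1 probabilities in \[0, 1\].
#' @export
predict.csgsaClassifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  if (object$learner == "nn") {
    xs <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
    .mlpPredict(object$fit, xs)
  } else {
    predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1))
  }
}

#' Split-frequency feature importance of a tree ensemble
#'
#' Counts, per feature, how often it is used to split the data across all
#' trees of a gradient-boosted ensemble (the "F-score"), returned in
#' descending order. The counts sum to the ensemble's total split count.
#'
#' @param model a `csgsaClassifier` with `learner = "gbt"`.
#' @return named integer vector of split counts, descending.
#' @export
featureImportance <- function(model) {
  if (!inherits(model, "csgsaClassifier") || model$learner != "gbt")
    stop("feature importance by split count requires a tree ('gbt') model")
  dump <- xgboost::xgb.dump(model$fit)
  used <- regmatches(dump, regexpr("\\[[^<]+<", dump))
  used <- substr(used, 2, nchar(used) - 1)
  counts <- sort(table(used), decreasing = TRUE)
  setNames(as.integer(counts), names(counts))
}

#' Repeated stratified 70/30 evaluation with pooled ROC
#'
#' The evaluation protocol of the screening study: per repeat, samples are
#' split stratified-at-random into 70% training and 30% testing; all
#' feature engineering (marker log offsets, EGP scaling, PCA loadings) is
#' fit on the training fold only; the classifier is trained and the test
#' fold scored. Test predictions are pooled over all repeats (each sample is
#' expected in the test pool about `n_repeats * (1 - train_fraction)` times)
#' and the headline ROC-AUC is computed on that cumulative pool; per-repeat
#' AUCs are retained for learner comparison.
#'
#' @inheritParams buildFeatures
#' @param labels per-sample class labels ("cancer"/"healthy").
#' @param learner,params passed to [trainClassifier()].
#' @param nRepeats number of random splits (default 10).
#' @param trainFraction training fraction (default 0.7).
#' @param seed master seed; repeat r uses seed + r for its split and fit.
#' @return an `EvaluationResult`: `predictions` (sample, repeat, probability,
#'   label), `pooled_auc`, `roc`, `per_repeat_auc`.
#' @export
repeatedSplitEvaluate <- function(markerTable, glycoValues = NULL,
                                  egpMatrix = NULL, labels,
                                  modelSet = 3, learner = "nn",
                                  nRepeats = 10, trainFraction = 0.7,
                                  k = 100, seed = 1L, leakyPCA = FALSE,
                                  params = list()) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  markerTable <- as.matrix(markerTable)
  n <- nrow(markerTable)
  stopifnot(length(labels) == n)
  y <- .asBinary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  ids <- rownames(markerTable) %||% sprintf("S%04d", seq_len(n))

  preds <- vector("list", nRepeats)
  per_auc <- numeric(nRepeats)
  for (r in seq_len(nRepeats)) {
    tr <- withSeed(seed + r, {
      for (attempt in 1:100) {
        idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
          ntr <- min(max(round(length(ix) * trainFraction), 1L),
                     length(ix) - 1L)
          sample(ix, ntr)
        }))
        if (length(unique(y[-idx])) == 2 && length(unique(y[idx])) == 2) break
        if (attempt == 100) stop("could not find a two-class split")
      }
      sort(idx)   # original row order, matching buildFeatures' views
    })
    ft <- buildFeatures(markerTable, glycoValues, egpMatrix,
                        modelSet = modelSet, k = k, trainIndex = tr,
                        leakyPCA = leakyPCA)
    model <- trainClassifier(ft$train, y[tr], learner = learner,
                             seed = seed + r, params = params)
    te <- setdiff(seq_len(n), tr)
    p <- predict(model, ft$test)
    preds[[r]] <- data.frame(sample_id = ids[te], rep = r,
                             probability = unname(p), label = y[te])
    per_auc[r] <- rocAUC(p, y[te], positive = 1)$auc
  }
  pool <- do.call(rbind, preds)
  roc <- rocAUC(pool$probability, pool$label, positive = 1)
  structure(list(predictions = pool, pooled_auc = roc$auc, roc = roc,
                 per_repeat_auc = per_auc, model_set = modelSet,
                 learner = learner),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("Model %d (%s): pooled AUC %.3f over %d repeats (per-repeat %.3f +- %.3f)\n",
              x$model_set, x$learner, x$pooled_auc,
              length(x$per_repeat_auc), mean(x$per_repeat_auc),
              sd(x$per_repeat_auc)))
  invisible(x)
}

#' CSGSA score transform
#'
#' Maps a predicted cancer probability p to the reporting scale
#' score = -log10(1 - p), with p clipped at 1 - 1e-10 so scores span
#' \[0, 10\]. `csgsaProb` inverts the transform.
#'
#' @param p predicted probabilities in \[0, 1\].
#' @return scores in \[0, 10\].
#' @examples
#' csgsaScore(c(0, 0.9, 0.99, 1))  # 0 1 2 10
#' @export
csgsaScore <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop("probabilities must lie in [0, 1]")
  -log10(1 - pmin(p, 1 - 1e-10))
}

#' @rdname csgsaScore
#' @param score CSGSA scores in \[0, 10\].
#' @export
csgsaProb <- function(score) 1 - 10^(-score)

#' Compare two learners across repeated splits
#'
#' Paired two-sided t-test on per-repeat AUCs of two learners evaluated on
#' the same splits. When the paired differences are exactly constant the
#' test degenerates: p = 1 for a zero difference, p = 0 otherwise.
#'
#' @param auc_a,auc_b per-repeat AUC vectors of equal length >= 2.
#' @return the p-value.
#' @export
compareLearners <- function(auc_a, auc_b) {
  stopifnot(length(auc_a) == length(auc_b))
  if (length(auc_a) < 2) stop("need >= 2 repeats")
  d <- auc_a - auc_b
  if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  t.test(auc_a, auc_b, paired = TRUE)$p.value
}
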