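#' Model-family specification for the classification core
#'
#' @param family `"plsda"` (partial least squares discriminant analysis) or
#'   `"svm"` (support vector machine with a linear kernel).
#' @param grid tuning grid: number of components for PLS-DA, cost values for
#'   the SVM.
#' @param rfe_step features removed per recursive-feature-elimination step.
#' @param inner_folds folds of the inner tuning/selection cross-validation.
#' @return list of class `model_spec`.
#' @export
modelSpec <- function(family = c("plsda", "svm"),
                      grid = NULL, rfe_step = 20L, inner_folds = 10L) {
  family <- match.arg(family)
  if (is.null(grid))
    grid <- if (family == "plsda") 1:5 else c(0.01, 0.1, 1, 10)
  if (!length(grid)) stop("tuning grid must be non-empty")
  if (rfe_step < 1) stop("rfe_step must be >= 1")
  structure(list(family = family, grid = grid,
                 rfe_step = as.integer(rfe_step),
                 inner_folds = as.integer(inner_folds)),
            class = "model_spec")
}

## ---- scaling -------------------------------------------------------------

fitScaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  bad <- scl == 0 | !is.finite(scl)
  if (any(bad))
    stop("constant feature column(s) after scaling: ",
         paste(colnames(X)[bad], collapse = ", "))
  list(center = ctr, scale = scl)
}

applyScaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, `-`), 2, sc$scale, `/`)
}

## ---- stratified splitting ------------------------------------------------

largestRemainder <- function(sizes, total) {
  raw <- sizes / sum(sizes) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Stratified train/validation split
#'
#' Splits per diagnosis class to `round(train_fraction * n_class)` training
#' samples; within a class, allocation is balanced over sex and IQ terciles
#' (largest-remainder apportionment) with a seeded shuffle inside each
#' substratum, so both partitions carry similar proportions of the
#' stratification factors.
#'
#' @param samples data.frame with `sample_id`, `diagnosis` and optionally the
#'   `strata` columns.
#' @param train_fraction fraction in (0, 1).
#' @param strata extra factor columns used within class (default sex; `iq` is
#'   binned into terciles when present).
#' @param seed integer seed.
#' @return data.frame `sample_id`, `partition` ("train"/"validation").
#' @export
stratifiedSplit <- function(samples, train_fraction, strata = "sex",
                            seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  stopifnot(all(c("sample_id", "diagnosis") %in% colnames(samples)))
  set.seed(as.integer(seed))
  part <- rep("validation", nrow(samples))
  for (d in unique(samples$diagnosis)) {
    idx <- which(samples$diagnosis == d)
    n_train <- round(train_fraction * length(idx))
    key <- rep("all", length(idx))
    for (s in intersect(strata, colnames(samples)))
      key <- paste(key, samples[[s]][idx])
    if ("iq" %in% colnames(samples)) {
      br <- unique(quantile(samples$iq[idx], c(0, 1 / 3, 2 / 3, 1),
                            na.rm = TRUE))
      if (length(br) > 2)
        key <- paste(key, cut(samples$iq[idx], br, include.lowest = TRUE))
    }
    sub <- split(idx, key)
    alloc <- largestRemainder(lengths(sub), n_train)
    for (k in seq_along(sub)) {
      take <- sub[[k]][sample.int(length(sub[[k]]))][seq_len(alloc[k])]
      part[take] <- "train"
    }
  }
  data.frame(sample_id = samples$sample_id, partition = part,
             stringsAsFactors = FALSE)
}

classStratifiedTrainIdx <- function(y, fraction) {
  idx <- integer(0)
  for (lv in levels(y)) {
    w <- which(y == lv)
    idx <- c(idx, w[sample.int(length(w))][seq_len(round(fraction * length(w)))])
  }
  sort(idx)
}

stratifiedFoldIds <- function(y, k) {
  f <- integer(length(y))
  for (lv in levels(y)) {
    w <- which(y == lv)
    f[w] <- sample(rep_len(sample.int(k), length(w)))
  }
  f
}

## ---- PLS-DA --------------------------------------------------------------

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis for two classes: the class is
#' coded -1 (control) / +1 (case), predictors are autoscaled (mean 0, sd 1,
#' parameters kept for prediction), and latent components are extracted by
#' NIPALS -- each component's weight vector maximizes covariance with the
#' class code, followed by deflation. Prediction is the sign of the regressed
#' class score.
#'
#' @param X samples x features numeric matrix (raw scale; scaled internally).
#' @param y factor with levels control, case (or coercible).
#' @param n_components number of latent components (capped at rank limits).
#' @return object of class `plsda_model` with weights `W`, loadings `P`,
#'   scores `T`, per-component regression coefficients `q`, explained class
#'   variance `ssy`, the scaler, and `coef` (regression vector on the scaled
#'   predictors).
#' @export
fitPlsda <- function(X, y, n_components = 2L) {
  X <- as.matrix(X)
  y <- asDiagnosisFactor(y)
  yv <- ifelse(y == "case", 1, -1)
  sc <- fitScaler(X)
  Xs <- applyScaler(X, sc)
  ybar <- mean(yv)
  yc <- yv - ybar
  A <- min(n_components, ncol(X), nrow(X) - 1)
  p <- ncol(X)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, nrow(X), 0)
  q <- ssy <- numeric(0)
  Xd <- Xs; yd <- yc
  for (a in seq_len(A)) {
    wv <- crossprod(Xd, yd)
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break
    wv <- wv / nw
    tv <- Xd %*% wv
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xd, tv) / tt
    qa <- sum(yd * tv) / tt
    Xd <- Xd - tv %*% t(pv)
    yd <- yd - qa * tv
    W <- cbind(W, wv); P <- cbind(P, pv); Tm <- cbind(Tm, tv)
    q <- c(q, qa); ssy <- c(ssy, qa^2 * tt)
  }
  if (!ncol(W)) stop("no covariance between predictors and class")
  coef <- W %*% solve(crossprod(P, W), q)
  structure(list(W = W, P = P, T = Tm, q = q, ssy = ssy, coef = coef,
                 intercept = ybar, scaler = sc,
                 features = colnames(X), n_components = ncol(W)),
            class = "plsda_model")
}

#' @rdname fitPlsda
#' @param object a fitted `plsda_model`
#' @param newdata samples x features matrix on the raw scale
#' @param ... unused
#' @return `predict`: list with `score` (continuous decision value) and
#'   `class` (factor control/case; case iff score > 0).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  Xs <- applyScaler(as.matrix(newdata)[, object$features, drop = FALSE],
                    object$scaler)
  score <- drop(Xs %*% object$coef) + object$intercept
  cls <- factor(ifelse(score > 0, "case", "control"),
                levels = c("control", "case"))
  list(score = score, class = cls)
}

#' Variable importance in the projection
#'
#' `VIP_j = sqrt(p * sum_a ssy_a * (w_aj / ||w_a||)^2 / sum_a ssy_a)` where
#' `p` is the feature count, `w_a` the component-a weight vector and `ssy_a`
#' the class variance explained by component a. By construction
#' `sum_j VIP_j^2 = p`.
#'
#' @param model a fitted `plsda_model`.
#' @return named numeric vector of VIP scores.
#' @export
vipScores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  if (sum(model$ssy) <= 0) stop("zero total explained class variance")
  W2 <- sweep(model$W, 2, sqrt(colSums(model$W^2)), `/`)^2
  p <- nrow(W2)
  vip <- sqrt(p * drop(W2 %*% model$ssy) / sum(model$ssy))
  setNames(vip, model$features)
}

## ---- linear SVM ----------------------------------------------------------

#' Fit a linear-kernel support vector machine
#'
#' Maximum-margin linear classifier with hinge-loss penalty `cost`, fitted by
#' \pkg{e1071} on autoscaled predictors. The weight vector is oriented so
#' that larger decision values indicate the case class; per-feature
#' importance is |weight| rescaled so the squared scores sum to the feature
#' count (comparable to VIP).
#'
#' @param X samples x features matrix (raw scale; scaled internally).
#' @param y factor with levels control, case.
#' @param cost positive penalty parameter.
#' @return object of class `svm_linear_model` with `w`, `b`, the scaler and
#'   `importance`.
#' @export
fitLinearSVM <- function(X, y, cost = 1) {
  if (cost <= 0) stop("cost must be positive")
  X <- as.matrix(X)
  y <- asDiagnosisFactor(y)
  sc <- fitScaler(X)
  Xs <- applyScaler(X, sc)
  fit <- e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  dec <- drop(Xs %*% w) + b
  if (mean(dec[y == "case"]) < mean(dec[y == "control"])) {
    w <- -w; b <- -b
  }
  imp <- abs(w)
  imp <- imp * sqrt(length(imp) / sum(imp^2))
  structure(list(w = setNames(w, colnames(X)), b = b, scaler = sc,
                 importance = setNames(imp, colnames(X)),
                 features = colnames(X)),
            class = "svm_linear_model")
}

#' @rdname fitLinearSVM
#' @param object a fitted `svm_linear_model`
#' @param newdata samples x features matrix on the raw scale
#' @param ... unused
#' @export
predict.svm_linear_model <- function(object, newdata, ...) {
  Xs <- applyScaler(as.matrix(newdata)[, object$features, drop = FALSE],
                    object$scaler)
  score <- drop(Xs %*% object$w) + object$b
  cls <- factor(ifelse(score > 0, "case", "control"),
                levels = c("control", "case"))
  list(score = score, class = cls)
}

## ---- metrics -------------------------------------------------------------

asDiagnosisFactor <- function(y) {
  if (!is.factor(y)) y <- factor(y)
  if (!all(levels(y) %in% c("control", "case")))
    stop("class labels must be 'control'/'case'")
  factor(as.character(y), levels = c("control", "case"))
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, counting ties as 1/2.
#'
#' @param scores numeric decision values (higher = more case-like).
#' @param labels factor or vector with both classes (control/case).
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.9, 0.4, 0.8, 0.2), c("case", "case", "control", "control"))
#' @export
rocAuc <- function(scores, labels) {
  y <- asDiagnosisFactor(labels)
  np <- sum(y == "case"); nn <- sum(y == "control")
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == "case"]) - np * (np + 1) / 2) / (np * nn)
}

#' Accuracy, sensitivity and specificity
#'
#' Accuracy is the proportion of correctly classified samples; sensitivity
#' the proportion of correctly classified cases; specificity the proportion
#' of correctly classified controls.
#'
#' @param predicted,truth class vectors (control/case) of equal length.
#' @return named numeric vector (accuracy, sensitivity, specificity).
#' @export
classificationMetrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  pr <- asDiagnosisFactor(predicted)
  tr <- asDiagnosisFactor(truth)
  if (length(unique(tr)) < 2) stop("truth must contain both classes")
  c(accuracy = mean(pr == tr),
    sensitivity = mean(pr[tr == "case"] == "case"),
    specificity = mean(pr[tr == "control"] == "control"))
}

## ---- fitting helpers -----------------------------------------------------

fitFamily <- function(X, y, spec, param) {
  if (spec$family == "plsda") fitPlsda(X, y, n_components = param)
  else fitLinearSVM(X, y, cost = param)
}

familyImportance <- function(model, spec) {
  if (spec$family == "plsda") vipScores(model) else model$importance
}

# pooled out-of-fold decision values -> one AUC
innerCvAuc <- function(X, y, spec, param, fold_ids) {
  scores <- numeric(length(y))
  for (k in unique(fold_ids)) {
    tr <- fold_ids != k
    if (length(unique(y[tr])) < 2) next
    fit <- fitFamily(X[tr, , drop = FALSE], y[tr], spec, param)
    scores[!tr] <- predict(fit, X[!tr, , drop = FALSE])$score
  }
  rocAuc(scores, y)
}

tuneParam <- function(X, y, spec, fold_ids) {
  aucs <- vapply(spec$grid, function(g) innerCvAuc(X, y, spec, g, fold_ids),
                 0)
  # ties favor the simpler model (first grid entry)
  spec$grid[which.max(aucs)]
}

rfeSizes <- function(p, step) {
  if (p <= step) return(p)
  sizes <- seq(floor((p - 1) / step) * step, step, by = -step)
  c(p, sizes[sizes < p])
}

# backward RFE on (X, y): returns best subset (by inner-CV AUC) and the
# last-computed importance of every feature
runRfe <- function(X, y, spec, param, fold_ids) {
  p <- ncol(X)
  if (p < spec$rfe_step)
    stop("fewer features (", p, ") than rfe_step (", spec$rfe_step, ")")
  sizes <- rfeSizes(p, spec$rfe_step)
  current <- colnames(X)
  last_imp <- setNames(rep(NA_real_, p), colnames(X))
  auc_by_size <- setNames(numeric(length(sizes)), sizes)
  subsets <- list()
  for (i in seq_along(sizes)) {
    k <- sizes[i]
    current <- current[seq_len(min(k, length(current)))]
    Xc <- X[, current, drop = FALSE]
    fit <- fitFamily(Xc, y, spec, param)
    imp <- familyImportance(fit, spec)
    last_imp[current] <- imp[current]
    auc_by_size[i] <- innerCvAuc(Xc, y, spec, param, fold_ids)
    subsets[[as.character(k)]] <- current
    # order current set by importance (desc, ties by id) for the next cut
    current <- current[order(-imp[current], current)]
  }
  # ties in AUC favor the smaller subset
  top <- which(auc_by_size == max(auc_by_size))
  best <- names(auc_by_size)[top[length(top)]]
  list(best_size = as.integer(best), best_subset = subsets[[best]],
       auc_by_size = auc_by_size, importance = last_imp)
}

oneResample <- function(X, y, spec, outer_fraction, rs_seed,
                        permute = FALSE) {
  set.seed(rs_seed)
  if (permute) y <- sample(y)
  tr_idx <- classStratifiedTrainIdx(y, outer_fraction)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xte <- X[-tr_idx, , drop = FALSE]; yte <- y[-tr_idx]
  fold_ids <- stratifiedFoldIds(ytr, spec$inner_folds)
  param <- tuneParam(Xtr, ytr, spec, fold_ids)
  rfe <- runRfe(Xtr, ytr, spec, param, fold_ids)
  fit <- fitFamily(Xtr[, rfe$best_subset, drop = FALSE], ytr, spec, param)
  pred <- predict(fit, Xte)
  m <- classificationMetrics(pred$class, yte)
  list(metrics = c(auc = rocAuc(pred$score, yte), m),
       n_train = length(tr_idx), n_test = length(yte),
       subset_size = rfe$best_size, param = param,
       importance = rfe$importance)
}

deriveSeeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## ---- nested cross-validation ---------------------------------------------

#' Nested cross-validation with RFE and a resample-averaged VIP index
#'
#' For each of `n_resamples` outer resamples: a class-stratified
#' `outer_fraction` split of the training samples; on the outer-train part
#' only, an inner `inner_folds`-fold cross-validation tunes the model
#' parameter over `spec$grid`, then backward recursive feature elimination
#' removes the `rfe_step` lowest-importance features per step, scoring every
#' candidate subset by inner-CV AUC; the best subset's model predicts the
#' untouched outer-test part. Importance scores (VIP for PLS-DA, rescaled
#' |weight| for the linear SVM) are averaged across resamples -- a feature
#' eliminated during RFE contributes its last-computed score -- and ranked
#' (rank 1 = most important, ties broken by feature id). Outer-test samples
#' never influence scaling, tuning, elimination or ranking.
#'
#' @param X samples x features matrix (or a [MetaboSet-class], in which case
#'   `y` defaults to its diagnosis).
#' @param y factor control/case.
#' @param spec a [modelSpec()].
#' @param n_resamples number of outer resamples (default 100).
#' @param outer_fraction outer-train fraction (default 0.8).
#' @param seed run seed; per-resample seeds are derived from it so any
#'   resample is reproducible in isolation.
#' @return list of class `nested_cv` with `resamples` (per-resample metrics
#'   and chosen subset size), `vip_index` (feature_id, mean_importance,
#'   rank), `importance` (resamples x features matrix) and `summary`
#'   (mean and sd of the outer-test metrics).
#' @export
nestedCvRank <- function(X, y = NULL, spec = modelSpec("plsda"),
                         n_resamples = 100L, outer_fraction = 0.8,
                         seed = 1L) {
  if (is(X, "MetaboSet")) {
    if (is.null(y)) y <- diagnosis(X)
    X <- t(areas(X))
  }
  y <- asDiagnosisFactor(y)
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  seeds <- deriveSeeds(seed, n_resamples)
  res <- lapply(seq_len(n_resamples), function(r)
    oneResample(X, y, spec, outer_fraction, seeds[r]))
  collectNestedCv(res, spec, colnames(X))
}

collectNestedCv <- function(res, spec, feature_ids) {
  imp <- do.call(rbind, lapply(res, `[[`, "importance"))
  mets <- do.call(rbind, lapply(res, `[[`, "metrics"))
  resamples <- data.frame(
    resample = seq_len(nrow(mets)),
    n_train = vapply(res, `[[`, 0L, "n_train"),
    n_test = vapply(res, `[[`, 0L, "n_test"),
    subset_size = vapply(res, `[[`, 0L, "subset_size"),
    param = vapply(res, function(r) r$param, 0),
    mets)
  mean_imp <- colMeans(imp, na.rm = TRUE)
  ord <- order(-mean_imp, feature_ids)
  vip_index <- data.frame(feature_id = feature_ids,
                          mean_importance = mean_imp,
                          rank = NA_integer_, stringsAsFactors = FALSE)
  vip_index$rank[ord] <- seq_along(ord)
  structure(list(resamples = resamples, vip_index = vip_index,
                 importance = imp, family = spec$family,
                 summary = rbind(mean = colMeans(mets),
                                 sd = apply(mets, 2, sd))),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat("Nested CV (", x$family, "): ", nrow(x$resamples), " resamples\n",
      sep = "")
  print(round(x$summary, 3))
  invisible(x)
}

#' Permutation null of the nested-CV pipeline
#'
#' Reruns the full nested procedure of [nestedCvRank()] with a fresh random
#' permutation of the class labels in every outer resample, yielding the
#' null distribution of held-out performance.
#'
#' @inheritParams nestedCvRank
#' @return list of class `permutation_null`: `resamples` (per-resample null
#'   metrics), `mean_auc`, and `interval` (2.5% and 97.5% quantiles of the
#'   null AUC).
#' @export
permutationNull <- function(X, y = NULL, spec = modelSpec("plsda"),
                            n_resamples = 100L, outer_fraction = 0.8,
                            seed = 1L) {
  if (is(X, "MetaboSet")) {
    if (is.null(y)) y <- diagnosis(X)
    X <- t(areas(X))
  }
  y <- asDiagnosisFactor(y)
  seeds <- deriveSeeds(seed, n_resamples)
  res <- lapply(seq_len(n_resamples), function(r)
    oneResample(X, y, spec, outer_fraction, seeds[r], permute = TRUE))
  mets <- do.call(rbind, lapply(res, `[[`, "metrics"))
  structure(list(resamples = as.data.frame(mets),
                 mean_auc = mean(mets[, "auc"]),
                 interval = quantile(mets[, "auc"], c(0.025, 0.975))),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null over", nrow(x$resamples), "resamples\n")
  cat(sprintf("mean AUC %.3f (95%% interval %.3f-%.3f)\n", x$mean_auc,
              x$interval[1], x$interval[2]))
  invisible(x)
}

#' Feature-stepping evaluation on an independent validation set
#'
#' Steps through the VIP index in bins (by default 20, 40, ... up to all
#' features): for each bin size k, the model is tuned by inner
#' cross-validation and refitted on all training samples using the top-k
#' ranked features, then predicts the untouched validation set.
#'
#' @param train_X,train_y training matrix/labels (or `train_X` a
#'   [MetaboSet-class]).
#' @param valid_X,valid_y validation matrix/labels (no sample overlap with
#'   training allowed).
#' @param vip_index data.frame from [nestedCvRank()] (`$vip_index`), computed
#'   on the training samples only.
#' @param spec a [modelSpec()].
#' @param bins ascending subset sizes; default `seq(20, p, 20)` plus p.
#' @param seed seed for the inner-CV fold assignment.
#' @return data.frame per bin size: n_features, accuracy, sensitivity,
#'   specificity, auc.
#' @export
featureSteppingEval <- function(train_X, train_y = NULL, valid_X,
                                valid_y = NULL, vip_index,
                                spec = modelSpec("plsda"), bins = NULL,
                                seed = 1L) {
  if (is(train_X, "MetaboSet")) {
    if (is.null(train_y)) train_y <- diagnosis(train_X)
    train_X <- t(areas(train_X))
  }
  if (is(valid_X, "MetaboSet")) {
    if (is.null(valid_y)) valid_y <- diagnosis(valid_X)
    valid_X <- t(areas(valid_X))
  }
  if (length(intersect(rownames(train_X), rownames(valid_X))))
    stop("validation samples overlap the training set")
  train_y <- asDiagnosisFactor(train_y)
  valid_y <- asDiagnosisFactor(valid_y)
  if (is.list(vip_index) && !is.data.frame(vip_index))
    vip_index <- vip_index$vip_index
  p <- nrow(vip_index)
  if (is.null(bins)) bins <- unique(c(seq(spec$rfe_step, p, spec$rfe_step), p))
  if (is.unsorted(bins, strictly = TRUE) || max(bins) != p)
    stop("bins must be strictly increasing and end at the feature count")
  ranked <- vip_index$feature_id[order(vip_index$rank)]
  set.seed(as.integer(seed))
  fold_ids <- stratifiedFoldIds(train_y, spec$inner_folds)
  out <- lapply(bins, function(k) {
    feats <- ranked[seq_len(k)]
    Xtr <- train_X[, feats, drop = FALSE]
    param <- tuneParam(Xtr, train_y, spec, fold_ids)
    fit <- fitFamily(Xtr, train_y, spec, param)
    pred <- predict(fit, valid_X[, feats, drop = FALSE])
    m <- classificationMetrics(pred$class, valid_y)
    data.frame(n_features = k, param = param, accuracy = m["accuracy"],
               sensitivity = m["sensitivity"], specificity = m["specificity"],
               auc = rocAuc(pred$score, valid_y), row.names = NULL)
  })
  do.call(rbind, out)
}
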