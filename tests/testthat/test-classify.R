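test_that("stratifiedSplit reproduces the 61/21 study split", {
  cohort <- sampleCohort(cohortSpec(), seed = 1)
  sp <- stratifiedSplit(cohort, train_fraction = 61 / 82, seed = 2)
  tb <- table(sp$partition, cohort[sp$sample_id, "diagnosis"])
  expect_equal(unname(tb["train", "case"]), 39)
  expect_equal(unname(tb["train", "control"]), 22)
  expect_equal(unname(tb["validation", "case"]), 13)
  expect_equal(unname(tb["validation", "control"]), 8)
  # sex proportions carried into both partitions (within rounding)
  male_tr <- mean(cohort[sp$sample_id[sp$partition == "train"], "sex"] == "M")
  male_va <- mean(cohort[sp$sample_id[sp$partition == "validation"],
                         "sex"] == "M")
  expect_lt(abs(male_tr - male_va), 0.1)
  expect_identical(sp, stratifiedSplit(cohort, 61 / 82, seed = 2))
  expect_error(stratifiedSplit(cohort, 1), "between 0 and 1")
})

test_that("PLS-DA separates a separable toy problem", {
  set.seed(31)
  X <- cbind(sig = c(rnorm(10, 3), rnorm(10, -3)),
             noise = rnorm(20))
  y <- rep(c("case", "control"), each = 10)
  fit <- fitPlsda(X, y, n_components = 1)
  pred <- predict(fit, X)
  expect_equal(as.character(pred$class), y)
  expect_equal(rocAuc(pred$score, y), 1)
})

test_that("one-component weights are proportional to the class-mean contrast", {
  set.seed(32)
  X <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(rep(c("case", "control"), c(18, 12)),
              levels = c("control", "case"))
  fit <- fitPlsda(X, y, n_components = 1)
  Xs <- scale(X)
  contrast <- colMeans(Xs[y == "case", ]) - colMeans(Xs[y == "control", ])
  w <- drop(fit$W[, 1])
  expect_equal(w / sqrt(sum(w^2)),
               contrast / sqrt(sum(contrast^2)), tolerance = 1e-10)
})

test_that("VIP satisfies its algebraic identity and orders signal over noise", {
  set.seed(33)
  # single feature: VIP is exactly 1
  X1 <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "f1"))
  y <- rep(c("case", "control"), 10)
  expect_equal(unname(vipScores(fitPlsda(X1, y, 1))), 1)
  # sum of squared VIPs equals the feature count for every fit
  y40 <- rep(c("case", "control"), 20)
  for (i in 1:20) {
    p <- sample(2:15, 1)
    X <- matrix(rnorm(40 * p), 40, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    X[, 1] <- X[, 1] + ifelse(y40 == "case", 1.5, 0)
    fit <- fitPlsda(X, y40, n_components = sample(1:3, 1))
    v <- vipScores(fit)
    expect_equal(sum(v^2), p, tolerance = 1e-8)
  }
  # informative feature above 1, pure noise below
  X <- cbind(sig = rnorm(40) + ifelse(y40 == "case", 2, 0), noise = rnorm(40))
  v <- vipScores(fitPlsda(X, y40, 1))
  expect_gt(v["sig"], 1)
  expect_lt(v["noise"], 1)
})

test_that("PLS-DA predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(34)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- factor(rep(c("case", "control"), 15), levels = c("control", "case"))
  X[, 1:2] <- X[, 1:2] + ifelse(y == "case", 1, 0)
  fit <- fitPlsda(X, y, n_components = 2)
  ref <- mixOmics::pls(scale(X), ifelse(y == "case", 1, -1), ncomp = 2,
                       scale = FALSE, mode = "regression")
  # latent scores span the same space (up to sign)
  for (a in 1:2)
    expect_equal(abs(cor(fit$T[, a], ref$variates$X[, a])), 1,
                 tolerance = 1e-6)
})

test_that("linear SVM behaves as a maximum-margin classifier", {
  # 2-point toy: both classified, midpoint on the boundary
  X <- matrix(c(1, -1, 0.5, -0.5), 2, 2,
              dimnames = list(NULL, c("a", "b")))
  y <- c("case", "control")
  fit <- fitLinearSVM(X, y, cost = 10)
  pred <- predict(fit, X)
  expect_equal(as.character(pred$class), y)
  expect_equal(sum(pred$score), 0, tolerance = 1e-6)
  set.seed(35)
  Xr <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
  yr <- factor(ifelse(Xr[, 1] + rnorm(40, 0, 0.5) > 0, "case", "control"),
               levels = c("control", "case"))
  f1 <- fitLinearSVM(Xr, yr, cost = 1)
  # class flip negates the weight vector
  yflip <- factor(ifelse(yr == "case", "control", "case"),
                  levels = c("control", "case"))
  f2 <- fitLinearSVM(Xr, yflip, cost = 1)
  expect_equal(unname(f1$w), -unname(f2$w), tolerance = 1e-6)
  # squared importances sum to the feature count
  expect_equal(sum(f1$importance^2), 3, tolerance = 1e-8)
  expect_error(fitLinearSVM(Xr, yr, cost = 0), "positive")
})

test_that("duplicated feature columns split their weight equally", {
  set.seed(36)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(ifelse(X[, 1] + rnorm(40, 0, 0.8) > 0, "case", "control"),
              levels = c("control", "case"))
  Xd <- cbind(X, f1b = X[, 1])
  fd <- fitLinearSVM(Xd, y, cost = 100)
  expect_equal(unname(fd$w["f1"]), unname(fd$w["f1b"]), tolerance = 1e-10)
  # in the weak-regularization limit the split weights sum to the single fit
  f1 <- fitLinearSVM(X, y, cost = 100)
  expect_equal(unname(fd$w["f1"] + fd$w["f1b"]), unname(f1$w["f1"]),
               tolerance = 1e-3)
})

test_that("rocAuc matches the all-pairs oracle on 1000 random inputs", {
  expect_equal(rocAuc(c(0.9, 0.4, 0.8, 0.2), c("case", "case", "control",
                                               "control")), 0.75)
  expect_equal(rocAuc(c(3, 2, 1), c("case", "control", "case")), 0.5)
  expect_equal(rocAuc(rep(1, 6), rep(c("case", "control"), 3)), 0.5)
  expect_error(rocAuc(1:3, rep("case", 3)), "both classes")
  set.seed(37)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    labels <- c("case", "control",
                sample(c("case", "control"), n - 2, replace = TRUE))
    scores <- sample(seq_len(5), n, replace = TRUE) + # ties likely
      round(rnorm(n), 1)
    expect_equal(rocAuc(scores, labels), aucOracle(scores, labels))
  }
  # invariant under monotone transforms of the scores
  s <- rnorm(20); l <- rep(c("case", "control"), 10)
  expect_equal(rocAuc(s, l), rocAuc(exp(s), l))
})

test_that("classification metrics match their definitions", {
  truth <- rep(c("case", "control"), c(13, 8))
  pred <- truth
  pred[c(1, 2)] <- "control"   # 2 cases missed
  pred[c(14, 15)] <- "case"    # 2 controls missed
  m <- classificationMetrics(pred, truth)
  expect_equal(round(unname(m), 2), c(0.81, 0.85, 0.75))
  # identity: accuracy = (sens*13 + spec*8) / 21
  expect_equal(m[["accuracy"]],
               (m[["sensitivity"]] * 13 + m[["specificity"]] * 8) / 21)
  expect_equal(unname(classificationMetrics(truth, truth)), c(1, 1, 1))
  all_case <- rep("case", 21)
  m2 <- classificationMetrics(all_case, truth)
  expect_equal(unname(m2[c("sensitivity", "specificity")]), c(1, 0))
  expect_error(classificationMetrics(pred[1:3], truth), "length")
})

test_that("nested CV uses study-sized outer partitions and the 20-step grid", {
  ms <- simulateModelingSet(seed = 41)
  spec <- modelSpec("plsda", grid = 2, inner_folds = 5)
  cv <- nestedCvRank(ms, spec = spec, n_resamples = 3, seed = 41)
  expect_true(all(cv$resamples$n_train == 49))
  expect_true(all(cv$resamples$n_test == 12))
  expect_true(all(cv$resamples$subset_size %in% c(179, seq(160, 20, -20))))
  expect_equal(sort(unique(cv$vip_index$rank)), 1:179)
  # determinism
  cv2 <- nestedCvRank(ms, spec = spec, n_resamples = 3, seed = 41)
  expect_equal(cv$vip_index, cv2$vip_index)
  expect_equal(cv$resamples, cv2$resamples)
})

test_that("outer-test samples never influence the VIP ranking", {
  ms <- simulateModelingSet(n_case = 20, n_control = 14, n_features = 40,
                            n_informative = 5, seed = 42)
  X <- t(areas(ms)); y <- diagnosis(ms)
  spec <- modelSpec("plsda", grid = 2, rfe_step = 10, inner_folds = 5)
  cv1 <- nestedCvRank(X, y, spec = spec, n_resamples = 1, seed = 7)
  # reconstruct the single resample's outer-test rows and corrupt them
  set.seed(metamark:::deriveSeeds(7, 1)[1])
  tr_idx <- metamark:::classStratifiedTrainIdx(y, 0.8)
  Xn <- X
  Xn[-tr_idx, ] <- matrix(rlnorm(length(Xn[-tr_idx, ]), 10, 1),
                          nrow = nrow(Xn) - length(tr_idx))
  cv2 <- nestedCvRank(Xn, y, spec = spec, n_resamples = 1, seed = 7)
  expect_equal(cv1$vip_index, cv2$vip_index)
  expect_equal(cv1$importance, cv2$importance)
})

test_that("feature stepping covers ascending bins ending at all features", {
  ms <- simulateModelingSet(n_case = 24, n_control = 16, n_features = 50,
                            n_informative = 8, seed = 43)
  tr <- ms[, c(1:16, 25:32)]; va <- ms[, c(17:24, 33:40)]
  spec <- modelSpec("plsda", grid = 2, rfe_step = 10, inner_folds = 5)
  cv <- nestedCvRank(tr, spec = spec, n_resamples = 2, seed = 43)
  st <- featureSteppingEval(tr, valid_X = va, vip_index = cv, spec = spec,
                            seed = 43)
  expect_equal(st$n_features, c(10, 20, 30, 40, 50))
  expect_true(all(st$auc >= 0 & st$auc <= 1))
  expect_error(featureSteppingEval(tr, valid_X = tr, vip_index = cv,
                                   spec = spec), "overlap")
  # the default bin ladder for 179 features
  expect_equal(metamark:::rfeSizes(179, 20), c(179, seq(160, 20, -20)))
})

test_that("permutation runs are reproducible under a fixed seed", {
  ms <- simulateModelingSet(n_case = 20, n_control = 14, n_features = 30,
                            n_informative = 5, seed = 44)
  spec <- modelSpec("plsda", grid = 2, rfe_step = 10, inner_folds = 4)
  n1 <- permutationNull(ms, spec = spec, n_resamples = 3, seed = 9)
  n2 <- permutationNull(ms, spec = spec, n_resamples = 3, seed = 9)
  expect_equal(n1$resamples, n2$resamples)
})
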