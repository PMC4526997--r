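# Score regression, symptom classifier, metrics, and the bootstrap-LOPO
# protocol.

test_that("unpenalized least squares interpolates noiseless data", {
  withr::with_seed(1, X <- matrix(rnorm(20), ncol = 1))
  y <- 3 * X[, 1] + 1
  fit <- fit_score_regression(X, y)
  expect_equal(fit$a0, 1, tolerance = 1e-8)
  expect_equal(fit$a, 3, tolerance = 1e-8)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
})

test_that("a huge L1 penalty shrinks all slopes to zero", {
  withr::with_seed(2, {
    X <- matrix(rnorm(40), ncol = 2)
    y <- X %*% c(2, -1) + rnorm(20, 0, 0.1)
  })
  fit <- fit_score_regression(X, y, reg_config(lambda1 = 1e6))
  expect_equal(fit$a, c(0, 0))
  expect_equal(fit$a0, mean(y), tolerance = 1e-8)
})

test_that("coordinate descent matches the closed-form ridge solution", {
  withr::with_seed(3, {
    X <- matrix(rnorm(20), ncol = 2)
    y <- drop(X %*% c(1.5, -0.7)) + rnorm(10, 0, 0.3)
  })
  lambda2 <- 0.1
  # normal-equations oracle in the standardized space the model uses
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Xs <- scale(X, ctr, scl)
  bs <- solve(crossprod(Xs) + lambda2 * diag(2), crossprod(Xs, y - mean(y)))
  a_oracle <- drop(bs) / scl
  a0_oracle <- mean(y) - sum(a_oracle * ctr)
  fit <- fit_score_regression(X, y, reg_config(lambda1 = 0, lambda2 = lambda2))
  expect_equal(fit$a, unname(a_oracle), tolerance = 1e-8)
  expect_equal(fit$a0, unname(a0_oracle), tolerance = 1e-8)
})

test_that("elastic-net path agrees with the glmnet cross-check", {
  skip_if_not_installed("glmnet")
  withr::with_seed(4, {
    n <- 50
    X <- matrix(rnorm(n * 3), ncol = 3)
    y <- drop(X %*% c(2, 0, -1)) + rnorm(n, 0, 0.5)
  })
  # map objectives: ours is (1/2)RSS + l1|b| + (l2/2)|b|^2 on standardized X.
  # glmnet minimizes (1/(2n))RSS + lam(alpha|b| + (1-alpha)/2 |b|^2) after
  # internally rescaling y by its population SD, which leaves an effective
  # penalty of n*lam*alpha on |b| and n*lam*(1-alpha)/sd(y) on |b|^2/2
  l1 <- 2; l2 <- 1.5
  sy <- sqrt(mean((y - mean(y))^2))
  lam <- (l1 + l2 * sy) / n
  alpha <- l1 / (l1 + l2 * sy)
  Xs <- scale(X, colMeans(X), apply(X, 2, sd))
  g <- glmnet::glmnet(Xs, y, alpha = alpha, lambda = lam, standardize = FALSE,
                      intercept = TRUE, thresh = 1e-14)
  ours <- fit_score_regression(Xs, y, reg_config(lambda1 = l1, lambda2 = l2))
  expect_equal(ours$a, as.numeric(g$beta), tolerance = 1e-4)
})

test_that("rank-deficient unpenalized fits fail with advice", {
  X <- cbind(1:6, 2 * (1:6))
  expect_error(fit_score_regression(X, rnorm(6)), "regularization")
})

test_that("unpenalized logistic matches the IRLS (glm) oracle", {
  withr::with_seed(5, {
    X <- matrix(c(-2.1, -1.4, -0.8, -0.2, 0.3, 0.9, 1.6, 2.2), ncol = 1)
    yb <- c(0, 0, 1, 0, 1, 0, 1, 1)
  })
  fit <- fit_symptom_classifier(X, yb)
  oracle <- glm(yb ~ X, family = binomial())
  expect_equal(fit$b0, unname(coef(oracle)[1]), tolerance = 1e-6)
  expect_equal(fit$b, unname(coef(oracle)[2]), tolerance = 1e-6)

  # separable 1-D data with slight L2: perfect training accuracy
  Xs <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  ys <- c(0, 0, 0, 1, 1, 1)
  fs <- fit_symptom_classifier(Xs, ys, reg_config(lambda2 = 0.01))
  expect_equal(predict(fs, Xs), ys)

  # mirror-symmetric balanced data: intercept ~ 0
  Xm <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), ncol = 1)
  ym <- c(0, 0, 0, 1, 1, 1)
  fm <- fit_symptom_classifier(Xm, ym, reg_config(lambda2 = 0.1))
  expect_lt(abs(fm$b0), 1e-6)

  expect_error(fit_symptom_classifier(Xs, rep(1, 6)), "classes")
})

test_that("nrmsd matches its formula and scale-invariance", {
  expect_equal(nrmsd(c(1, 2, 3), c(1, 2, 3), 17), 0)
  expect_equal(nrmsd(rep(1.7, 5) + 1:5, 1:5, 17), 0.1)
  withr::with_seed(6, {
    p <- rnorm(6); t <- rnorm(6)
  })
  expect_equal(nrmsd(p, t, 4.2), sqrt(mean((p - t)^2)) / 4.2,
               tolerance = 1e-12)
  # joint affine transform with matching range rescale
  expect_equal(nrmsd(3 * p + 1, 3 * t + 1, 3 * 4.2), nrmsd(p, t, 4.2),
               tolerance = 1e-12)
  expect_true(is.na(nrmsd(numeric(), numeric(), 17)))
})

test_that("classification metrics follow the confusion table", {
  expect_equal(classification_metrics(c(1, 0, 1), c(1, 0, 1)),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  allpos <- classification_metrics(rep(1, 4), c(1, 1, 0, 0))
  expect_equal(unname(allpos), c(0.5, 1, 0))
  # TP=3 FN=1 FP=2 TN=4 -> (0.7, 0.75, 0.6667)
  truth <- c(rep(1, 4), rep(0, 6))
  pred <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- classification_metrics(pred, truth)
  expect_equal(unname(m), c(0.7, 0.75, 2 / 3), tolerance = 1e-12)
  expect_true(is.na(classification_metrics(c(1, 1), c(1, 1))["specificity"]))
  expect_error(classification_metrics(1, c(1, 0)), "mismatch")
})

test_that("B = 1 with the identity resample equals plain LOPO", {
  f <- strong_cohort_features()
  for (fs in list("normalized_entropy", c("usage_frequency", "usage_duration"))) {
    plain <- lopo_evaluate(f, fs)
    boot <- bootstrap_lopo_evaluate(f, fs, B = 1, seed = 9,
                                    resample = "identity")
    expect_equal(boot$accuracy_mean, unname(plain["accuracy"]))
    expect_equal(boot$sensitivity_mean, unname(plain["sensitivity"]))
    expect_equal(boot$specificity_mean, unname(plain["specificity"]))
    expect_equal(boot$nrmsd_mean, unname(plain["nrmsd"]))
    expect_equal(boot$accuracy_sd, 0)
    expect_equal(boot$nrmsd_sd, 0)
    expect_equal(boot$dup_leak_rate, 0)
  }
})

test_that("bootstrap evaluation is deterministic and bounded", {
  f <- strong_cohort_features()
  r1 <- bootstrap_lopo_evaluate(f, "home_stay", B = 8, seed = 31)
  r2 <- bootstrap_lopo_evaluate(f, "home_stay", B = 8, seed = 31)
  expect_identical(r1, r2)
  r3 <- bootstrap_lopo_evaluate(f, "home_stay", B = 8, seed = 32)
  expect_false(identical(r1$accuracy_mean, r3$accuracy_mean))
  for (col in c("accuracy_mean", "sensitivity_mean", "specificity_mean")) {
    expect_gte(r1[[col]], 0)
    expect_lte(r1[[col]], 1)
  }
  expect_gte(r1$nrmsd_mean, 0)
})

test_that("inner-CV tuning does not leak the held-out entry", {
  # canary: a feature that equals the outcome ONLY in the held-out row of
  # each LOPO fold (noise elsewhere) must not improve the CV metrics
  withr::with_seed(40, {
    n <- 14
    u <- runif(n)
    f <- data.frame(participant_id = sprintf("p%02d", 1:n),
                    f1 = u + rnorm(n, 0, 0.3),
                    f2 = rnorm(n), f3 = rnorm(n),
                    phq9 = as.integer(round(10 * u)))
  })
  reg <- reg_config(tune = TRUE,
                    lambda1_grid = 10^seq(-3, 1, length.out = 4),
                    lambda2_grid = 10^seq(-3, 1, length.out = 4))
  base <- lopo_evaluate(f, c("f1", "f2", "f3"), reg = reg)
  # swap f3 for the canary: per held-out row i, the training values the inner
  # CV sees are pure noise, so tuning cannot exploit the held-out equality.
  # Build it by running LOPO manually with a per-fold feature column.
  n <- nrow(f)
  preds <- numeric(n)
  withr::with_seed(41, {
    for (i in seq_len(n)) {
      canary <- rnorm(n)  # noise for training rows...
      canary[i] <- f$phq9[i]  # ...equal to the outcome only in the held-out row
      Xi <- cbind(f1 = f$f1, f2 = f$f2, f3 = canary)
      fit <- fit_score_regression(Xi[-i, , drop = FALSE], f$phq9[-i], reg)
      preds[i] <- predict(fit, Xi[i, , drop = FALSE])
    }
  })
  canary_nrmsd <- nrmsd(preds, f$phq9, diff(range(f$phq9)))
  # the canary must not beat the honest model beyond noise
  expect_gt(canary_nrmsd, unname(base["nrmsd"]) - 0.05)
})

test_that("the default policy regularizes only above two features", {
  f <- strong_cohort_features()
  ev <- evaluate_feature_sets(f, list("home_stay",
                                      c("usage_frequency", "usage_duration")),
                              B = 2, seed = 3)
  expect_s3_class(ev, "evaluation_report")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$B, c(2, 2))
})
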