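# Severity models: linear PHQ-9 score regression and logistic symptom
# classification with elastic-net regularization, plus the bootstrapped
# leave-one-participant-out evaluation protocol.
#
# Penalized objective (intercept never penalized):
#   linear:   (1/2) sum (y - b0 - X b)^2 + lambda1 ||b||_1 + (lambda2/2) ||b||_2^2
#   logistic: negative log-likelihood + the same penalty
# solved by cyclic coordinate descent (linear) and penalized IRLS whose
# weighted least-squares steps use the same coordinate descent (logistic).
# Features are standardized to zero mean / unit SD internally; returned
# coefficients are on the original scale.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

standardize_X <- function(X) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(Xs = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

# weighted elastic-net coordinate descent on standardized X
enet_cd <- function(Xs, y, w = rep(1, length(y)), lambda1 = 0, lambda2 = 0,
                    beta = rep(0, ncol(Xs)), b0 = 0,
                    tol = 1e-11, maxit = 50000L) {
  p <- ncol(Xs)
  r <- y - b0 - drop(Xs %*% beta)
  sw <- sum(w)
  wX2 <- colSums(w * Xs^2)
  for (it in seq_len(maxit)) {
    delta <- 0
    b0_new <- b0 + sum(w * r) / sw
    r <- r - (b0_new - b0)
    delta <- max(delta, abs(b0_new - b0))
    b0 <- b0_new
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      z <- sum(w * Xs[, j] * r) + wX2[j] * bj_old
      bj <- soft_threshold(z, lambda1) / (wX2[j] + lambda2)
      if (bj != bj_old) {
        r <- r - Xs[, j] * (bj - bj_old)
        beta[j] <- bj
        delta <- max(delta, abs(bj - bj_old))
      }
    }
    if (delta < tol) break
  }
  list(b0 = b0, beta = beta, iters = it)
}

#' Regularization settings for the severity models
#'
#' @param lambda1,lambda2 L1 and L2 penalty weights (used when `tune` is
#'   `FALSE`).
#' @param tune If `TRUE`, pick `(lambda1, lambda2)` from the grids by
#'   `folds`-fold cross-validation on the training data.
#' @param lambda1_grid,lambda2_grid Candidate grids; default 10 log-spaced
#'   points over \[1e-4, 1e2\] (0 is implicitly considered through small
#'   values).
#' @param folds Inner-CV folds (default 5).
#' @return List of class `reg_config`.
#' @export
reg_config <- function(lambda1 = 0, lambda2 = 0, tune = FALSE,
                       lambda1_grid = 10^seq(-4, 2, length.out = 10),
                       lambda2_grid = 10^seq(-4, 2, length.out = 10),
                       folds = 5) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, folds >= 2)
  if (tune) stopifnot(length(lambda1_grid) > 0, length(lambda2_grid) > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, tune = tune,
                 lambda1_grid = lambda1_grid, lambda2_grid = lambda2_grid,
                 folds = folds), class = "reg_config")
}

# deterministic fold assignment (round-robin over a seeded permutation)
make_folds <- function(n, k, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  ord <- sample.int(n)
  folds <- rep(seq_len(k), length.out = n)
  folds[ord]
}

tune_lambdas <- function(X, y, reg, family, seed = 7L) {
  # inner CV only ranks the lambda grid, so the per-candidate fits run at a
  # relaxed tolerance; the final model is refit tightly afterwards
  n <- nrow(X)
  k <- min(reg$folds, n)
  fold <- make_folds(n, k, seed)
  grid <- expand.grid(l1 = reg$lambda1_grid, l2 = reg$lambda2_grid)
  cv_err <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- fold != f; te <- !tr
      if (family == "gaussian") {
        fit <- fit_score_regression(X[tr, , drop = FALSE], y[tr],
                                    reg_config(grid$l1[g], grid$l2[g]),
                                    tol = 1e-6, maxit = 1000L)
        mean((predict(fit, X[te, , drop = FALSE]) - y[te])^2)
      } else {
        if (length(unique(y[tr])) < 2) return(NA_real_)
        fit <- fit_symptom_classifier(X[tr, , drop = FALSE], y[tr],
                                      reg_config(grid$l1[g], grid$l2[g]),
                                      maxit = 25L, tol = 1e-7,
                                      cd_tol = 1e-6, cd_maxit = 500L)
        pr <- clamp(predict(fit, X[te, , drop = FALSE], type = "prob"),
                    1e-12, 1 - 1e-12)
        -mean(y[te] * log(pr) + (1 - y[te]) * log(1 - pr))
      }
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- which.min(cv_err)
  list(lambda1 = grid$l1[best], lambda2 = grid$l2[best])
}

#' Fit the linear PHQ-9 score-estimation model
#'
#' `score = a0 + a1 F1 + ... + an Fn`, fit by least squares, with an optional
#' elastic-net penalty `lambda1 ||a||_1 + (lambda2/2) ||a||_2^2` on the slopes
#' (the intercept is never penalized). With `tune = TRUE` the penalty weights
#' are chosen by inner cross-validation on the training data only.
#'
#' @param X Feature matrix or data frame (rows = participants).
#' @param y Numeric PHQ-9 scores.
#' @param reg A [reg_config()].
#' @param tol,maxit Coordinate-descent convergence tolerance and iteration
#'   cap for penalized fits.
#' @return Object of class `score_model` with `a0`, `a` (original-scale
#'   coefficients), and the lambdas used.
#' @export
fit_score_regression <- function(X, y, reg = reg_config(), tol = 1e-11,
                                 maxit = 50000L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 3)
  if (reg$tune) {
    lam <- tune_lambdas(X, y, reg, "gaussian")
    reg <- reg_config(lam$lambda1, lam$lambda2)
  }
  if (reg$lambda1 == 0 && reg$lambda2 == 0) {
    Xf <- cbind(1, X)
    qr_ <- qr(Xf)
    if (qr_$rank < ncol(Xf))
      stop("rank-deficient unpenalized fit; enable regularization ",
           "(reg_config(tune = TRUE) or nonzero lambdas)")
    cf <- qr.coef(qr_, y)
    return(structure(list(a0 = unname(cf[1]), a = unname(cf[-1]),
                          lambda1 = 0, lambda2 = 0,
                          features = colnames(X)), class = "score_model"))
  }
  std <- standardize_X(X)
  fit <- enet_cd(std$Xs, y - mean(y), lambda1 = reg$lambda1,
                 lambda2 = reg$lambda2, tol = tol, maxit = maxit)
  a <- fit$beta / std$scale
  a0 <- mean(y) + fit$b0 - sum(a * std$center)
  structure(list(a0 = a0, a = unname(a), lambda1 = reg$lambda1,
                 lambda2 = reg$lambda2, features = colnames(X)),
            class = "score_model")
}

#' @export
predict.score_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  drop(object$a0 + X %*% object$a)
}

#' Fit the logistic symptom classifier
#'
#' `P(symptoms) = sigmoid(b0 + b1 F1 + ... + bn Fn)`, fit by penalized
#' maximum likelihood (IRLS whose weighted least-squares steps run the same
#' elastic-net coordinate descent as the linear model). A participant is
#' classified as symptomatic when the predicted probability exceeds 0.5.
#'
#' @param X Feature matrix or data frame.
#' @param labels 0/1 vector (1 = has depressive symptoms, PHQ-9 >= cutoff).
#' @param reg A [reg_config()].
#' @param maxit,tol IRLS iteration cap and deviance convergence tolerance.
#' @param cd_tol,cd_maxit Convergence controls for the inner coordinate
#'   descent of each IRLS step.
#' @return Object of class `symptom_model` with `b0`, `b`, `threshold`.
#' @export
fit_symptom_classifier <- function(X, labels, reg = reg_config(),
                                   maxit = 100L, tol = 1e-10,
                                   cd_tol = 1e-11, cd_maxit = 10000L) {
  X <- as.matrix(X)
  labels <- as.numeric(labels)
  stopifnot(nrow(X) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2)
    stop("both classes must be present in the training data")
  if (reg$tune) {
    lam <- tune_lambdas(X, labels, reg, "binomial")
    reg <- reg_config(lam$lambda1, lam$lambda2)
  }
  std <- standardize_X(X)
  p <- ncol(X)
  beta <- rep(0, p); b0 <- log(mean(labels) / (1 - mean(labels)))
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- b0 + drop(std$Xs %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- clamp(mu, 1e-10, 1 - 1e-10)
    w <- mu * (1 - mu)
    z <- eta + (labels - mu) / w
    if (reg$lambda1 == 0) {
      # no L1 term: the weighted least-squares step has an exact solution;
      # a vanishing ridge keeps degenerate designs (constant or duplicated
      # columns in a bootstrap fold) solvable without noticeably perturbing
      # the regular case
      A <- cbind(1, std$Xs)
      rhs <- crossprod(A, w * z)
      M <- crossprod(A, w * A) + diag(c(0, rep(reg$lambda2, p)))
      cf <- tryCatch(drop(solve(M, rhs)), error = function(e)
        drop(solve(M + diag(c(0, rep(1e-8, p))), rhs)))
      b0 <- cf[1]; beta <- cf[-1]
    } else {
      fit <- enet_cd(std$Xs, z, w = w, lambda1 = reg$lambda1,
                     lambda2 = reg$lambda2, beta = beta, b0 = b0,
                     tol = cd_tol, maxit = cd_maxit)
      beta <- fit$beta; b0 <- fit$b0
    }
    dev <- -2 * sum(labels * log(mu) + (1 - labels) * log(1 - mu))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  b <- beta / std$scale
  structure(list(b0 = b0 - sum(b * std$center), b = unname(b),
                 threshold = 0.5, lambda1 = reg$lambda1,
                 lambda2 = reg$lambda2, features = colnames(X),
                 iters = it), class = "symptom_model")
}

#' @export
#' @rdname fit_symptom_classifier
#' @param object A `symptom_model`.
#' @param newdata Feature matrix/data frame to predict.
#' @param type `"prob"` for P(symptoms), `"label"` for the 0/1 decision.
#' @param ... Unused.
predict.symptom_model <- function(object, newdata, type = c("label", "prob"),
                                  ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  pr <- 1 / (1 + exp(-(object$b0 + drop(X %*% object$b))))
  if (type == "prob") pr else as.integer(pr > object$threshold)
}

#' Normalized root-mean-square deviation
#'
#' RMSD between predicted and true scores, divided by the observed score
#' range (the study convention: the observed PHQ-9 range, e.g. 0-17).
#'
#' @param pred,truth Equal-length numeric vectors.
#' @param range Normalizing range (> 0).
#' @return Nonnegative scalar (`NA` for empty input).
#' @export
nrmsd <- function(pred, truth, range) {
  stopifnot(length(pred) == length(truth), range > 0)
  if (length(pred) == 0) return(NA_real_)
  sqrt(mean((pred - truth)^2)) / range
}

#' Confusion-matrix rates for the symptom classifier
#'
#' Positive class = has depressive symptoms. A rate whose reference class is
#' absent is `NA`.
#'
#' @param pred_labels,true_labels 0/1 vectors of equal length.
#' @return Named vector: `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels))
    stop("prediction/truth length mismatch")
  stopifnot(length(true_labels) > 0)
  pos <- true_labels == 1
  c(accuracy = mean(pred_labels == true_labels),
    sensitivity = if (any(pos)) mean(pred_labels[pos] == 1) else NA_real_,
    specificity = if (any(!pos)) mean(pred_labels[!pos] == 0) else NA_real_)
}

# leave-one-entry-out CV over the rows of X; returns pooled predictions
lopo_predictions <- function(X, scores, labels, reg_lin, reg_clf) {
  n <- nrow(X)
  pred_score <- rep(NA_real_, n)
  pred_label <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    # a bootstrap-duplicated training fold can be rank-deficient (e.g. a
    # constant feature column); fall back to a vanishing ridge penalty
    fit_r <- tryCatch(
      fit_score_regression(X[tr, , drop = FALSE], scores[tr], reg_lin),
      error = function(e)
        fit_score_regression(X[tr, , drop = FALSE], scores[tr],
                             reg_config(lambda2 = 1e-8)))
    pred_score[i] <- predict(fit_r, X[i, , drop = FALSE])
    if (length(unique(labels[tr])) < 2) {
      pred_label[i] <- as.integer(round(mean(labels[tr])))
    } else {
      fit_c <- fit_symptom_classifier(X[tr, , drop = FALSE], labels[tr],
                                      reg_clf)
      pred_label[i] <- predict(fit_c, X[i, , drop = FALSE])
    }
  }
  list(score = pred_score, label = pred_label)
}

#' Plain leave-one-participant-out evaluation
#'
#' For each entry: fit the score regression and symptom classifier on all
#' other entries, predict the held-out one; pool the held-out predictions and
#' compute accuracy/sensitivity/specificity and NRMSD.
#'
#' @param features Feature table including a `phq9` column.
#' @param feature_set Character vector of feature column names to use.
#' @param reg A [reg_config()], or `NULL` for the default policy:
#'   cross-validated elastic net when more than two features are used, plain
#'   least squares / maximum likelihood otherwise.
#' @param cutoff PHQ-9 symptom cutoff (default 5).
#' @param nrmsd_range Normalizing range for NRMSD; defaults to the observed
#'   score range of `features$phq9`.
#' @return Named vector: accuracy, sensitivity, specificity, nrmsd.
#' @export
lopo_evaluate <- function(features, feature_set, reg = NULL, cutoff = 5,
                          nrmsd_range = NULL) {
  dat <- complete_feature_rows(features, feature_set)
  if (is.null(reg)) reg <- default_reg_policy(length(feature_set))
  if (is.null(nrmsd_range)) nrmsd_range <- diff(range(dat$scores))
  pred <- lopo_predictions(dat$X, dat$scores, dat$labels(cutoff), reg, reg)
  c(classification_metrics(pred$label, dat$labels(cutoff)),
    nrmsd = nrmsd(pred$score, dat$scores, nrmsd_range))
}

default_reg_policy <- function(n_features) {
  if (n_features > 2) reg_config(tune = TRUE) else reg_config()
}

complete_feature_rows <- function(features, feature_set) {
  stopifnot(all(feature_set %in% names(features)), "phq9" %in% names(features))
  X <- as.matrix(features[feature_set])
  ok <- stats::complete.cases(X) & is.finite(features$phq9)
  X <- X[ok, , drop = FALSE]
  scores <- features$phq9[ok]
  list(X = X, scores = scores,
       labels = function(cutoff) as.integer(scores >= cutoff),
       ids = features$participant_id[ok])
}

#' Bootstrapped leave-one-participant-out evaluation
#'
#' The study protocol: draw `B` bootstrap resamples of participants (with
#' replacement), run leave-one-entry-out cross-validation inside each
#' resample, pool the held-out predictions, and report the mean and SD across
#' resamples of accuracy, sensitivity, specificity, and NRMSD. Resamples with
#' fewer than two entries of either symptom class are redrawn (and counted).
#' Because duplicated participants can appear on both sides of a
#' leave-one-entry-out split, the report also carries the average fraction of
#' held-out entries whose participant is duplicated into the training side
#' (`dup_leak_rate`), so the resulting optimism can be quantified.
#'
#' @inheritParams lopo_evaluate
#' @param B Number of bootstrap resamples (study default 1000).
#' @param seed Integer seed; the whole evaluation is deterministic given it.
#' @param resample `"bootstrap"` for sampling with replacement,
#'   `"identity"` to reuse the original cohort in every resample (so `B = 1`
#'   reduces to plain leave-one-participant-out).
#' @param unique_participants If `TRUE`, duplicated participants in a
#'   resample are collapsed to one entry before cross-validation (unit-level
#'   hold-out instead of entry-level).
#' @return One-row data frame of class `evaluation_report`: feature set, B,
#'   mean/SD of each metric, redraw count, duplicate-leak rate.
#' @export
bootstrap_lopo_evaluate <- function(features, feature_set, B = 1000,
                                    reg = NULL, seed = 1L, cutoff = 5,
                                    resample = c("bootstrap", "identity"),
                                    unique_participants = FALSE,
                                    nrmsd_range = NULL) {
  resample <- match.arg(resample)
  dat <- complete_feature_rows(features, feature_set)
  n <- nrow(dat$X)
  stopifnot(n >= 4)
  labels <- dat$labels(cutoff)
  if (length(unique(labels)) < 2)
    stop("both symptom classes must be present in the cohort")
  if (is.null(reg)) reg <- default_reg_policy(length(feature_set))
  if (is.null(nrmsd_range)) nrmsd_range <- diff(range(dat$scores))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  metrics <- matrix(NA_real_, B, 4,
                    dimnames = list(NULL, c("accuracy", "sensitivity",
                                            "specificity", "nrmsd")))
  n_redrawn <- 0L
  leak <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- if (resample == "identity") seq_len(n) else
        sample.int(n, n, replace = TRUE)
      if (unique_participants) idx <- unique(idx)
      lb <- labels[idx]
      if (sum(lb == 1) >= 2 && sum(lb == 0) >= 2 &&
          diff(range(dat$scores[idx])) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    leak[b] <- mean(duplicated(idx) | duplicated(idx, fromLast = TRUE))
    pred <- lopo_predictions(dat$X[idx, , drop = FALSE], dat$scores[idx],
                             labels[idx], reg, reg)
    metrics[b, 1:3] <- classification_metrics(pred$label, labels[idx])
    metrics[b, 4] <- nrmsd(pred$score, dat$scores[idx], nrmsd_range)
  }
  mu <- colMeans(metrics)
  sdv <- apply(metrics, 2, stats::sd)
  sdv[!is.finite(sdv)] <- 0
  if (B == 1) sdv[] <- 0
  out <- data.frame(feature_set = paste(feature_set, collapse = "+"),
                    n = n, B = B,
                    accuracy_mean = mu[1], accuracy_sd = sdv[1],
                    sensitivity_mean = mu[2], sensitivity_sd = sdv[2],
                    specificity_mean = mu[3], specificity_sd = sdv[3],
                    nrmsd_mean = mu[4], nrmsd_sd = sdv[4],
                    n_redrawn = n_redrawn, dup_leak_rate = mean(leak))
  rownames(out) <- NULL
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Evaluate several feature sets into a table
#'
#' Produces the familiar per-feature-set report: one row per feature set,
#' mean (SD) accuracy, sensitivity, specificity, and NRMSD across
#' bootstrapped leave-one-participant-out runs.
#'
#' @inheritParams bootstrap_lopo_evaluate
#' @param feature_sets List of character vectors (each one feature set); a
#'   single character vector is treated as one set per feature.
#' @return `evaluation_report` data frame, one row per feature set.
#' @export
evaluate_feature_sets <- function(features, feature_sets, B = 1000,
                                  reg = NULL, seed = 1L, cutoff = 5,
                                  nrmsd_range = NULL) {
  if (is.character(feature_sets)) feature_sets <- as.list(feature_sets)
  rows <- lapply(seq_along(feature_sets), function(i)
    bootstrap_lopo_evaluate(features, feature_sets[[i]], B = B, reg = reg,
                            seed = seed + i - 1L, cutoff = cutoff,
                            nrmsd_range = nrmsd_range))
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Bootstrapped leave-one-participant-out evaluation (B = %d)\n",
              x$B[1]))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-45s acc %5.1f%% (%4.1f)  sens %5.1f%%  spec %5.1f%%  NRMSD %.3f (%.3f)\n",
                x$feature_set[i], 100 * x$accuracy_mean[i],
                100 * x$accuracy_sd[i], 100 * x$sensitivity_mean[i],
                100 * x$specificity_mean[i], x$nrmsd_mean[i], x$nrmsd_sd[i]))
  }
  invisible(x)
}
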