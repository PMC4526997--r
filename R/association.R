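# Descriptive inference: feature-score correlations, symptom-cutoff group
# comparisons, feature-feature correlation matrix.

#' Pearson correlation with a two-sided p-value
#'
#' Pairwise-complete: rows where either value is `NA` are dropped. The
#' p-value comes from the t transform with n - 2 degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length.
#' @param name Label carried into the result.
#' @return One-row data frame: `feature`, `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y, name = "feature") {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(data.frame(feature = name, r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  data.frame(feature = name, r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Split scores at the PHQ-9 symptom cutoff
#'
#' @param scores Numeric PHQ-9 scores.
#' @param cutoff Cutoff (default 5): `lo` holds scores strictly below, `hi`
#'   scores at or above (at least mild symptoms).
#' @return List with elements `lo` and `hi`.
#' @export
split_by_cutoff <- function(scores, cutoff = 5) {
  list(lo = scores[scores < cutoff], hi = scores[scores >= cutoff])
}

#' Two-sample comparison of a feature across symptom groups
#'
#' Welch (unequal-variance) two-sided t-test by default; set
#' `var_equal = TRUE` for the pooled-variance variant.
#'
#' @param lo,hi Feature values in the below-cutoff and at-or-above-cutoff
#'   groups.
#' @param name Label carried into the result.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return One-row data frame: `feature`, `t`, `p`, group means and SDs and
#'   sizes. `NA` statistics if either group has fewer than 2 non-missing
#'   values.
#' @export
group_ttest <- function(lo, hi, name = "feature", var_equal = FALSE) {
  lo <- lo[is.finite(lo)]; hi <- hi[is.finite(hi)]
  base <- data.frame(feature = name, t = NA_real_, p = NA_real_,
                     mean_lo = mean(lo), sd_lo = stats::sd(lo),
                     mean_hi = mean(hi), sd_hi = stats::sd(hi),
                     n_lo = length(lo), n_hi = length(hi))
  if (length(lo) < 2 || length(hi) < 2) return(base)
  tt <- tryCatch(stats::t.test(hi, lo, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt)) return(base)
  base$t <- unname(tt$statistic)
  base$p <- tt$p.value
  base
}

#' Pairwise feature correlation matrix
#'
#' Pearson correlations between all feature columns with pairwise-complete
#' missing-value handling; unit diagonal.
#'
#' @param features Data frame of feature columns (non-numeric columns are
#'   dropped).
#' @return List with matrices `r`, `p`, `n` (symmetric, dimnames = feature
#'   names).
#' @export
feature_correlation_matrix <- function(features) {
  num <- features[vapply(features, is.numeric, TRUE)]
  num <- num[setdiff(names(num), "phq9")]
  k <- ncol(num)
  stopifnot(k >= 1)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(names(num), names(num)))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    n[i, i] <- sum(is.finite(num[[i]]))
    p[i, i] <- 0
    for (j in seq_len(k)) {
      if (j <= i) next
      res <- pearson_with_p(num[[i]], num[[j]])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
      n[i, j] <- n[j, i] <- res$n
    }
  }
  list(r = r, p = p, n = n)
}

#' Feature-score association table
#'
#' For every feature column: Pearson correlation with the PHQ-9 score, and a
#' Welch t-test comparing participants at or above the symptom cutoff with
#' those below. No multiple-comparison correction is applied (the analysis
#' is descriptive; see the methods vignette).
#'
#' @param features Feature table with a `phq9` column (as produced by
#'   [extract_features_cohort()]).
#' @param cutoff Symptom cutoff (default 5).
#' @param var_equal Passed to [group_ttest()].
#' @return Data frame with one row per feature: `feature`, `r`, `p_cor`, `n`,
#'   `t`, `p_t`, group means/SDs/sizes.
#' @export
associate_features <- function(features, cutoff = 5, var_equal = FALSE) {
  stopifnot("phq9" %in% names(features))
  fn <- intersect(feature_names(), names(features))
  rows <- lapply(fn, function(nm) {
    cr <- pearson_with_p(features[[nm]], features$phq9, name = nm)
    grp_hi <- features[[nm]][features$phq9 >= cutoff]
    grp_lo <- features[[nm]][features$phq9 < cutoff]
    tt <- group_ttest(grp_lo, grp_hi, name = nm, var_equal = var_equal)
    data.frame(feature = nm, r = cr$r, p_cor = cr$p, n = cr$n,
               t = tt$t, p_t = tt$p, mean_lo = tt$mean_lo, sd_lo = tt$sd_lo,
               mean_hi = tt$mean_hi, sd_hi = tt$sd_hi,
               n_lo = tt$n_lo, n_hi = tt$n_hi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
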