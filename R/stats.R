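#' Lin's concordance correlation coefficient
#'
#' Agreement between two readers' measurements of the same quantity:
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2), with population
#' (1/n) moments. Unlike the Pearson correlation, CCC is penalized by
#' location and scale shifts, so |CCC| <= |r| always. The qualitative band
#' is good (> 0.75), moderate (0.40 to 0.75, boundary 0.40 included) or
#' poor (< 0.40).
#'
#' @param x,y Paired measurements (length >= 3, finite).
#' @return List with `ccc` and `band`. When both inputs are constant and
#'   equal the coefficient is undefined and reported as NA.
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))$ccc  # 4/7
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stopf("x and y must have equal length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("values must be finite")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    return(list(ccc = NA_real_, band = NA_character_))
  ccc <- 2 * sxy / denom
  list(ccc = ccc, band = ccc_band(ccc))
}

ccc_band <- function(ccc) {
  if (is.na(ccc)) NA_character_
  else if (ccc > 0.75) "good"
  else if (ccc >= 0.40) "moderate"
  else "poor"
}

#' Unpaired two-tailed Student's t test
#'
#' Pooled-variance two-sample t test (the classic SPSS default); Welch's
#' unequal-variance variant is available behind `var_equal = FALSE`.
#'
#' @param x,y Values in the two groups, each n >= 2.
#' @param var_equal Pool the variances (default TRUE).
#' @return List with `t`, `p` and `degenerate` (TRUE when the pooled
#'   variance is zero; then t = 0, p = 1 for equal means and t = Inf,
#'   p = 0 otherwise).
#' @export
two_group_t <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else Inf, p = if (eq) 1 else 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' Chi-square test with automatic Fisher fallback
#'
#' Pearson chi-square test (without continuity correction) on a 2 x k
#' contingency table of counts, falling back to Fisher's exact test when
#' any expected cell count is below 5.
#'
#' @param tab Matrix of non-negative integer counts, 2 rows.
#' @return List with `p`, `method` ("chisq" or "fisher") and `statistic`
#'   (chi-square statistic; NA for Fisher).
#' @export
categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2) stopf("expected a 2 x k table")
  if (!is_count(tab) || any(tab < 0)) stopf("counts must be non-negative integers")
  if (sum(tab) == 0) stopf("all-zero table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(p = stats::fisher.test(tab)$p.value, method = "fisher",
         statistic = NA_real_)
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    list(p = ct$p.value, method = "chisq", statistic = unname(ct$statistic))
  }
}

# Orient values so that larger score predicts the positive class.
orient_scores <- function(values, positive_mask, direction) {
  if (direction == "auto") {
    a_higher <- rank_auc(values[positive_mask], values[!positive_mask])
    direction <- if (a_higher >= 0.5) "higher" else "lower"
  }
  list(scores = if (direction == "lower") -values else values,
       direction = direction)
}

# AUC of scores (higher = positive) via midranks: the Mann-Whitney
# U-statistic / (n1 n2), identical to the trapezoidal area under the
# empirical ROC. O(n log n), safe for very large cohorts.
rank_auc <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components by the midrank method.
# V10[i] = P(pos_i > neg) + 0.5 P(pos_i = neg), V01 analogous.
delong_components <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

delong_var <- function(comp) {
  m <- length(comp$v10); n <- length(comp$v01)
  stats::var(comp$v10) / m + stats::var(comp$v01) / n
}

#' Empirical ROC analysis with Youden-optimal cutoff
#'
#' Builds the empirical ROC of a continuous imaging parameter against a
#' binary responder label. The AUC is the trapezoidal area, computed as
#' the Mann-Whitney U-statistic (ties counted 1/2). The reported cutoff
#' maximizes Youden's J = sensitivity + specificity - 1 over all
#' thresholds midway between adjacent distinct observed values; ties in J
#' are broken toward higher sensitivity, then toward the lower threshold.
#' The predictor orientation ("lower" or "higher" value predicts the
#' positive class) can be fixed or chosen automatically so that
#' AUC >= 0.5. The 95% CI uses the DeLong variance with a normal
#' approximation, clamped to [0, 1].
#'
#' @param values Parameter values, one per patient.
#' @param labels Group labels, one per patient.
#' @param positive Level of `labels` regarded as positive (default
#'   `"responder"`).
#' @param direction `"auto"`, `"lower"` or `"higher"`: which direction of
#'   `values` predicts the positive class.
#' @return List with `auc`, `ci95`, `cutoff`, `sensitivity`,
#'   `specificity`, `orientation` and `youden`. With a single distinct
#'   value the AUC is 0.5 and the cutoff undefined (NA).
#' @export
roc_analysis <- function(values, labels, positive = "responder",
                         direction = c("auto", "lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(labels))
  pos_mask <- labels == positive
  if (!any(pos_mask) || all(pos_mask)) stopf("both groups must be non-empty")
  if (any(!is.finite(values))) stopf("values must be finite")
  if (length(unique(values)) == 1) {
    return(list(auc = 0.5, ci95 = c(NA_real_, NA_real_), cutoff = NA_real_,
                sensitivity = NA_real_, specificity = NA_real_,
                orientation = if (direction == "auto") "lower" else direction,
                youden = NA_real_))
  }
  or <- orient_scores(values, pos_mask, direction)
  pos <- or$scores[pos_mask]; neg <- or$scores[!pos_mask]
  comp <- delong_components(pos, neg)
  auc <- comp$auc
  se <- sqrt(max(delong_var(comp), 0))
  ci <- clamp(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0, 1)

  # candidate thresholds: midpoints between adjacent distinct values,
  # on the original parameter scale
  u <- sort(unique(values))
  cand <- (u[-1] + u[-length(u)]) / 2
  test_pos <- if (or$direction == "lower") {
    function(c) list(sens = mean(values[pos_mask] <= c),
                     spec = mean(values[!pos_mask] > c))
  } else {
    function(c) list(sens = mean(values[pos_mask] >= c),
                     spec = mean(values[!pos_mask] < c))
  }
  perf <- vapply(cand, function(c) {
    p <- test_pos(c); c(p$sens, p$spec)
  }, numeric(2))
  j <- perf[1, ] + perf[2, ] - 1
  best <- which(j == max(j))
  if (length(best) > 1) {
    best <- best[perf[1, best] == max(perf[1, best])]  # higher sensitivity
    best <- best[which.min(cand[best])]                # then lower threshold
  }
  list(auc = auc, ci95 = ci, cutoff = cand[best],
       sensitivity = perf[1, best], specificity = perf[2, best],
       orientation = or$direction, youden = j[best])
}

#' Paired DeLong test comparing two AUCs
#'
#' Compares the AUCs of two imaging parameters measured on the same
#' patients using the DeLong covariance of the structural components
#' (two-tailed z test). A paired-bootstrap alternative is available.
#'
#' @param values_a,values_b Two predictors on the same patients.
#' @param labels Shared group labels.
#' @param positive Positive class (default `"responder"`).
#' @param direction_a,direction_b Orientation of each predictor (see
#'   [roc_analysis()]).
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap resamples and RNG seed (bootstrap only).
#' @return List with `auc_a`, `auc_b`, `z`, `p` and `method`.
#' @export
compare_auc <- function(values_a, values_b, labels, positive = "responder",
                        direction_a = "auto", direction_b = "auto",
                        method = c("delong", "bootstrap"),
                        n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  if (length(values_a) != length(labels) || length(values_b) != length(labels))
    stopf("both predictors must cover the same patients")
  pos_mask <- labels == positive
  if (!any(pos_mask) || all(pos_mask)) stopf("both groups must be non-empty")
  sa <- orient_scores(values_a, pos_mask, direction_a)$scores
  sb <- orient_scores(values_b, pos_mask, direction_b)$scores
  ca <- delong_components(sa[pos_mask], sa[!pos_mask])
  cb <- delong_components(sb[pos_mask], sb[!pos_mask])
  d_auc <- ca$auc - cb$auc
  if (method == "delong") {
    m <- sum(pos_mask); n <- sum(!pos_mask)
    cov_ab <- stats::cov(ca$v10, cb$v10) / m + stats::cov(ca$v01, cb$v01) / n
    v <- delong_var(ca) + delong_var(cb) - 2 * cov_ab
    if (v <= .Machine$double.eps) {
      z <- if (abs(d_auc) < sqrt(.Machine$double.eps)) 0 else sign(d_auc) * Inf
    } else z <- d_auc / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    set.seed(seed)
    idx_pos <- which(pos_mask); idx_neg <- which(!pos_mask)
    diffs <- replicate(n_boot, {
      ip <- sample(idx_pos, replace = TRUE)
      ineg <- sample(idx_neg, replace = TRUE)
      rank_auc(sa[ip], sa[ineg]) - rank_auc(sb[ip], sb[ineg])
    })
    se <- stats::sd(diffs)
    z <- if (se == 0) 0 else d_auc / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, z = z, p = p, method = method)
}

#' Closed-form AUC of two normal populations
#'
#' For values distributed N(mean1, sd1^2) in one group and N(mean2, sd2^2)
#' in the other, the AUC of the better-oriented ROC is
#' Phi(|mean1 - mean2| / sqrt(sd1^2 + sd2^2)). Used as an analytic oracle
#' for [roc_analysis()] on large simulated cohorts.
#'
#' @param mean1,sd1 Moments of group 1 (sd > 0).
#' @param mean2,sd2 Moments of group 2 (sd > 0).
#' @return The AUC.
#' @export
binormal_auc <- function(mean1, sd1, mean2, sd2) {
  stopifnot(sd1 > 0, sd2 > 0)
  stats::pnorm(abs(mean1 - mean2) / sqrt(sd1^2 + sd2^2))
}
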