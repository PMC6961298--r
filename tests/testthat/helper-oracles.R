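# Independent oracles used to check the package's own implementations,
# plus a lazily-built default simulated study shared across test files.

# brute-force pairwise AUC: U / (n1 n2) with ties counted one half
pairwise_auc_oracle <- function(pos, neg) {
  u <- 0
  for (p in pos) for (n in neg) u <- u + (p > n) + 0.5 * (p == n)
  u / (length(pos) * length(neg))
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum of the probabilities of all tables (fixed margins) no more likely
# than the observed one
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Lin's CCC straight from the definition with population moments
ccc_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# DeLong paired AUC-difference p-value by explicit double loops
delong_paired_oracle <- function(score_a, score_b, is_pos) {
  comp <- function(s) {
    pos <- s[is_pos]; neg <- s[!is_pos]
    m <- length(pos); n <- length(neg)
    v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                  numeric(1))
    v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                  numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
  }
  a <- comp(score_a); b <- comp(score_b)
  v <- stats::var(a$v10) / a$m + stats::var(a$v01) / a$n +
       stats::var(b$v10) / b$m + stats::var(b$v01) / b$n -
       2 * (stats::cov(a$v10, b$v10) / a$m + stats::cov(a$v01, b$v01) / a$n)
  z <- (a$auc - b$auc) / sqrt(v)
  list(auc_a = a$auc, auc_b = b$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# log-scale SSE grid search for the mono-exponential fit
mono_grid_oracle <- function(values, b, adc_grid, lns0_grid) {
  best <- c(NA, NA, Inf)
  for (a in adc_grid) for (l in lns0_grid) {
    sse <- sum((log(values) - (l - b * a))^2)
    # ties broken toward the smaller parameter value
    if (sse < best[3] - 1e-15) best <- c(a, l, sse)
  }
  list(adc = best[1], lns0 = best[2], sse = best[3])
}

# worked-example parameter sets (reporting scale) used across tests
worked_examples <- function() {
  list(
    mono = list(responder = c(adc = 0.619), nonresponder = c(adc = 0.993)),
    sem = list(responder = c(ddc = 0.972, alpha = 0.910),
               nonresponder = c(ddc = 1.237, alpha = 0.621)),
    ivim = list(responder = c(d = 0.608, d_star = 6.891, f = 25.318),
                nonresponder = c(d = 0.876, d_star = 8.820, f = 32.356)))
}

# the default simulated study is expensive enough to share: build once
.study_cache <- new.env(parent = emptyenv())
get_default_study <- function(seed = 1234) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- run_study(seed = seed)
  .study_cache[[key]]
}
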