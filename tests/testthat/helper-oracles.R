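# Independent oracles, coded straightforwardly and separately from the
# package implementations they check.

# Simple Good-Turing (Gale-Sampson, linear smoothing of log Z vs log r),
# plain loops.
sgt_oracle <- function(counts) {
  n_total <- sum(counts)
  r_vals <- sort(unique(counts[counts > 0]))
  nr <- vapply(r_vals, function(r) sum(counts == r), numeric(1))
  k <- length(r_vals)
  z <- numeric(k)
  for (idx in seq_len(k)) {
    q <- if (idx == 1) 0 else r_vals[idx - 1]
    t <- if (idx == k) 2 * r_vals[k] - r_vals[k - 1] else r_vals[idx + 1]
    z[idx] <- nr[idx] / (0.5 * (t - q))
  }
  fit <- lm(log(z) ~ log(r_vals))
  a <- coef(fit)[[1]]
  b <- coef(fit)[[2]]
  s_fun <- function(r) exp(a + b * log(r))
  r_star <- vapply(r_vals, function(r) (r + 1) * s_fun(r + 1) / s_fun(r),
                   numeric(1))
  p0 <- sum(counts == 1) / n_total
  denom <- sum(nr * r_star)
  p <- numeric(length(counts))
  for (i in seq_along(counts)) {
    if (counts[i] > 0) {
      p[i] <- (1 - p0) * r_star[match(counts[i], r_vals)] / denom
    }
  }
  n_zero <- sum(counts == 0)
  if (n_zero > 0) p[counts == 0] <- p0 / n_zero
  p / sum(p)
}

# All count vectors of length n_feat summing to total.
enumerate_count_vectors <- function(n_feat, total) {
  if (n_feat == 1) return(matrix(total, ncol = 1))
  out <- NULL
  for (x1 in 0:total) {
    rest <- enumerate_count_vectors(n_feat - 1, total - x1)
    out <- rbind(out, cbind(x1, rest))
  }
  unname(out)
}

# Benjamini-Hochberg step-up, coded directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(ps[i:m] * m / seq(i, m)))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Crossing of two weighted Gaussian densities, solved in closed form
# (quadratic in x); returns the root inside (m1, m2).
gaussian_crossing_oracle <- function(w1, m1, s1, w2, m2, s2) {
  k <- log(w1 / w2) + log(s2 / s1)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + k
  roots <- Re(polyroot(c(cc, b, a)))
  roots[roots > m1 & roots < m2][1]
}
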