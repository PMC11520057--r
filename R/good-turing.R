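#' Simple Good-Turing proportion estimates
#'
#' Gale-Sampson Simple Good-Turing estimation of per-feature proportions from
#' a vector of summed counts, using linear smoothing of log Z_r against log r
#' (Z_r being the frequency-of-frequencies N_r spread over the gap to the
#' neighbouring observed counts). The total unseen mass n1/N is shared
#' uniformly over zero-count features; if no feature has count zero the unseen
#' mass is renormalized away. The returned proportions always sum to 1.
#'
#' When the estimate is not identifiable (fewer than two distinct positive
#' counts, or no singletons so the unseen mass is zero by construction), the
#' function falls back to add-pseudocount proportions `(counts + 0.1) / sum`
#' with a warning.
#'
#' @param counts Non-negative integer vector of per-feature counts; must have
#'   a positive sum.
#' @return A list with `proportions` (numeric, sums to 1), `p0` (estimated
#'   unseen mass before renormalization) and `method` (`"sgt"` or
#'   `"pseudocount"`).
#' @export
good_turing_proportions <- function(counts) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be finite non-negative integers", call. = FALSE)
  }
  n_total <- sum(counts)
  if (n_total <= 0) stop("counts sum to zero; no profile to estimate",
                         call. = FALSE)

  pos <- counts > 0
  tab <- table(counts[pos])
  r <- as.numeric(names(tab))
  nr <- as.numeric(tab)
  n1 <- if (any(r == 1)) nr[r == 1] else 0

  if (length(r) < 2L || n1 == 0) {
    warning("Good-Turing estimate not identifiable (",
            if (length(r) < 2L) "fewer than two distinct counts"
            else "no singleton features",
            "); falling back to +0.1 pseudocount proportions", call. = FALSE)
    p <- (counts + 0.1) / sum(counts + 0.1)
    return(list(proportions = p, p0 = 0, method = "pseudocount"))
  }

  k <- length(r)
  r_prev <- c(0, r[-k])
  r_next <- c(r[-1], 2 * r[k] - r[k - 1L])
  z <- nr / (0.5 * (r_next - r_prev))
  fit <- lm(log(z) ~ log(r))
  slope <- coef(fit)[[2L]]
  if (slope > -1) {
    warning("Good-Turing log-log slope ", signif(slope, 3),
            " > -1; smoothed estimates may be unreliable", call. = FALSE)
  }
  # r* = (r+1) S(r+1)/S(r) with log S(r) = a + slope*log(r)
  r_star <- (r + 1) * ((r + 1) / r)^slope

  p0 <- n1 / n_total
  norm <- sum(nr * r_star)
  p <- numeric(length(counts))
  p[pos] <- (1 - p0) * r_star[match(counts[pos], r)] / norm
  n_zero <- sum(!pos)
  if (n_zero > 0) p[!pos] <- p0 / n_zero
  p <- p / sum(p)
  list(proportions = p, p0 = p0, method = "sgt")
}
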