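# Independent oracles used across the suite.

# Brute-force maximizer of the weighted Bernoulli log-likelihood over a dense
# 2-parameter grid (intercept + slope).  Deliberately independent of the
# package's IRLS path.
grid_oracle <- function(x, y, w, lim = 4, step = 1e-3) {
  # coarse pass then fine pass around the coarse optimum
  eval_ll <- function(b0, b1) {
    mu <- plogis(b0 + b1 * x)
    sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  }
  coarse <- seq(-lim, lim, by = 0.05)
  ll <- outer(coarse, coarse, Vectorize(eval_ll))
  i <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  fine0 <- seq(coarse[i[1]] - 0.06, coarse[i[1]] + 0.06, by = step)
  fine1 <- seq(coarse[i[2]] - 0.06, coarse[i[2]] + 0.06, by = step)
  ll2 <- outer(fine0, fine1, Vectorize(eval_ll))
  j <- which(ll2 == max(ll2), arr.ind = TRUE)[1, ]
  c(fine0[j[1]], fine1[j[2]])
}

# Small logistic data generator for oracle comparisons.
sim_logistic <- function(n, beta = c(-0.3, 0.8), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x))
  data.frame(x = x, y = y)
}
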