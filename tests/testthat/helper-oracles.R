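# Naive greedy oracle: re-solves the full least-squares problem from scratch
# at every step, never reusing state from the previous step.
omp_oracle <- function(X, y, d0) {
  n <- nrow(X)
  mu <- colMeans(X); sdv <- sqrt(colMeans(X^2) - mu^2)
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  yc <- y - mean(y)
  active <- integer(0)
  for (step in seq_len(d0)) {
    resid <- if (length(active)) {
      yc - Xs[, active, drop = FALSE] %*%
        solve(crossprod(Xs[, active, drop = FALSE]),
              crossprod(Xs[, active, drop = FALSE], yc))
    } else yc
    corr <- abs(drop(crossprod(Xs, resid)))
    corr[active] <- -Inf
    active <- c(active, which.max(corr))
  }
  beta_std <- numeric(ncol(X))
  beta_std[active] <- solve(crossprod(Xs[, active, drop = FALSE]),
                            crossprod(Xs[, active, drop = FALSE], yc))
  beta <- beta_std / sdv
  list(support = sort(active), coefficients = beta,
       intercept = mean(y) - sum(beta * mu))
}
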