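#' Orthogonal matching pursuit configuration
#'
#' @param delta Fraction in (0, 1] of the candidate regulators admissible as
#'   the l0 budget ceiling `d0max = min(floor(delta * p), rank(X))`.
#' @param d0max_override Optional positive integer overriding the ceiling.
#' @param k_inner Number of inner cross-validation folds.
#' @return A list of class `omp_config`.
#' @export
omp_config <- function(delta = 0.5, d0max_override = NULL, k_inner = 5L) {
  stopifnot(delta > 0, delta <= 1, k_inner >= 2)
  structure(list(delta = delta, d0max_override = d0max_override,
                 k_inner = as.integer(k_inner)),
            class = "omp_config")
}

# z-score columns with population sd so that crossprod(x) = n on the
# standardized scale; near-constant columns are flagged and zeroed out of the
# candidate pool.
standardize_columns <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)
  ok <- sdv > 1e-12
  Xs <- sweep(X, 2L, mu, "-")
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2L, sdv[ok], "/")
  Xs[, !ok] <- 0
  list(X = Xs, mean = mu, sd = sdv, ok = ok)
}

numerical_rank <- function(X) {
  if (nrow(X) == 0L || ncol(X) == 0L) return(0L)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (!length(sv) || sv[1] == 0) return(0L)
  sum(sv > max(dim(X)) * .Machine$double.eps * sv[1])
}

new_fit_result <- function(coefficients, intercept, hyperparams) {
  structure(list(coefficients = coefficients, intercept = intercept,
                 support = which(coefficients != 0),
                 selected_hyperparams = hyperparams),
            class = "gxn_fit")
}

#' Fit orthogonal matching pursuit with a fixed support budget
#'
#' Greedy forward selection: at each step the candidate feature with the
#' largest absolute correlation with the current residual enters the support,
#' all selected coefficients are refit by least squares, and the residual is
#' recomputed.  Selection stops after `d0` steps or when the residual is
#' (numerically) zero.  Features are standardized and the target centered
#' internally on the supplied rows; returned coefficients are on the original
#' feature scale with the implied intercept.
#'
#' @param X Numeric matrix, rows = observations, columns = candidate features.
#' @param y Numeric response vector.
#' @param d0 Non-negative integer support budget.
#' @return A `gxn_fit` with elements `coefficients`, `intercept`, `support`,
#'   `selected_hyperparams`.
#' @export
omp_fit <- function(X, y, d0) {
  path <- omp_path(X, y, d0)
  k <- length(path$supports)
  coef_std <- if (k == 0L) numeric(ncol(X)) else path$coef_std[[k]]
  unstandardize_fit(coef_std, path$std, mean(y), list(d0 = as.integer(d0)))
}

# Full greedy path up to d0max; coefficient vectors are on the standardized
# scale.  Shared by omp_fit and the cross-validated selector (the greedy
# supports are nested, so one path serves every candidate d0).
omp_path <- function(X, y, d0max) {
  if (d0max < 0) stop("d0 must be non-negative")
  n <- nrow(X); p <- ncol(X)
  std <- standardize_columns(X)
  yc <- y - mean(y)
  active <- integer(0)
  supports <- list(); coef_std <- list()
  resid <- yc
  resid_norms <- numeric(0)
  d0max <- min(d0max, sum(std$ok))
  while (length(active) < d0max) {
    corr <- abs(crossprod(std$X, resid)[, 1L])
    corr[active] <- -Inf
    corr[!std$ok] <- -Inf
    j <- which.max(corr)
    if (!is.finite(corr[j]) || corr[j] < 1e-12) break
    active <- c(active, j)
    beta <- qr.coef(qr(std$X[, active, drop = FALSE]), yc)
    beta[is.na(beta)] <- 0
    resid <- yc - std$X[, active, drop = FALSE] %*% beta
    cv <- numeric(p); cv[active] <- beta
    supports[[length(supports) + 1L]] <- active
    coef_std[[length(coef_std) + 1L]] <- cv
    resid_norms <- c(resid_norms, sqrt(sum(resid^2)))
    if (sqrt(sum(resid^2)) < 1e-10 * max(1, sqrt(sum(yc^2)))) break
  }
  list(supports = supports, coef_std = coef_std, std = std,
       resid_norms = resid_norms, y_mean = mean(y))
}

# Map standardized-scale coefficients back to the original feature scale.
unstandardize_fit <- function(coef_std, std, y_mean, hyperparams) {
  coef_orig <- coef_std
  coef_orig[std$ok] <- coef_std[std$ok] / std$sd[std$ok]
  intercept <- y_mean - sum(coef_orig * std$mean)
  new_fit_result(coef_orig, intercept, hyperparams)
}

predict_fit <- function(fit, X) {
  drop(X %*% fit$coefficients) + fit$intercept
}

# Seeded shuffle-then-block fold assignment shared by both solvers: rows are
# shuffled once, then cut into k contiguous blocks (remainder rows go to the
# first folds).
make_folds <- function(n, k, seed) {
  if (n < k) stop("fewer rows (", n, ") than folds (", k, ")")
  ord <- sample_with_seed(seed, n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unname(split(ord, rep(seq_len(k), times = sizes)))
}

sample_with_seed <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  sample.int(n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_seed_local <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Select the OMP support budget by inner cross-validation
#'
#' Every candidate budget `d0` in `0..d0max` is scored by mean validation R2
#' over `k_inner` folds (one greedy path per fold serves all budgets, since
#' greedy supports are nested).  Under the default `"1se"` rule the smallest
#' budget whose mean R2 lies within one standard error of the best mean wins
#' (the usual cross-validation parsimony rule; spurious extra features improve
#' the mean only within its own noise, so this resolves the
#' statistically-tied region toward sparsity).  `rule = "max"` takes the
#' plain argmax with exact ties going to the smaller budget.  The returned
#' fit is retrained on all supplied rows.
#'
#' @param X,y Training data (original scale).
#' @param cfg An [omp_config()].
#' @param seed Integer seed controlling fold assignment.
#' @param rule Budget selection rule, `"1se"` (default) or `"max"`.
#' @return List with `best_d0`, `fit` (a `gxn_fit`), and `cv_r2` (mean
#'   validation R2 per candidate, index 1 = d0 of 0).
#' @export
omp_select_d0 <- function(X, y, cfg = omp_config(), seed = 1L,
                          rule = c("1se", "max")) {
  rule <- match.arg(rule)
  n <- nrow(X); p <- ncol(X)
  d0max <- cfg$d0max_override %||%
    min(floor(cfg$delta * p), numerical_rank(standardize_columns(X)$X))
  d0max <- min(d0max, p)
  folds <- make_folds(n, cfg$k_inner, seed)
  scores <- matrix(NA_real_, nrow = length(folds), ncol = d0max + 1L)
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    Xtr <- X[-val, , drop = FALSE]; ytr <- y[-val]
    path <- omp_path(Xtr, ytr, d0max)
    for (d0 in 0:d0max) {
      if (d0 == 0L) {
        pred <- rep(mean(ytr), length(val))
      } else if (d0 <= length(path$coef_std)) {
        fit <- unstandardize_fit(path$coef_std[[d0]], path$std, mean(ytr), NULL)
        pred <- predict_fit(fit, X[val, , drop = FALSE])
      } else {
        # residual hit zero early: larger budgets equal the last path point
        fit <- unstandardize_fit(path$coef_std[[length(path$coef_std)]],
                                 path$std, mean(ytr), NULL)
        pred <- predict_fit(fit, X[val, , drop = FALSE])
      }
      scores[f, d0 + 1L] <- r2_score(y[val], pred)
    }
  }
  mean_r2 <- colMeans(scores, na.rm = TRUE)
  mean_r2[is.nan(mean_r2)] <- -Inf
  top <- which.max(mean_r2)            # which.max takes the first (smallest d0) on ties
  if (rule == "1se" && is.finite(mean_r2[top])) {
    se <- stats::sd(scores[, top]) / sqrt(nrow(scores))
    if (is.na(se)) se <- 0
    best_d0 <- which(mean_r2 >= mean_r2[top] - se)[1L] - 1L
  } else {
    best_d0 <- top - 1L
  }
  list(best_d0 = as.integer(best_d0),
       fit = omp_fit(X, y, best_d0),
       cv_r2 = mean_r2)
}
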