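#' Elastic-net configuration
#'
#' Defaults follow the method's reference settings: mixing grid
#' `rho_grid = c(0.8, 0.9, 0.99, 1)` biased toward sparse solutions, a
#' log-spaced path of `K_alpha` regularization strengths, and
#' `epsilon = 1/K_alpha` tying the path depth to its length.
#'
#' @param rho_grid Numeric vector of l1 mixing weights in (0, 1].
#' @param K_alpha Number of alpha values on the path.
#' @param epsilon Ratio `alpha_min / alpha_max` in (0, 1); default `1/K_alpha`.
#' @param k_inner Inner cross-validation folds.
#' @param max_iter Maximum coordinate-descent sweeps.
#' @param tol Convergence tolerance on the largest coefficient change in one
#'   sweep (standardized scale).
#' @return A list of class `en_config`.
#' @export
en_config <- function(rho_grid = c(0.8, 0.9, 0.99, 1), K_alpha = 10L,
                      epsilon = NULL, k_inner = 5L, max_iter = 1000L,
                      tol = 1e-7) {
  epsilon <- epsilon %||% (1 / K_alpha)
  stopifnot(all(rho_grid > 0), all(rho_grid <= 1), K_alpha >= 1,
            epsilon > 0, epsilon < 1 || K_alpha == 1, k_inner >= 2)
  structure(list(rho_grid = rho_grid, K_alpha = as.integer(K_alpha),
                 epsilon = epsilon, k_inner = as.integer(k_inner),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "en_config")
}

#' Compute the pathwise alpha grid
#'
#' `alpha_max = max_(i != j) |x_i' x_j| / (D * rho)` over ordered pairs of
#' standardized columns of `X_learn` (at `alpha_max` the elastic-net solution
#' for any column of `X_learn` regressed on the others is the zero vector);
#' `alpha_min = epsilon * alpha_max`; `K_alpha` values are log-spaced between
#' them, strictly decreasing.
#'
#' @param X_learn Numeric matrix whose columns span the candidate features
#'   (standardized internally).
#' @param rho Positive l1 mixing weight.
#' @param K_alpha Number of grid values.
#' @param epsilon Ratio of the smallest to the largest alpha.
#' @return Strictly decreasing numeric vector of length `K_alpha`.
#' @export
en_alpha_grid <- function(X_learn, rho, K_alpha, epsilon = 1 / K_alpha) {
  stopifnot(rho > 0, K_alpha >= 1)
  std <- standardize_columns(X_learn)
  Xs <- std$X[, std$ok, drop = FALSE]
  if (ncol(Xs) < 2L) stop("alpha grid needs at least two non-constant feature columns")
  G <- crossprod(Xs)
  diag(G) <- 0
  amax <- max(abs(G)) / (nrow(X_learn) * rho)
  if (amax <= .Machine$double.eps) {
    stop("degenerate alpha grid: all pairwise cross-products are zero ",
         "(orthogonal design); fall back to alpha_max = max|X'y| / (D*rho)")
  }
  if (K_alpha == 1L) return(amax)
  exp(seq(log(amax), log(epsilon * amax), length.out = K_alpha))
}

#' Fit one elastic-net problem by randomized coordinate descent
#'
#' Minimizes `||y - X c||^2 / (2 D) + alpha * rho * ||c||_1 +
#' alpha * (1 - rho) * ||c||^2 / 2` on internally standardized features.
#' One coordinate is updated at a time in a freshly drawn random order per
#' sweep (seeded, hence bit-reproducible); convergence is declared when the
#' largest coefficient change in a sweep drops below `tol`.
#'
#' @param X Numeric matrix of candidate features.
#' @param y Numeric response.
#' @param alpha Overall regularization strength (>= 0).
#' @param rho l1 mixing weight in \[0, 1\].
#' @param seed Integer seed for the coordinate order.
#' @param max_iter Maximum sweeps.
#' @param tol Convergence tolerance.
#' @param init Optional warm-start coefficients on the standardized scale.
#' @return A `gxn_fit` (original-scale coefficients and intercept).
#' @export
en_fit <- function(X, y, alpha, rho, seed = 1L, max_iter = 1000L, tol = 1e-7,
                   init = NULL) {
  stopifnot(alpha >= 0, rho >= 0, rho <= 1)
  n <- nrow(X)
  std <- standardize_columns(X)
  yc <- y - mean(y)
  res <- with_seed_local(seed,
    en_cd_core(std$X, yc, n, std$ok, alpha, rho, max_iter, tol, init))
  if (!res$converged) {
    warning(sprintf("coordinate descent did not converge in %d sweeps (last max coefficient change %.3g)",
                    max_iter, res$last_delta))
  }
  fit <- unstandardize_fit(res$coef, std, mean(y),
                           list(alpha = alpha, rho = rho))
  fit$coef_std <- res$coef
  fit
}

# Gram-based coordinate descent; assumes RNG state already set by the caller.
en_cd_core <- function(Xs, yc, n, ok, alpha, rho, max_iter, tol, init = NULL) {
  p <- ncol(Xs)
  G <- crossprod(Xs) / n          # G[j,j] = 1 for non-constant columns
  b <- crossprod(Xs, yc)[, 1L] / n
  cf <- if (is.null(init)) numeric(p) else init
  thr <- alpha * rho
  denom <- 1 + alpha * (1 - rho)
  converged <- FALSE
  last_delta <- Inf
  for (it in seq_len(max_iter)) {
    ordc <- sample.int(p)
    delta <- 0
    for (j in ordc) {
      if (!ok[j]) next
      gj <- b[j] - sum(G[, j] * cf) + G[j, j] * cf[j]
      new <- soft_threshold(gj, thr) / denom
      d <- abs(new - cf[j])
      if (d > delta) delta <- d
      cf[j] <- new
    }
    last_delta <- delta
    if (delta < tol) { converged <- TRUE; break }
  }
  list(coef = cf, converged = converged, last_delta = last_delta)
}

soft_threshold <- function(z, t) sign(z) * max(abs(z) - t, 0)

#' Select elastic-net hyperparameters by inner cross-validation
#'
#' Explores `rho_grid x alpha path` (the alpha path is recomputed per rho from
#' `grid_matrix`), scoring each pair by mean validation R2 over `k_inner`
#' folds with warm starts along the path.  Ties prefer the sparser model:
#' larger rho, then larger alpha.  The winning pair is refit on all rows.
#'
#' @param X,y Training data.
#' @param cfg An [en_config()].
#' @param seed Integer seed (fold assignment and coordinate orders).
#' @param grid_matrix Matrix used to compute the alpha grid; defaults to `X`.
#'   Passing the full regulator matrix (target column included) preserves the
#'   null-vector property at `alpha_max` for regulator targets.
#' @return List with `best_alpha`, `best_rho`, `fit`, and the search table
#'   `cv_table` (`rho`, `alpha`, `mean_r2`).
#' @export
en_select <- function(X, y, cfg = en_config(), seed = 1L, grid_matrix = X) {
  n <- nrow(X)
  folds <- make_folds(n, cfg$k_inner, seed)
  rows <- list()
  for (rho in cfg$rho_grid) {
    alphas <- en_alpha_grid(grid_matrix, rho, cfg$K_alpha, cfg$epsilon)
    scores <- matrix(NA_real_, length(folds), length(alphas))
    for (f in seq_along(folds)) {
      val <- folds[[f]]
      Xtr <- X[-val, , drop = FALSE]; ytr <- y[-val]
      std <- standardize_columns(Xtr)
      ytr_c <- ytr - mean(ytr)
      warm <- NULL
      for (a in seq_along(alphas)) {
        res <- with_seed_local(seed + a,
          en_cd_core(std$X, ytr_c, nrow(Xtr), std$ok, alphas[a], rho,
                     cfg$max_iter, cfg$tol, warm))
        warm <- res$coef
        fit <- unstandardize_fit(res$coef, std, mean(ytr), NULL)
        scores[f, a] <- r2_score(y[val], predict_fit(fit, X[val, , drop = FALSE]))
      }
    }
    rows[[length(rows) + 1L]] <-
      tibble::tibble(rho = rho, alpha = alphas,
                     mean_r2 = colMeans(scores, na.rm = TRUE))
  }
  tab <- dplyr::bind_rows(rows)
  tab$mean_r2[is.nan(tab$mean_r2)] <- -Inf
  # ties toward sparsity: larger rho, then larger alpha
  best <- tab[order(-tab$mean_r2, -tab$rho, -tab$alpha), ][1L, ]
  fit <- en_fit(X, y, best$alpha, best$rho, seed = seed,
                max_iter = cfg$max_iter, tol = cfg$tol)
  list(best_alpha = best$alpha, best_rho = best$rho, fit = fit, cv_table = tab)
}
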