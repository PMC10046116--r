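#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, evaluated on the supplied
#' fold.  Equals 1 for perfect prediction, 0 for the fold-mean predictor, and
#' can be arbitrarily negative.  Undefined (NA) when `y_true` is constant.
#'
#' @param y_true Observed values (length >= 2).
#' @param y_pred Predicted values.
#' @return A single numeric value or `NA_real_`.
#' @export
r2_score <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  tss <- sum((y_true - mean(y_true))^2)
  if (tss <= 0) return(NA_real_)
  1 - sum((y_true - y_pred)^2) / tss
}

#' Candidate regulators for one gene
#'
#' The features allowed in gene `g`'s model: every regulator except `g`
#' itself (no self-loops), in the regulator set's order.
#'
#' @param g Gene identifier.
#' @param regulators Character vector of regulator ids.
#' @return Character vector, possibly empty.
#' @export
candidate_features <- function(g, regulators) {
  setdiff(regulators, g)
}

derive_gene_seed <- function(seed, gene_index) {
  as.integer((as.numeric(seed) * 1000003 + gene_index * 7919) %% 2147483629L) + 1L
}

#' Fit the self-expression model of one gene
#'
#' Nested cross-validation: the outer loop holds out each of `k_outer` folds
#' in turn, runs the method's inner-CV hyperparameter selector on the
#' remaining rows, and records validation R2 and wall-clock fit time on the
#' held-out fold.  The reported coefficient column is the inner-CV-selected
#' model refit on all conditions; the outer folds only monitor
#' generalization.
#'
#' @param X A `gxn_expression` (conditions x genes).
#' @param g Gene id (must be a column of `X`).
#' @param regulators Character vector of candidate regulator ids.
#' @param method `"omp"` or `"en"`.
#' @param cfg An [omp_config()] or [en_config()] matching `method`.
#' @param k_outer Outer folds.
#' @param seed Integer seed for this gene.
#' @return List with `coefficients` (named over `regulators`, zero at `g`),
#'   `report` (tibble: one row per outer fold), `mean_r2`, `hyperparams`,
#'   `flag` (`"ok"`, `"constant"`, or `"no_candidates"`).
#' @export
fit_gene <- function(X, g, regulators, method = c("omp", "en"), cfg = NULL,
                     k_outer = 5L, seed = 1L) {
  method <- match.arg(method)
  cfg <- cfg %||% if (method == "omp") omp_config() else en_config()
  y <- X[, g]
  cands <- candidate_features(g, regulators)
  zero_col <- stats::setNames(numeric(length(regulators)), regulators)
  empty_report <- tibble::tibble(fold = integer(), r2 = numeric(),
                                 hyperparams = character(), runtime = numeric())
  if (!length(cands)) {
    return(list(coefficients = zero_col, report = empty_report,
                mean_r2 = NA_real_, hyperparams = NA_character_,
                flag = "no_candidates"))
  }
  if (stats::sd(y) <= 1e-12) {
    return(list(coefficients = zero_col, report = empty_report,
                mean_r2 = NA_real_, hyperparams = NA_character_,
                flag = "constant"))
  }
  Xc <- unclass(X)[, cands, drop = FALSE]
  grid_matrix <- unclass(X)[, regulators, drop = FALSE]
  folds <- make_folds(nrow(Xc), k_outer, seed)
  rep_rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    t0 <- proc.time()[["elapsed"]]
    sel <- run_selector(Xc[-val, , drop = FALSE], y[-val], method, cfg,
                        seed = seed + f, grid_matrix = grid_matrix[-val, , drop = FALSE])
    runtime <- proc.time()[["elapsed"]] - t0
    r2 <- r2_score(y[val], predict_fit(sel$fit, Xc[val, , drop = FALSE]))
    rep_rows[[f]] <- tibble::tibble(fold = f, r2 = r2,
                                    hyperparams = format_hyperparams(sel),
                                    runtime = runtime)
  }
  report <- dplyr::bind_rows(rep_rows)
  final <- run_selector(Xc, y, method, cfg, seed = seed,
                        grid_matrix = grid_matrix)
  coefs <- zero_col
  coefs[cands] <- final$fit$coefficients
  list(coefficients = coefs, report = report,
       mean_r2 = mean(report$r2, na.rm = TRUE),
       hyperparams = format_hyperparams(final), flag = "ok")
}

run_selector <- function(X, y, method, cfg, seed, grid_matrix) {
  if (method == "omp") {
    sel <- omp_select_d0(X, y, cfg, seed = seed)
    list(fit = sel$fit, label = sprintf("d0=%d", sel$best_d0))
  } else {
    sel <- en_select(X, y, cfg, seed = seed, grid_matrix = grid_matrix)
    list(fit = sel$fit,
         label = sprintf("alpha=%.6g,rho=%g", sel$best_alpha, sel$best_rho))
  }
}

format_hyperparams <- function(sel) sel$label

#' Infer a gene self-expressive network
#'
#' Applies [fit_gene()] to every gene, assembling the sparse coefficient
#' matrix `C` (rows = regulators, columns = genes) under the structural
#' constraints: no self-loops (`C[g, g] = 0`) and only regulators as
#' predictors.  Per-gene seeds are derived deterministically from `seed`, so
#' results do not depend on evaluation order.
#'
#' @param X A `gxn_expression`.
#' @param regulators Character vector of regulator ids (subset of the genes of
#'   `X`); defaults to all genes.
#' @param method `"omp"` or `"en"`.
#' @param cfg Solver configuration ([omp_config()] / [en_config()]).
#' @param k_outer Outer cross-validation folds.
#' @param seed Integer run seed.
#' @param genes Genes to fit (defaults to all genes of `X`); unfitted genes
#'   get zero columns flagged `"not_fitted"`.
#' @return An object of class `gxn_model`: sparse matrix `C`, tibble
#'   `per_gene` (gene, mean_r2, hyperparams, flag), tibble `folds` (per-fold
#'   diagnostics), plus `method`, `k_inner`, `k_outer`, `seed`, `regulators`,
#'   `genes`.
#' @export
infer_gxn <- function(X, regulators = colnames(X), method = c("omp", "en"),
                      cfg = NULL, k_outer = 5L, seed = 1L,
                      genes = colnames(X)) {
  method <- match.arg(method)
  cfg <- cfg %||% if (method == "omp") omp_config() else en_config()
  if (!all(regulators %in% colnames(X))) {
    stop("regulators absent from the expression matrix: ",
         paste(utils::head(setdiff(regulators, colnames(X)), 5), collapse = ", "))
  }
  if (!all(genes %in% colnames(X))) stop("unknown genes requested")
  all_genes <- colnames(X)
  C <- Matrix::Matrix(0, nrow = length(regulators), ncol = length(all_genes),
                      dimnames = list(regulators, all_genes), sparse = TRUE)
  per_gene <- vector("list", length(all_genes))
  fold_rows <- vector("list", length(all_genes))
  for (i in seq_along(all_genes)) {
    g <- all_genes[i]
    if (!g %in% genes) {
      per_gene[[i]] <- tibble::tibble(gene = g, mean_r2 = NA_real_,
                                      hyperparams = NA_character_,
                                      flag = "not_fitted")
      next
    }
    res <- fit_gene(X, g, regulators, method = method, cfg = cfg,
                    k_outer = k_outer, seed = derive_gene_seed(seed, i))
    nz <- which(res$coefficients != 0)
    if (length(nz)) C[nz, i] <- res$coefficients[nz]
    per_gene[[i]] <- tibble::tibble(gene = g, mean_r2 = res$mean_r2,
                                    hyperparams = res$hyperparams,
                                    flag = res$flag)
    if (nrow(res$report)) {
      fold_rows[[i]] <- dplyr::mutate(res$report, gene = g, .before = 1L)
    }
  }
  structure(
    list(C = C,
         per_gene = dplyr::bind_rows(per_gene),
         folds = dplyr::bind_rows(fold_rows),
         method = method, cfg = cfg,
         k_inner = cfg$k_inner, k_outer = as.integer(k_outer),
         seed = as.integer(seed),
         regulators = regulators, genes = all_genes),
    class = "gxn_model")
}

#' @export
print.gxn_model <- function(x, ...) {
  cat(sprintf("<gxn_model> %s: %d regulators x %d genes, %d edges, mean validation R2 %.3f\n",
              toupper(x$method), nrow(x$C), ncol(x$C), Matrix::nnzero(x$C),
              mean(x$per_gene$mean_r2, na.rm = TRUE)))
  invisible(x)
}

#' Retain links from well-generalizing models
#'
#' Keeps edge `(regulator, target)` when its coefficient is nonzero and the
#' target's mean outer-validation R2 strictly exceeds `threshold` (default
#' 0.5).  Genes with undefined R2 contribute no edges.
#'
#' @param model A `gxn_model`.
#' @param threshold R2 cut-off.
#' @return Tibble `regulator`, `target`, `coefficient`, `target_mean_r2`.
#' @export
filter_links_by_r2 <- function(model, threshold = 0.5) {
  edges <- generics::tidy(model)
  keep <- !is.na(edges$target_mean_r2) & edges$target_mean_r2 > threshold
  edges[keep, , drop = FALSE]
}
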