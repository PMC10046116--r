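#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted network model into an edge table
#'
#' @param x A `gxn_model`.
#' @param ... Unused.
#' @return Tibble `regulator`, `target`, `coefficient`, `target_mean_r2`,
#'   one row per nonzero coefficient.
#' @export
tidy.gxn_model <- function(x, ...) {
  idx <- Matrix::which(x$C != 0, arr.ind = TRUE)
  r2 <- stats::setNames(x$per_gene$mean_r2, x$per_gene$gene)
  out <- tibble::tibble(
    regulator = rownames(x$C)[idx[, 1L]],
    target = colnames(x$C)[idx[, 2L]],
    coefficient = x$C[idx],
    target_mean_r2 = unname(r2[colnames(x$C)[idx[, 2L]]]))
  out[order(-abs(out$coefficient), out$regulator, out$target), ]
}

#' One-row summary of a fitted network model
#'
#' @param x A `gxn_model`.
#' @param ... Unused.
#' @return Tibble with `method`, `n_genes`, `n_regulators`, `n_edges`,
#'   `sparsity`, `mean_r2`, `seed`.
#' @export
glance.gxn_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_genes = ncol(x$C),
    n_regulators = nrow(x$C),
    n_edges = Matrix::nnzero(x$C),
    sparsity = 100 * (1 - Matrix::nnzero(x$C) /
                        full_universe_size(ncol(x$C), nrow(x$C))),
    mean_r2 = mean(x$per_gene$mean_r2, na.rm = TRUE),
    seed = x$seed)
}

#' Tidy a community partition
#'
#' @param x A `gxn_partition`.
#' @param ... Unused.
#' @return Tibble `node`, `community`.
#' @export
tidy.gxn_partition <- function(x, ...) x$membership

#' One-row summary of a community partition
#'
#' @param x A `gxn_partition`.
#' @param ... Unused.
#' @return Tibble `n_communities`, `r`, `Q`, `largest_community`.
#' @export
glance.gxn_partition <- function(x, ...) {
  tibble::tibble(n_communities = length(unique(x$membership$community)),
                 r = x$r, Q = x$Q,
                 largest_community = as.integer(max(x$sizes)))
}

#' Tidy a resolution scan
#'
#' @param x A `gxn_resolution_scan`.
#' @param ... Unused.
#' @return The scan tibble (`r`, `sse`, `n_communities`, `smoothed_sse`).
#' @export
tidy.gxn_resolution_scan <- function(x, ...) x$scan

#' Plot a resolution scan
#'
#' Raw and smoothed SSE against the resolution, with the chosen elbow marked.
#'
#' @param object A `gxn_resolution_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gxn_resolution_scan <- function(object, ...) {
  df <- object$scan
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$sse), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_sse), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$r_star, linetype = "dashed") +
    ggplot2::labs(x = "resolution r", y = "community SSE",
                  title = sprintf("Resolution scan (r* = %g)", object$r_star))
}

#' Plot community sizes
#'
#' @param object A `gxn_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gxn_partition <- function(object, ...) {
  df <- dplyr::count(object$membership, .data$community, name = "size")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$community), y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "community", y = "genes",
                  title = sprintf("%d communities at r = %g (Q = %.3f)",
                                  nrow(df), object$r, object$Q))
}

#' Plot in/out-degree distributions of a network
#'
#' @param net A `gxn_network`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(net) {
  deg <- degrees(net)
  long <- tidyr::pivot_longer(deg, c("in_degree", "out_degree"),
                              names_to = "kind", values_to = "degree")
  long <- long[!is.na(long$degree), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = "degree", y = "nodes")
}
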