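#' Build the directed network encoded by a coefficient matrix
#'
#' Edges run regulator -> target with the (signed) regression coefficient as
#' weight; self-loops are structurally absent.
#'
#' @param x A `gxn_model`, or an edge tibble with columns `regulator`,
#'   `target`, `coefficient` (e.g. from [filter_links_by_r2()]).
#' @param regulators,genes Node sets; taken from the model when `x` is a
#'   `gxn_model`.
#' @return An object of class `gxn_network`: tibble `edges`, character
#'   `nodes`, character `regulators`.
#' @export
as_network <- function(x, regulators = NULL, genes = NULL) {
  if (inherits(x, "gxn_model")) {
    edges <- generics::tidy(x)[, c("regulator", "target", "coefficient")]
    regulators <- regulators %||% x$regulators
    genes <- genes %||% x$genes
  } else {
    edges <- tibble::as_tibble(x)[, c("regulator", "target", "coefficient")]
    regulators <- regulators %||% sort(unique(edges$regulator))
    genes <- genes %||% sort(unique(c(edges$regulator, edges$target)))
  }
  names(edges)[3] <- "weight"
  edges <- edges[edges$weight != 0, , drop = FALSE]
  if (any(edges$regulator == edges$target)) stop("self-loop edge in network")
  if (!all(edges$regulator %in% regulators)) stop("edge from a non-regulator node")
  if (!all(regulators %in% genes)) stop("regulators must be a subset of the gene set")
  structure(list(edges = edges, nodes = genes, regulators = regulators),
            class = "gxn_network")
}

#' @export
print.gxn_network <- function(x, ...) {
  cat(sprintf("<gxn_network> %d nodes (%d regulators), %d edges\n",
              length(x$nodes), length(x$regulators), nrow(x$edges)))
  invisible(x)
}

#' Size of the candidate edge universe
#'
#' Number of ordered regulator-gene pairs excluding self-loops under the
#' convention that regulators are genes: `n_regulators * (n_genes - 1)`.
#'
#' @param n_genes,n_regulators Positive counts with
#'   `n_regulators <= n_genes`.
#' @return A single number (possible edges).
#' @export
full_universe_size <- function(n_genes, n_regulators) {
  stopifnot(n_genes >= 1, n_regulators >= 1)
  if (n_regulators > n_genes) {
    stop("more regulators than genes: the regulator set must be a subset of the genes")
  }
  as.numeric(n_regulators) * (as.numeric(n_genes) - 1)
}

#' Network sparsity
#'
#' Percentage of the candidate edge universe *not* used by the network:
#' `100 * |Efull \ E| / |Efull|`.
#'
#' @param net A `gxn_network`.
#' @return Percentage in \[0, 100\].
#' @export
sparsity <- function(net) {
  full <- full_universe_size(length(net$nodes), length(net$regulators))
  if (full == 0) stop("sparsity undefined: empty edge universe")
  100 * (full - nrow(net$edges)) / full
}

#' Unweighted in- and out-degrees
#'
#' In-degree of a gene = number of regulators in its model; out-degree of a
#' regulator = number of target models that selected it.  Coefficient
#' magnitudes are ignored.
#'
#' @param net A `gxn_network`.
#' @return Tibble `node`, `in_degree`, `out_degree` covering every node
#'   (`out_degree` is `NA` for non-regulators).
#' @export
degrees <- function(net) {
  indeg <- table(factor(net$edges$target, levels = net$nodes))
  outdeg <- table(factor(net$edges$regulator, levels = net$regulators))
  tibble::tibble(
    node = net$nodes,
    in_degree = as.integer(indeg[net$nodes]),
    out_degree = ifelse(net$nodes %in% net$regulators,
                        as.integer(outdeg[net$nodes]), NA_integer_)
  )
}

#' Export a network as GraphML
#'
#' Edge attributes `weight` (absolute coefficient) and `sign` are attached;
#' node attribute `is_regulator` marks the regulator set.
#'
#' @param net A `gxn_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$regulator, to = net$edges$target,
               weight = abs(net$edges$weight),
               sign = sign(net$edges$weight)),
    directed = TRUE,
    vertices = data.frame(name = net$nodes,
                          is_regulator = net$nodes %in% net$regulators))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
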