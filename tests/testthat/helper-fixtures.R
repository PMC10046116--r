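# Shared fixture builders; everything is generated in code, seeded.

toy_expression <- function(D = 6, genes = c("g1", "g2", "g3"), seed = 11) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(D * length(genes)), D, length(genes))
    expression_matrix(vals, gene_ids = genes)
  })
}

# Directed toy network from an edge data frame.
toy_network <- function(edges, nodes = NULL, regulators = NULL) {
  edges <- tibble::as_tibble(edges)
  nodes <- nodes %||% sort(unique(c(edges$regulator, edges$target)))
  regulators <- regulators %||% sort(unique(edges$regulator))
  as_network(edges, regulators = regulators, genes = nodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two directed 3-cycles with unit weights (disjoint blocks).
two_cycles_network <- function() {
  edges <- tibble::tibble(
    regulator = c("a1", "a2", "a3", "b1", "b2", "b3"),
    target    = c("a2", "a3", "a1", "b2", "b3", "b1"),
    coefficient = 1)
  toy_network(edges, nodes = c("a1", "a2", "a3", "b1", "b2", "b3"),
              regulators = c("a1", "a2", "a3", "b1", "b2", "b3"))
}

# Literal double-loop evaluation of the generalized directed modularity,
# independent of the package's matrix implementation.
modularity_bruteforce <- function(net, membership, r) {
  m <- nrow(net$edges)
  ekey <- paste(net$edges$regulator, net$edges$target)
  w <- stats::setNames(abs(net$edges$weight), ekey)
  dout <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  din <- dout
  for (i in seq_len(m)) {
    dout[net$edges$regulator[i]] <- dout[net$edges$regulator[i]] + 1
    din[net$edges$target[i]] <- din[net$edges$target[i]] + 1
  }
  q <- 0
  for (psi in net$regulators) {
    for (g in net$nodes) {
      if (psi == g) next
      if (membership[[psi]] != membership[[g]]) next
      wij <- if (paste(psi, g) %in% ekey) w[[paste(psi, g)]] else 0
      q <- q + wij - r * dout[[psi]] * din[[g]] / m
    }
  }
  q / m
}

# All set partitions of seq_len(n) (Bell number; 203 for n = 6).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(i, blocks) {
    if (i > n) {
      out[[length(out) + 1L]] <<- blocks
      return(invisible())
    }
    for (b in seq_along(blocks)) {
      nb <- blocks
      nb[[b]] <- c(nb[[b]], i)
      recurse(i + 1L, nb)
    }
    recurse(i + 1L, c(blocks, list(i)))
  }
  recurse(2L, list(1L))
  out
}

# Random small directed network over n nodes, all nodes regulators.
random_small_network <- function(n = 6, p_edge = 0.35, seed = 1) {
  withr::with_seed(seed, {
    nodes <- paste0("n", seq_len(n))
    pairs <- expand.grid(regulator = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, ]
    keep <- runif(nrow(pairs)) < p_edge
    if (!any(keep)) keep[1] <- TRUE
    edges <- pairs[keep, ]
    edges$coefficient <- runif(nrow(edges), 0.2, 1.5)
    toy_network(edges, nodes = nodes, regulators = nodes)
  })
}

random_membership <- function(net, k, seed) {
  withr::with_seed(seed, {
    stats::setNames(sample.int(k, length(net$nodes), replace = TRUE), net$nodes)
  })
}
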