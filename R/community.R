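#' Generalized directed modularity
#'
#' For a directed regulator->gene network with edge weights `|coefficient|`,
#' \deqn{Q = \frac{1}{|E|} \sum_{\psi \ne g} \left[w(\psi,g) -
#'   r\,\frac{deg^+(\psi)\,deg^-(g)}{|E|}\right] \zeta(\psi,g)}
#' where degrees are unweighted counts, `r` scales the configuration-model
#' null term, and `zeta = 1` when the two nodes share a community.  Pairs with
#' `psi = g` are excluded (the network has no self-loops), so the
#' all-singletons partition scores exactly 0.
#'
#' @param net A `gxn_network` with at least one edge.
#' @param partition A `gxn_partition` or a named vector mapping every node of
#'   `net` to a community id.
#' @param r Positive resolution parameter.
#' @return The modularity `Q`.
#' @export
generalized_modularity <- function(net, partition, r = 1) {
  M <- modularity_matrix(net, r)
  memb <- as_membership(partition, net$nodes)
  Q <- 0
  for (comm in unique(memb)) {
    idx <- which(memb == comm)
    Q <- Q + sum(M[idx, idx])
  }
  Q / nrow(net$edges)
}

# Node-pair contribution matrix: M[i, j] = w(i, j) - r * dout(i) * din(j) / |E|
# for regulator i and node j with i != j; all other entries zero.
modularity_matrix <- function(net, r) {
  if (nrow(net$edges) == 0L) stop("modularity undefined for an empty edge set")
  n <- length(net$nodes)
  node_idx <- stats::setNames(seq_len(n), net$nodes)
  deg <- degrees(net)
  dout <- ifelse(is.na(deg$out_degree), 0L, deg$out_degree)
  din <- deg$in_degree
  m <- nrow(net$edges)
  M <- -r * outer(dout, din) / m   # rows with dout = 0 (non-regulators) stay zero
  ei <- node_idx[net$edges$regulator]
  ej <- node_idx[net$edges$target]
  M[cbind(ei, ej)] <- M[cbind(ei, ej)] + abs(net$edges$weight)
  diag(M) <- 0
  M
}

as_membership <- function(partition, nodes) {
  memb <- if (inherits(partition, "gxn_partition")) {
    stats::setNames(partition$membership$community, partition$membership$node)
  } else partition
  if (!all(nodes %in% names(memb))) stop("partition must assign every network node")
  unname(memb[nodes])
}

#' Greedy agglomerative community detection
#'
#' Clauset-Newman-Moore-style greedy maximization of
#' [generalized_modularity()]: starting from singletons, the pair of
#' communities whose merge most increases `Q` is joined (ties: lexicographically
#' smallest pair) until a single community remains; the partition attaining
#' the maximal `Q` along the merge path is returned.
#'
#' @param net A `gxn_network` with at least one edge.
#' @param r Positive resolution parameter.
#' @return A `gxn_partition`: tibble `membership` (`node`, `community`), the
#'   resolution `r`, modularity `Q`, and community `sizes`.
#' @export
greedy_partition <- function(net, r = 1) {
  M <- modularity_matrix(net, r)
  m <- nrow(net$edges)
  n <- length(net$nodes)
  TT <- M                              # community-pair totals; starts at node level
  members <- as.list(seq_len(n))
  assign_best <- seq_len(n)
  Qcur <- 0                            # singleton partition: no intra pairs
  Qbest <- 0
  while (nrow(TT) > 1L) {
    gains <- (TT + t(TT)) / m
    diag(gains) <- -Inf
    best <- max(gains)
    hits <- which(gains == best, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pick <- hits[order(hits[, 1], hits[, 2])[1L], ]
    i <- pick[1L]; j <- pick[2L]
    Qcur <- Qcur + best
    TT[i, ] <- TT[i, ] + TT[j, ]
    TT[, i] <- TT[, i] + TT[, j]
    TT <- TT[-j, -j, drop = FALSE]
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
    if (Qcur > Qbest + 1e-12) {
      Qbest <- Qcur
      assign_best <- integer(n)
      for (k in seq_along(members)) assign_best[members[[k]]] <- k
    }
  }
  # stable community ids: renumber by smallest member node index
  first_node <- tapply(seq_len(n), assign_best, min)
  relabel <- rank(first_node, ties.method = "first")
  comm <- as.integer(relabel[as.character(assign_best)])
  membership <- tibble::tibble(node = net$nodes, community = comm)
  structure(list(membership = membership, r = r, Q = Qbest,
                 sizes = sort(table(comm), decreasing = TRUE)),
            class = "gxn_partition")
}

#' @export
print.gxn_partition <- function(x, ...) {
  cat(sprintf("<gxn_partition> %d communities, r = %g, Q = %.4f\n",
              length(unique(x$membership$community)), x$r, x$Q))
  invisible(x)
}

#' Within-community sum of squared errors
#'
#' Total squared deviation of each gene's expression profile from its
#' community's mean profile, summed over communities.  Tighter (more
#' expression-homogeneous) communities give smaller SSE.
#'
#' @param X A `gxn_expression` containing every partitioned gene.
#' @param partition A `gxn_partition` or named membership vector.
#' @return Non-negative SSE.
#' @export
community_sse <- function(X, partition) {
  memb <- if (inherits(partition, "gxn_partition")) {
    stats::setNames(partition$membership$community, partition$membership$node)
  } else partition
  if (!all(names(memb) %in% colnames(X))) {
    stop("partition genes missing from the expression matrix")
  }
  sse <- 0
  for (comm in unique(memb)) {
    genes <- names(memb)[memb == comm]
    prof <- unclass(X)[, genes, drop = FALSE]
    sse <- sse + sum(sweep(prof, 1L, rowMeans(prof), "-")^2)
  }
  sse
}

#' Scan resolutions and pick the SSE elbow
#'
#' Partitions the network at every resolution of `r_grid`, computes the
#' community SSE, smooths the SSE curve with a centered moving average
#' (window 5, truncated at the edges) and locates the elbow with the Kneedle
#' procedure for a decreasing convex curve.  When no knee exists the point of
#' maximum finite-difference curvature is used, with a warning.
#'
#' @param X A `gxn_expression`.
#' @param net A `gxn_network` over genes of `X`.
#' @param r_grid Increasing resolution grid (>= 8 points).
#' @return A `gxn_resolution_scan`: tibble `scan` (`r`, `sse`,
#'   `n_communities`, `smoothed_sse`), chosen `r_star`, the partition at
#'   `r_star`, and `fallback` flag.
#' @export
select_resolution <- function(X, net, r_grid = seq(0.5, 5, by = 0.1)) {
  if (length(r_grid) < 8L) stop("resolution grid needs at least 8 points")
  if (is.unsorted(r_grid, strictly = TRUE)) stop("r_grid must be strictly increasing")
  parts <- lapply(r_grid, function(r) greedy_partition(net, r))
  sse <- vapply(parts, function(p) community_sse(X, p), numeric(1))
  ncomm <- vapply(parts, function(p) length(unique(p$membership$community)), integer(1))
  smoothed <- moving_average(sse, window = 5L)
  knee <- kneedle_decreasing(r_grid, smoothed)
  fallback <- is.null(knee)
  if (fallback) {
    warning("no knee found on the smoothed SSE curve; falling back to maximum curvature")
    curv <- abs(diff(diff(smoothed)))
    knee <- r_grid[which.max(curv) + 1L]
  }
  structure(
    list(scan = tibble::tibble(r = r_grid, sse = sse, n_communities = ncomm,
                               smoothed_sse = smoothed),
         r_star = knee,
         partition = parts[[which(r_grid == knee)[1L]]],
         fallback = fallback),
    class = "gxn_resolution_scan")
}

#' @export
print.gxn_resolution_scan <- function(x, ...) {
  cat(sprintf("<gxn_resolution_scan> %d resolutions, r* = %g%s\n",
              nrow(x$scan), x$r_star,
              if (x$fallback) " (curvature fallback)" else ""))
  invisible(x)
}

# Centered moving average, window truncated at the sequence edges.
moving_average <- function(x, window = 5L) {
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# Kneedle for a decreasing convex curve: flip vertically to an increasing
# concave curve, take the difference from the diagonal, and return the first
# local maximum confirmed by a subsequent drop below its sensitivity
# threshold (S = 1).  NULL when the difference curve never rises above zero.
kneedle_decreasing <- function(x, y) {
  n <- length(x)
  rngx <- diff(range(x)); rngy <- diff(range(y))
  if (rngx == 0 || rngy == 0) return(NULL)
  xn <- (x - min(x)) / rngx
  yn <- (y - min(y)) / rngy
  d <- (1 - yn) - xn
  if (max(d) <= 1e-12) return(NULL)
  is_lmx <- vapply(seq_len(n), function(i) {
    (i == 1L || d[i] >= d[i - 1L]) && (i == n || d[i] > d[i + 1L])
  }, logical(1))
  lmx <- which(is_lmx & d > 0)
  if (!length(lmx)) return(NULL)
  s_thresh <- mean(diff(xn))
  for (i in lmx) {
    thr <- d[i] - s_thresh
    after <- if (i < n) d[(i + 1L):n] else numeric(0)
    if (!length(after) || any(after < thr)) return(x[i])
  }
  x[lmx[which.max(d[lmx])]]
}
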