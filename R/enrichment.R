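#' Rank genes by difference of class means
#'
#' Score of a gene = mean expression in the target-class samples minus mean
#' expression in all remaining samples.  The returned ranking is descending,
#' with ties ordered by gene id so the ranking is deterministic.
#'
#' @param X A `gxn_expression`.
#' @param classes Tibble with columns `condition`, `class` (see
#'   [read_sample_classes()]).
#' @param target_class The class to contrast against the rest.
#' @return Tibble `gene`, `score`, sorted by decreasing score.
#' @export
rank_genes_diff_of_classes <- function(X, classes, target_class) {
  classes <- tibble::as_tibble(classes)
  if (!target_class %in% classes$class) stop("unknown class: ", target_class)
  in_cond <- classes$condition[classes$class == target_class]
  out_cond <- classes$condition[classes$class != target_class]
  if (length(in_cond) < 2 || length(out_cond) < 2) {
    stop("each side of the contrast needs at least 2 samples")
  }
  score <- colMeans(unclass(X)[in_cond, , drop = FALSE]) -
    colMeans(unclass(X)[out_cond, , drop = FALSE])
  out <- tibble::tibble(gene = colnames(X), score = unname(score))
  out[order(-out$score, out$gene), ]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running-sum statistic with weight exponent 1: walking down the
#' ranking, hits increment the sum proportionally to `|score|` (normalized
#' over the set), misses decrement it by `1/(n - |set|)`; the enrichment score
#' is the extremum of the running sum (signed).
#'
#' @param ranked Tibble `gene`, `score` in ranking order (e.g. from
#'   [rank_genes_diff_of_classes()]).
#' @param gene_set Character vector of gene ids.
#' @return ES in \[-1, 1\].
#' @export
enrichment_score <- function(ranked, gene_set) {
  hit <- ranked$gene %in% gene_set
  k <- sum(hit)
  n <- nrow(ranked)
  if (k == 0L || k == n) stop("gene set must intersect the ranking strictly")
  es_from_hits(abs(ranked$score), which(hit), n)
}

# Core running-sum extremum given hit positions; evaluated only at positions
# adjacent to hits (the extrema of the piecewise-linear sum live there).
es_from_hits <- function(abs_scores, hit_idx, n) {
  k <- length(hit_idx)
  w <- abs_scores[hit_idx]
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else rep(1 / k, k)    # all-zero scores: unweighted
  cum_hit <- cumsum(inc)
  miss_step <- 1 / (n - k)
  miss_before <- (hit_idx - seq_len(k)) * miss_step     # misses preceding each hit
  after <- cum_hit - miss_before                        # sum just after each hit
  before <- c(0, cum_hit[-k]) - miss_before             # sum just before each hit
  lo <- min(before, after, 0)
  hi <- max(before, after, 0)
  if (hi >= -lo) hi else lo
}

#' Community-level GSEA against sample classes
#'
#' For every (community, class) pair, genes are ranked by
#' [rank_genes_diff_of_classes()] and the community's enrichment score is
#' tested against a gene-set permutation null: `n_perm` size-matched random
#' sets drawn from the ranked universe.  The p-value is the
#' `(b + 1) / (m + 1)` rank of `|ES|` among same-sign null scores, NES is
#' `ES` divided by the mean `|null ES|` of the same sign, and FDR is
#' Benjamini-Hochberg across all tested pairs.
#'
#' @param X A `gxn_expression`.
#' @param classes Tibble `condition`, `class` (>= 2 classes).
#' @param partition A `gxn_partition` or named membership vector.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param min_size Minimum community size tested.
#' @param filter Keep only rows with `p < 0.05` and `fdr < 0.05` (the
#'   reporting convention); set `FALSE` to return every tested pair.
#' @return Tibble `community`, `class`, `es`, `nes`, `p`, `fdr`, `direction`.
#' @export
gsea_community_test <- function(X, classes, partition, n_perm = 10000L,
                                seed = 1L, min_size = 3L, filter = TRUE) {
  if (n_perm < 100L) stop("n_perm below 100 gives an unstable permutation null")
  classes <- tibble::as_tibble(classes)
  if (length(unique(classes$class)) < 2L) stop("need at least 2 classes")
  memb <- if (inherits(partition, "gxn_partition")) {
    stats::setNames(partition$membership$community, partition$membership$node)
  } else partition
  memb <- memb[names(memb) %in% colnames(X)]
  comms <- split(names(memb), memb)
  comms <- comms[vapply(comms, length, integer(1)) >= min_size]
  rows <- list()
  for (cls in sort(unique(classes$class))) {
    ranked <- rank_genes_diff_of_classes(X, classes, cls)
    abs_scores <- abs(ranked$score)
    n <- nrow(ranked)
    null_cache <- new.env(parent = emptyenv())
    for (ci in seq_along(comms)) {
      genes <- intersect(comms[[ci]], ranked$gene)
      k <- length(genes)
      if (k < min_size || k >= n) next
      es <- es_from_hits(abs_scores, sort(which(ranked$gene %in% genes)), n)
      key <- as.character(k)
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- with_seed_local(
          derive_gene_seed(seed, k) + match(cls, sort(unique(classes$class))),
          replicate(n_perm, es_from_hits(abs_scores, sort(sample.int(n, k)), n)))
      }
      null_es <- null_cache[[key]]
      same <- null_es[sign(null_es) == sign(es)]
      p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        community = names(comms)[ci], class = cls, es = es, nes = nes, p = p,
        direction = if (es >= 0) "over" else "under")
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(tibble::tibble(community = character(), class = character(),
                                        es = numeric(), nes = numeric(), p = numeric(),
                                        fdr = numeric(), direction = character()))
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("community", "class", "es", "nes", "p", "fdr", "direction")]
  if (filter) out <- out[out$p < 0.05 & out$fdr < 0.05, , drop = FALSE]
  out
}

#' Transitive descendants of an ontology term
#'
#' @param annotations A `gxn_annotations`.
#' @param root_term Term id.
#' @return Character vector of strict descendants (root excluded).
#' @export
term_descendants <- function(annotations, root_term) {
  parents <- annotations$parents
  children_of <- split(parents$term, parents$parent)
  seen <- character(0)
  frontier <- root_term
  while (length(frontier)) {
    kids <- unique(unlist(children_of[frontier], use.names = FALSE))
    kids <- setdiff(kids, c(seen, root_term))
    seen <- c(seen, kids)
    frontier <- kids
  }
  seen
}

#' GO-style over-representation test for a community
#'
#' One-sided hypergeometric test of each term's annotation count in the
#' community (study set) against the population, Benjamini-Hochberg corrected
#' across all tested terms; reported terms are restricted to strict
#' descendants of `root_term` and, by default, to `p < 0.05` and
#' `fdr < 0.05`.
#'
#' @param community_genes Character vector (study set).
#' @param population_genes Character vector containing the study set.
#' @param annotations A `gxn_annotations`.
#' @param root_term Term id whose descendants are reportable (e.g.
#'   `"GO:0048856"` for anatomical development, `"GO:0008150"` for any
#'   biological process).
#' @param filter Apply the significance filter (default `TRUE`).
#' @return Tibble `term`, `study_count`, `study_size`, `pop_count`,
#'   `pop_size`, `p`, `fdr`.
#' @export
go_overrepresentation <- function(community_genes, population_genes,
                                  annotations, root_term, filter = TRUE) {
  if (!all(community_genes %in% population_genes)) {
    stop("community genes must be contained in the population")
  }
  g2t <- annotations$gene2term
  g2t <- g2t[g2t$gene %in% population_genes, , drop = FALSE]
  if (!nrow(g2t)) stop("no population gene carries an annotation")
  study_size <- length(unique(community_genes))
  pop_size <- length(unique(population_genes))
  per_term <- split(g2t$gene, g2t$term)
  rows <- purrr::map2_dfr(per_term, names(per_term), function(genes, term) {
    pop_count <- length(unique(genes))
    study_count <- length(intersect(genes, community_genes))
    p <- stats::phyper(study_count - 1L, pop_count, pop_size - pop_count,
                       study_size, lower.tail = FALSE)
    tibble::tibble(term = term, study_count = study_count,
                   study_size = study_size, pop_count = pop_count,
                   pop_size = pop_size, p = p)
  })
  rows$fdr <- stats::p.adjust(rows$p, method = "BH")
  keep_terms <- term_descendants(annotations, root_term)
  rows <- rows[rows$term %in% keep_terms, , drop = FALSE]
  if (filter) rows <- rows[rows$p < 0.05 & rows$fdr < 0.05, , drop = FALSE]
  rows[order(rows$p, rows$term), ]
}
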