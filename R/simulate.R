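#' Describe a planted union-of-subspaces scenario
#'
#' The generator emulates the structural assumptions of self-expressive
#' network inference: genes live in a union of low-dimensional expression
#' subspaces (blocks), each target gene is a sparse linear combination of
#' regulators from its own block, and the planted support doubles as a dense
#' gold standard.
#'
#' @param n_blocks Number of expression subspaces.
#' @param regulators_per_block Integer scalar or vector (one per block).
#' @param targets_per_block Integer scalar or vector.
#' @param D Number of conditions.
#' @param support_size True regulators per target gene.
#' @param coef_range Absolute coefficient magnitudes are drawn uniformly in
#'   this range (bounded away from zero) with random signs.
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   targets.
#' @param seed Integer seed.
#' @return A list of class `gxn_scenario`.
#' @export
planted_scenario <- function(n_blocks = 3L, regulators_per_block = c(7L, 7L, 6L),
                             targets_per_block = 10L, D = 200L,
                             support_size = 3L, coef_range = c(0.5, 1.5),
                             noise_sd = 0.1, seed = 1L) {
  regulators_per_block <- rep_len(regulators_per_block, n_blocks)
  targets_per_block <- rep_len(targets_per_block, n_blocks)
  stopifnot(all(regulators_per_block >= 2), D >= 2 * support_size,
            all(support_size <= regulators_per_block),
            coef_range[1] > 0, coef_range[2] >= coef_range[1])
  structure(list(n_blocks = as.integer(n_blocks),
                 regulators_per_block = as.integer(regulators_per_block),
                 targets_per_block = as.integer(targets_per_block),
                 D = as.integer(D), support_size = as.integer(support_size),
                 coef_range = coef_range, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "gxn_scenario")
}

#' Simulate union-of-subspaces expression data with a planted network
#'
#' Each block's regulators are built from independent standard-normal latent
#' profiles mixed by a random full-rank matrix (block rank = number of block
#' regulators); each target gene is a sparse signed linear combination of
#' `support_size` regulators from its own block plus Gaussian noise.  The
#' planted support is returned both as a coefficient matrix `C_true` and as a
#' dense gold standard.
#'
#' @param scenario A [planted_scenario()].
#' @return List with `expression` (`gxn_expression`), `regulators`
#'   (character), `gold` (`gxn_gold`, dense), `blocks` (tibble `gene`,
#'   `block`, `role`) and `C_true` (regulators x genes matrix).
#' @export
simulate_subspace_expression <- function(scenario) {
  s <- scenario
  with_seed_local(s$seed, {
    reg_ids <- list(); tgt_ids <- list()
    reg_cols <- list(); tgt_cols <- list()
    supports <- list()
    for (b in seq_len(s$n_blocks)) {
      kr <- s$regulators_per_block[b]
      kt <- s$targets_per_block[b]
      ids_r <- sprintf("B%d_R%d", b, seq_len(kr))
      ids_t <- if (kt > 0) sprintf("B%d_T%d", b, seq_len(kt)) else character(0)
      latent <- matrix(stats::rnorm(s$D * kr), s$D, kr)
      # well-conditioned mixing: full block rank and mild regulator correlation
      # while keeping the planted supports identifiable by sparse regression
      mixing <- diag(kr) + matrix(stats::rnorm(kr * kr, sd = 0.3 / sqrt(kr)), kr, kr)
      regs <- latent %*% mixing
      colnames(regs) <- ids_r
      tgts <- matrix(0, s$D, kt, dimnames = list(NULL, ids_t))
      for (t in seq_len(kt)) {
        sup <- sample(ids_r, s$support_size)
        coefs <- stats::runif(s$support_size, s$coef_range[1], s$coef_range[2]) *
          sample(c(-1, 1), s$support_size, replace = TRUE)
        tgts[, t] <- regs[, sup, drop = FALSE] %*% coefs +
          stats::rnorm(s$D, sd = s$noise_sd)
        supports[[ids_t[t]]] <- stats::setNames(coefs, sup)
      }
      reg_ids[[b]] <- ids_r; tgt_ids[[b]] <- ids_t
      reg_cols[[b]] <- regs; tgt_cols[[b]] <- tgts
    }
    regulators <- unlist(reg_ids)
    targets <- unlist(tgt_ids)
    vals <- cbind(do.call(cbind, reg_cols), do.call(cbind, tgt_cols))
    X <- expression_matrix(vals, gene_ids = colnames(vals))
    C_true <- matrix(0, length(regulators), ncol(vals),
                     dimnames = list(regulators, colnames(vals)))
    for (g in names(supports)) C_true[names(supports[[g]]), g] <- supports[[g]]
    edges <- tibble::tibble(
      tf = unlist(lapply(supports, names), use.names = FALSE),
      target = rep(names(supports), vapply(supports, length, integer(1))))
    gold <- gold_standard(edges$tf, edges$target, rep(1L, nrow(edges)), dense = TRUE)
    # gold universe: every regulator x gene pair counts as tested
    gold$tested_tfs <- regulators
    gold$tested_genes <- colnames(vals)
    blocks <- tibble::tibble(
      gene = c(unlist(reg_ids), unlist(tgt_ids)),
      block = c(rep(seq_len(s$n_blocks), s$regulators_per_block),
                rep(seq_len(s$n_blocks), s$targets_per_block)),
      role = c(rep("regulator", sum(s$regulators_per_block)),
               rep("target", sum(s$targets_per_block))))
    list(expression = X, regulators = regulators, gold = gold,
         blocks = blocks, C_true = C_true)
  })
}

#' Overlay a two-class contrast on simulated expression
#'
#' Splits the conditions 50/50 into classes `"class1"` / `"class2"` (after a
#' seeded shuffle) and adds `effect` to the member genes in class-1 samples.
#'
#' @param X A `gxn_expression` with at least 4 conditions.
#' @param effect Additive shift applied to member genes in class 1.
#' @param member_genes Character vector of genes carrying the effect.
#' @param seed Integer seed.
#' @return List with `expression` (shifted copy) and `classes` (tibble
#'   `condition`, `class`).
#' @export
simulate_two_class <- function(X, effect, member_genes, seed = 1L) {
  if (nrow(X) < 4L) stop("need at least 4 conditions for a two-class split")
  stopifnot(all(member_genes %in% colnames(X)))
  ord <- sample_with_seed(seed, nrow(X))
  half <- nrow(X) %/% 2L
  cls <- rep("class2", nrow(X))
  cls[ord[seq_len(half)]] <- "class1"
  Xp <- unclass(X)
  Xp[cls == "class1", member_genes] <- Xp[cls == "class1", member_genes] + effect
  list(expression = expression_matrix(Xp),
       classes = tibble::tibble(condition = rownames(X), class = cls))
}

#' Simulate a block-aligned annotation table
#'
#' One "true" term per block annotating that block's genes (plus a fraction
#' of random leakage genes), `n_noise_terms` terms annotating random gene
#' sets, and a two-level parent graph: block terms under `SYN:DEV`, noise
#' terms under `SYN:OTHER`, both under the synthetic root `SYN:ROOT`.
#'
#' @param blocks Tibble `gene`, `block` (as returned by
#'   [simulate_subspace_expression()]); may have zero rows.
#' @param n_noise_terms Number of random noise terms.
#' @param seed Integer seed.
#' @param leakage Fraction of off-block genes added to each block term.
#' @return A `gxn_annotations`.
#' @export
simulate_annotations <- function(blocks, n_noise_terms = 5L, seed = 1L,
                                 leakage = 0.1) {
  blocks <- tibble::as_tibble(blocks)
  with_seed_local(seed, {
    g2t <- list()
    block_terms <- character(0)
    if (nrow(blocks)) {
      for (b in sort(unique(blocks$block))) {
        term <- sprintf("SYN:BLOCK%04d", b)
        block_terms <- c(block_terms, term)
        genes <- blocks$gene[blocks$block == b]
        others <- setdiff(blocks$gene, genes)
        n_leak <- min(length(others), round(leakage * length(genes)))
        leak <- if (n_leak > 0) sample(others, n_leak) else character(0)
        g2t[[term]] <- c(genes, leak)
      }
    }
    noise_terms <- if (n_noise_terms > 0) sprintf("SYN:NOISE%04d", seq_len(n_noise_terms)) else character(0)
    pool <- unique(blocks$gene)
    for (term in noise_terms) {
      size <- max(1L, min(length(pool), stats::rpois(1, 5) + 1L))
      g2t[[term]] <- if (length(pool)) sample(pool, size) else character(0)
    }
    g2t <- g2t[vapply(g2t, length, integer(1)) > 0]
    gene2term <- if (length(g2t)) {
      tibble::tibble(gene = unlist(g2t, use.names = FALSE),
                     term = rep(names(g2t), vapply(g2t, length, integer(1))))
    } else {
      tibble::tibble(gene = character(), term = character())
    }
    parents <- tibble::tibble(
      term = c(block_terms, noise_terms, "SYN:DEV", "SYN:OTHER"),
      parent = c(rep("SYN:DEV", length(block_terms)),
                 rep("SYN:OTHER", length(noise_terms)),
                 "SYN:ROOT", "SYN:ROOT"))
    annotation_table(gene2term, parents)
  })
}
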