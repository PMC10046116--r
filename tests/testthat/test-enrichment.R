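# straight-line running-sum evaluation, independent of the package internals
es_bruteforce <- function(scores, hit) {
  n <- length(scores)
  k <- sum(hit)
  sw <- sum(abs(scores[hit]))
  run <- 0; lo <- 0; hi <- 0
  for (i in seq_len(n)) {
    run <- if (hit[i]) run + abs(scores[i]) / sw else run - 1 / (n - k)
    lo <- min(lo, run); hi <- max(hi, run)
  }
  if (hi >= -lo) hi else lo
}

two_class_fixture <- function(D = 24, n_genes = 30, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(D * n_genes), D, n_genes,
                   dimnames = list(NULL, sprintf("g%02d", seq_len(n_genes))))
    X <- expression_matrix(vals)
  })
  classes <- tibble::tibble(condition = rownames(X),
                            class = rep(c("tissueA", "tissueB"), length.out = D))
  list(X = X, classes = classes)
}

test_that("difference-of-classes ranking matches per-gene mean contrasts", {
  fx <- two_class_fixture(seed = 2)
  ranked <- rank_genes_diff_of_classes(fx$X, fx$classes, "tissueA")
  inA <- fx$classes$condition[fx$classes$class == "tissueA"]
  outA <- fx$classes$condition[fx$classes$class != "tissueA"]
  g <- ranked$gene[5]
  expect_equal(ranked$score[5],
               mean(unclass(fx$X)[inA, g]) - mean(unclass(fx$X)[outA, g]))
  expect_true(all(diff(ranked$score) <= 0))

  # permuting sample order leaves scores untouched
  perm <- withr::with_seed(9, sample.int(nrow(fx$X)))
  Xp <- expression_matrix(unclass(fx$X)[perm, ],
                          condition_ids = rownames(fx$X)[perm])
  ranked_p <- rank_genes_diff_of_classes(Xp, fx$classes, "tissueA")
  expect_equal(ranked_p, ranked)

  # constant-difference gene scores zero; tiny classes error
  expect_error(rank_genes_diff_of_classes(
    fx$X, tibble::tibble(condition = rownames(fx$X),
                         class = c("a", rep("b", nrow(fx$X) - 1))), "a"),
    "at least 2")
})

test_that("the enrichment score matches a brute-force running sum", {
  fx <- two_class_fixture(seed = 3)
  ranked <- rank_genes_diff_of_classes(fx$X, fx$classes, "tissueA")
  for (s in 1:20) {
    set_genes <- withr::with_seed(s, sample(ranked$gene, sample(3:8, 1)))
    es <- enrichment_score(ranked, set_genes)
    expect_equal(es, es_bruteforce(ranked$score, ranked$gene %in% set_genes))
    expect_gte(es, -1); expect_lte(es, 1)
    # invariant under positive rescaling of the ranking scores
    ranked2 <- ranked; ranked2$score <- 7.3 * ranked2$score
    expect_equal(enrichment_score(ranked2, set_genes), es)
  }
  # top-k set with positive scores saturates at +1
  topk <- ranked$gene[1:4]
  stopifnot(all(ranked$score[1:4] > 0))
  expect_equal(enrichment_score(ranked, topk), 1)
  # bottom-k set reaches the -1 extreme symmetrically
  expect_equal(enrichment_score(ranked, ranked$gene[(nrow(ranked) - 3):nrow(ranked)]), -1)
  expect_error(enrichment_score(ranked, character(0)), "intersect")
})

test_that("the enrichment score agrees with the fgsea statistic", {
  skip_if_not_installed("fgsea")
  fx <- two_class_fixture(seed = 5)
  ranked <- rank_genes_diff_of_classes(fx$X, fx$classes, "tissueA")
  stats_vec <- stats::setNames(ranked$score, ranked$gene)
  for (s in 1:10) {
    set_genes <- withr::with_seed(40 + s, sample(ranked$gene, 5))
    ours <- enrichment_score(ranked, set_genes)
    ref <- fgsea::calcGseaStat(stats_vec,
                               selectedStats = which(ranked$gene %in% set_genes),
                               gseaParam = 1)
    if (ref == 0) {
      # fgsea reports 0 when the positive and negative extremes tie exactly;
      # we keep the signed extremum, so compare magnitudes via both extremes
      ext <- fgsea::calcGseaStat(stats_vec,
                                 selectedStats = which(ranked$gene %in% set_genes),
                                 gseaParam = 1, returnAllExtremes = TRUE)
      expect_equal(abs(ours), max(ext$tops, -ext$bottoms), tolerance = 1e-12)
    } else {
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  }
})

test_that("planted over-expression is detected with the right direction", {
  fx <- two_class_fixture(D = 40, n_genes = 40, seed = 7)
  members <- sprintf("g%02d", 1:8)
  shifted <- unclass(fx$X)
  inA <- fx$classes$class == "tissueA"
  shifted[inA, members] <- shifted[inA, members] + 2
  Xs <- expression_matrix(shifted)
  membership <- stats::setNames(rep(1:5, each = 8), colnames(Xs))
  res <- gsea_community_test(Xs, fx$classes, membership, n_perm = 500,
                             seed = 11, filter = FALSE)
  hit <- res[res$community == "1" & res$class == "tissueA", ]
  expect_equal(hit$direction, "over")
  expect_lt(hit$p, 0.05)
  expect_gt(hit$nes, 1)
})

test_that("permutation p-values are calibrated under a label shuffle", {
  raw_p <- c()
  for (s in 1:5) {
    fx <- two_class_fixture(D = 20, n_genes = 100, seed = 60 + s)
    membership <- stats::setNames(rep(1:10, each = 10), colnames(fx$X))
    res <- gsea_community_test(fx$X, fx$classes, membership, n_perm = 500,
                               seed = s, filter = FALSE)
    raw_p <- c(raw_p, res$p)
  }
  expect_gt(length(raw_p), 50)
  expect_lt(abs(mean(raw_p < 0.05) - 0.05), 0.04)
  expect_true(all(raw_p > 0))
})

test_that("permutation counts below 100 are rejected", {
  fx <- two_class_fixture(seed = 13)
  membership <- stats::setNames(rep(1:3, each = 10), colnames(fx$X))
  expect_error(gsea_community_test(fx$X, fx$classes, membership, n_perm = 10),
               "unstable")
})

test_that("hypergeometric over-representation matches exact combinatorics", {
  # study 8 of 10 annotated vs population 10 of 100
  population <- sprintf("p%03d", 1:100)
  annotated <- population[1:10]
  community <- c(population[1:8], population[95:96])
  ann <- annotation_table(
    tibble::tibble(gene = annotated, term = "T:DEV1"),
    tibble::tibble(term = "T:DEV1", parent = "T:ROOT"))
  res <- go_overrepresentation(community, population, ann, "T:ROOT",
                               filter = FALSE)
  exact <- sum(sapply(8:10, function(i) {
    choose(10, i) * choose(90, 10 - i) / choose(100, 10)
  }))
  expect_equal(res$p, exact, tolerance = 1e-12)
  expect_equal(res$study_count, 8L)

  # a root with no annotated descendants reports nothing
  lonely <- annotation_table(tibble::tibble(gene = annotated, term = "T:DEV1"),
                             tibble::tibble(term = "T:DEV1", parent = "T:ROOT"))
  expect_equal(nrow(go_overrepresentation(community, population, lonely,
                                          "T:ELSEWHERE", filter = FALSE)), 0L)
  expect_error(go_overrepresentation(c(community, "zzz"), population, ann,
                                     "T:ROOT"), "contained")
})

test_that("random communities rarely pass the over-representation filter", {
  sim <- simulate_subspace_expression(
    planted_scenario(D = 30, regulators_per_block = 5, targets_per_block = 10,
                     seed = 3))
  ann <- simulate_annotations(sim$blocks[, c("gene", "block")],
                              n_noise_terms = 5, seed = 3)
  population <- sim$blocks$gene
  clean <- 0L
  for (s in 1:20) {
    community <- withr::with_seed(200 + s, sample(population, 10))
    res <- go_overrepresentation(community, population, ann, "SYN:ROOT")
    if (nrow(res) == 0L) clean <- clean + 1L
  }
  expect_gte(clean, 19L)
})

test_that("BH correction preserves the p-value ordering", {
  fx <- two_class_fixture(D = 20, n_genes = 60, seed = 90)
  membership <- stats::setNames(rep(1:6, each = 10), colnames(fx$X))
  res <- gsea_community_test(fx$X, fx$classes, membership, n_perm = 200,
                             seed = 2, filter = FALSE)
  expect_equal(order(res$p), order(res$fdr, res$p))
})
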