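#' Restrict predicted links to the experimentally tested universe
#'
#' Mirrors the DREAM5 evaluation protocol: predicted links whose regulator or
#' target was never tested are discarded; tested pairs the prediction omits
#' are appended with score 0 so the ranking covers the whole tested universe.
#' Under the dense convention the universe is every tested-TF x tested-gene
#' pair minus self-loops; otherwise it is the pairs the gold file lists.
#'
#' @param links Tibble/data frame with columns `regulator` (or `tf`),
#'   `target`, and a score column (`score` or `coefficient`; coefficients are
#'   scored by absolute value since gold standards are unsigned).
#' @param gold A `gxn_gold`.
#' @return Tibble `tf`, `target`, `score`, `label`, ordered by decreasing
#'   score.
#' @export
restrict_to_tested <- function(links, gold) {
  if (!inherits(gold, "gxn_gold")) stop("`gold` must be a gxn_gold")
  if (nrow(gold$true_links) == 0L) stop("gold standard has no positive links")
  links <- tibble::as_tibble(links)
  if (!"tf" %in% names(links) && "regulator" %in% names(links)) {
    names(links)[names(links) == "regulator"] <- "tf"
  }
  if (!"score" %in% names(links)) {
    if ("coefficient" %in% names(links)) {
      links$score <- abs(links$coefficient)
    } else stop("links need a `score` or `coefficient` column")
  }
  links <- links[, c("tf", "target", "score")]
  if (anyDuplicated(links[, c("tf", "target")])) stop("duplicate predicted links")

  universe <- if (gold$dense) {
    tidyr::expand_grid(tf = gold$tested_tfs, target = gold$tested_genes)
  } else {
    gold$declared[, c("tf", "target")]
  }
  universe <- universe[universe$tf != universe$target, , drop = FALSE]
  pos_key <- paste(gold$true_links$tf, gold$true_links$target, sep = "\r")
  universe$label <- as.integer(paste(universe$tf, universe$target, sep = "\r") %in% pos_key)

  merged <- dplyr::left_join(universe, links, by = c("tf", "target"))
  merged$score[is.na(merged$score)] <- 0
  merged <- merged[order(-merged$score, merged$tf, merged$target), ]
  tibble::as_tibble(merged[, c("tf", "target", "score", "label")])
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation (probability that a random positive outscores a
#' random negative); tied scores contribute 1/2.
#'
#' @param labeled Tibble with columns `score` and `label`, or a numeric score
#'   vector when `label` is given separately.
#' @param label Optional 0/1 vector.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labeled, label = NULL) {
  sl <- as_score_label(labeled, label)
  n1 <- sum(sl$label == 1); n0 <- sum(sl$label == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes present")
  r <- rank(sl$score, ties.method = "average")
  (sum(r[sl$label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: precision times recall increment summed at
#' each positive, with tied scores processed as one block (precision taken at
#' the end of the block).
#'
#' @inheritParams auroc
#' @return AUPR in (0, 1\].
#' @export
aupr <- function(labeled, label = NULL) {
  sl <- as_score_label(labeled, label)
  npos <- sum(sl$label == 1)
  if (npos == 0) stop("AUPR needs at least one positive")
  ord <- order(-sl$score)
  s <- sl$score[ord]; y <- sl$label[ord]
  grp <- cumsum(!duplicated(s))
  tp_grp <- tapply(y, grp, sum)
  n_grp <- tapply(y, grp, length)
  tp_cum <- cumsum(tp_grp)
  n_cum <- cumsum(n_grp)
  prec <- tp_cum / n_cum
  d_recall <- tp_grp / npos
  sum(prec * d_recall)
}

as_score_label <- function(labeled, label) {
  if (is.null(label)) {
    labeled <- tibble::as_tibble(labeled)
    list(score = labeled$score, label = labeled$label)
  } else {
    list(score = as.numeric(labeled), label = as.integer(label))
  }
}

#' Positive prevalence of a dense gold standard
#'
#' `|Egold| / |Egoldfull|` with the full tested universe
#' `|tested TFs| * |tested genes| - |tested TFs|` (self-loops excluded,
#' tested TFs being tested genes too).
#'
#' @param gold A dense `gxn_gold`.
#' @return Fraction in \[0, 1\].
#' @export
class_imbalance <- function(gold) {
  if (!gold$dense) stop("class imbalance is defined for dense gold standards")
  full <- length(gold$tested_tfs) * length(gold$tested_genes) -
    sum(gold$tested_tfs %in% gold$tested_genes)
  if (full == 0) stop("empty tested universe")
  nrow(gold$true_links) / full
}

#' Score a model against a gold standard
#'
#' Ranks the model's links by absolute coefficient, restricts them to the
#' tested universe and computes AUROC and AUPR.
#'
#' @param model A `gxn_model` or an edge tibble.
#' @param gold A `gxn_gold`.
#' @return One-row tibble: `auroc`, `aupr`, `n_pos`, `n_tested`.
#' @export
evaluate_against_gold <- function(model, gold) {
  edges <- if (inherits(model, "gxn_model")) generics::tidy(model) else
    tibble::as_tibble(model)
  labeled <- restrict_to_tested(edges, gold)
  tibble::tibble(auroc = auroc(labeled), aupr = aupr(labeled),
                 n_pos = sum(labeled$label == 1), n_tested = nrow(labeled))
}
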