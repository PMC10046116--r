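#' Construct an expression matrix
#'
#' The package stores expression data as a plain numeric matrix in a fixed
#' internal orientation: conditions (samples) as rows, genes as columns.
#' Row names are condition identifiers, column names gene identifiers.
#'
#' @param values Numeric matrix, conditions x genes.
#' @param condition_ids Character vector of unique condition identifiers
#'   (defaults to existing row names, else `cond1..condD`).
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   existing column names).
#'
#' @return A numeric matrix of class `gxn_expression`.
#' @export
expression_matrix <- function(values, condition_ids = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(condition_ids)) {
    condition_ids <- rownames(values) %||% paste0("cond", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values) %||% paste0("g", seq_len(ncol(values)))
  }
  stopifnot(length(condition_ids) == nrow(values), length(gene_ids) == ncol(values))
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(condition_ids)) stop("duplicate condition ids")
  if (!all(is.finite(values))) stop("expression values must all be finite")
  dimnames(values) <- list(as.character(condition_ids), as.character(gene_ids))
  class(values) <- c("gxn_expression", "matrix", "array")
  values
}

#' @export
print.gxn_expression <- function(x, ...) {
  cat(sprintf("<gxn_expression> %d conditions x %d genes\n", nrow(x), ncol(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-separated expression matrix
#'
#' Expects the DREAM5 layout by default: one header row of gene identifiers
#' and one row per condition.  Transposed exports (genes as rows, first column
#' holding the gene ids) are handled through `orientation`; `"auto"` keeps the
#' file orientation unless the table is taller than wide *and* its header
#' overlaps a supplied regulator vocabulary, in which case it transposes.
#'
#' @param path Path to a TSV file with a single header row and numeric body.
#' @param orientation One of `"conditions_by_genes"`, `"genes_by_conditions"`,
#'   `"auto"`.
#' @param regulators Optional character vector used by `"auto"` to recognise
#'   gene identifiers.
#'
#' @return A `gxn_expression` matrix with attribute `"orientation_used"`.
#' @export
read_expression <- function(path,
                            orientation = c("conditions_by_genes",
                                            "genes_by_conditions", "auto"),
                            regulators = NULL) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) == 0L) stop("empty expression file: ", path)

  genes_as_rows <- orientation == "genes_by_conditions"
  if (orientation == "auto") {
    header_hits <- if (is.null(regulators)) 0 else mean(colnames(raw) %in% regulators)
    first_col_ids <- suppressWarnings(all(is.na(as.numeric(raw[[1L]]))))
    genes_as_rows <- first_col_ids && nrow(raw) > ncol(raw) && header_hits < 0.5
  }

  if (genes_as_rows) {
    gene_ids <- as.character(raw[[1L]])
    body <- raw[, -1L, drop = FALSE]
    vals <- parse_numeric_body(body, row_labels = gene_ids)
    mat <- t(vals)
    out <- expression_matrix(mat, condition_ids = colnames(body), gene_ids = gene_ids)
  } else {
    vals <- parse_numeric_body(raw, row_labels = paste0("cond", seq_len(nrow(raw))))
    out <- expression_matrix(vals, condition_ids = rownames(vals), gene_ids = colnames(raw))
  }
  attr(out, "orientation_used") <-
    if (genes_as_rows) "genes_by_conditions" else "conditions_by_genes"
  out
}

# Strict numeric parsing with cell-level error reporting.
parse_numeric_body <- function(df, row_labels) {
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(row_labels, colnames(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at (row %d, column %s): '%s'",
                   bad[1L], colnames(df)[j], df[[j]][bad[1L]]))
    }
    mat[, j] <- v
  }
  mat
}

#' Read a regulator list
#'
#' One gene identifier per line.  If `expression` is supplied, identifiers
#' absent from the expression matrix are dropped with a warning.
#'
#' @param path Path to the list file.
#' @param expression Optional `gxn_expression` to intersect against.
#' @return Character vector of regulator ids.
#' @export
read_regulators <- function(path, expression = NULL) {
  ids <- scan(path, what = character(), sep = "\n", quiet = TRUE)
  ids <- unique(trimws(ids))
  ids <- ids[nzchar(ids)]
  if (!is.null(expression)) {
    missing <- setdiff(ids, colnames(expression))
    if (length(missing)) {
      warning(length(missing), " regulator(s) absent from the expression matrix dropped: ",
              paste(utils::head(missing, 5L), collapse = ", "))
      ids <- intersect(ids, colnames(expression))
    }
  }
  if (!length(ids)) stop("regulator set is empty after intersection")
  ids
}

#' Read a gold-standard edge list
#'
#' Three tab-separated columns: regulator, target, label in \{0, 1\}.  Rows
#' with label 1 are true links; every row contributes to the tested universe.
#' Self-loop rows are dropped with a warning.  Under the default dense
#' convention all regulator-target pairs within the tested sets count as
#' experimentally tested, so unlisted pairs are negatives; with
#' `dense = FALSE` only rows listed with label 0 are negatives.
#'
#' @param path Path to the TSV file (no header).
#' @param dense Logical; treat the tested universe as the full cross product
#'   of tested regulators and tested genes (minus self-loops).
#' @return An object of class `gxn_gold` with elements `true_links` (tibble
#'   `tf`, `target`), `tested_tfs`, `tested_genes`, `declared` and `dense`.
#' @export
read_gold_standard <- function(path, dense = TRUE) {
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t",
                      colClasses = c("character", "character", "character"),
                      stringsAsFactors = FALSE),
    error = function(e) data.frame(V1 = character(), V2 = character(), V3 = character())
  )
  if (ncol(df) >= 3L) names(df)[1:3] <- c("tf", "target", "label") else {
    df <- data.frame(tf = character(), target = character(), label = character())
  }
  gold_standard(df$tf, df$target, df$label, dense = dense)
}

#' Construct a gold standard from vectors
#'
#' @param tf,target,label Parallel vectors: regulator id, target id, 0/1 label.
#' @param dense See [read_gold_standard()].
#' @return A `gxn_gold` object.
#' @export
gold_standard <- function(tf, target, label, dense = TRUE) {
  label_num <- suppressWarnings(as.numeric(label))
  if (length(label_num) && (any(is.na(label_num)) || !all(label_num %in% c(0, 1)))) {
    stop("gold-standard labels must be 0 or 1")
  }
  d <- tibble::tibble(tf = as.character(tf), target = as.character(target),
                      label = as.integer(label_num))
  self <- d$tf == d$target
  if (any(self)) {
    warning(sum(self), " self-loop row(s) dropped from gold standard")
    d <- d[!self, , drop = FALSE]
  }
  d <- dplyr::distinct(d)
  structure(
    list(
      true_links = dplyr::select(dplyr::filter(d, .data$label == 1L), "tf", "target"),
      tested_tfs = sort(unique(d$tf)),
      tested_genes = sort(unique(c(d$tf, d$target))),
      declared = d,
      dense = isTRUE(dense)
    ),
    class = "gxn_gold"
  )
}

#' @export
print.gxn_gold <- function(x, ...) {
  cat(sprintf("<gxn_gold> %d true links, %d tested TFs x %d tested genes (%s)\n",
              nrow(x$true_links), length(x$tested_tfs), length(x$tested_genes),
              if (x$dense) "dense" else "listed-negatives"))
  invisible(x)
}

#' Read sample class labels
#'
#' Two tab-separated columns (condition id, class label), no header.
#'
#' @param path Path to the TSV file.
#' @param expression Optional `gxn_expression`; labels are checked against its
#'   condition ids.
#' @return Tibble with columns `condition`, `class`.
#' @export
read_sample_classes <- function(path, expression = NULL) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  out <- tibble::tibble(condition = df[[1L]], class = df[[2L]])
  if (!is.null(expression)) {
    unknown <- setdiff(out$condition, rownames(expression))
    if (length(unknown)) stop("sample-class conditions absent from expression matrix: ",
                              paste(utils::head(unknown, 5L), collapse = ", "))
  }
  out
}

#' Construct an annotation table
#'
#' @param gene2term Data frame with columns `gene`, `term`.
#' @param parents Data frame with columns `term`, `parent` describing an
#'   acyclic is-a graph.
#' @return Object of class `gxn_annotations`.
#' @export
annotation_table <- function(gene2term, parents) {
  gene2term <- tibble::as_tibble(gene2term)[, c("gene", "term")]
  parents <- tibble::as_tibble(parents)[, c("term", "parent")]
  assert_acyclic(parents)
  structure(list(gene2term = dplyr::distinct(gene2term),
                 parents = dplyr::distinct(parents)),
            class = "gxn_annotations")
}

#' Read annotations from TSV files
#'
#' @param gene2term_path TSV (gene, term), no header.
#' @param parents_path TSV (term, parent), no header.
#' @return A `gxn_annotations` object.
#' @export
read_annotations <- function(gene2term_path, parents_path) {
  g2t <- utils::read.delim(gene2term_path, header = FALSE, sep = "\t",
                           colClasses = "character")
  par <- utils::read.delim(parents_path, header = FALSE, sep = "\t",
                           colClasses = "character")
  annotation_table(stats::setNames(g2t[, 1:2], c("gene", "term")),
                   stats::setNames(par[, 1:2], c("term", "parent")))
}

assert_acyclic <- function(parents) {
  if (!nrow(parents)) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(parents[, c("term", "parent")], directed = TRUE)
  if (!igraph::is_dag(g)) stop("term parent graph contains a cycle")
  invisible(TRUE)
}

#' Write a fitted model's edge table
#'
#' Tab-separated columns `regulator`, `target`, `coefficient`,
#' `target_mean_validation_R2`, sorted by absolute coefficient (descending).
#' Round-trips losslessly through [read_edge_table()].
#'
#' @param model A fitted `gxn_model` (see [infer_gxn()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(model, path) {
  if (!inherits(model, "gxn_model")) stop("`model` must be a fitted gxn_model")
  edges <- generics::tidy(model)
  edges <- dplyr::arrange(edges, dplyr::desc(abs(.data$coefficient)),
                          .data$regulator, .data$target)
  names(edges)[names(edges) == "target_mean_r2"] <- "target_mean_validation_R2"
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read an edge table written by [write_edge_table()]
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `regulator`, `target`, `coefficient`,
#'   `target_mean_r2`.
#' @export
read_edge_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tibble::tibble(regulator = as.character(df$regulator),
                 target = as.character(df$target),
                 coefficient = as.numeric(df$coefficient),
                 target_mean_r2 = as.numeric(df$target_mean_validation_R2))
}

#' Write an expression matrix in the DREAM5 layout
#'
#' @param x A `gxn_expression`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- as.data.frame(unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write a gold standard as a 3-column TSV
#'
#' Positives first, then any declared negatives.
#'
#' @param gold A `gxn_gold`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  utils::write.table(gold$declared, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
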