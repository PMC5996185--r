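#' Discretize a differential-expression top-table into a disease signature
#'
#' Converts a limma/GEO2R-style top-table into the \{-1, 0, +1\} per-gene
#' state used as the initial condition of the linear model: genes whose
#' adjusted p-value exceeds \code{alpha} are set to 0 (not dysregulated);
#' significant genes take the sign of their log fold-change. A gene with
#' \code{adj_p} exactly equal to \code{alpha} is kept (only strictly larger
#' p-values are filtered). logFC exactly 0 maps to 0 even when significant.
#'
#' Duplicate gene rows (multiple probes) are resolved by keeping the row
#' with the smallest adjusted p-value — the most confident probe — which is
#' deterministic. Malformed rows (empty gene, non-finite logFC, p-value
#' missing or outside \[0, 1\]) are skipped and counted.
#'
#' @param records data.frame with columns \code{gene}, \code{logFC},
#'   \code{adj_p} (GEO2R aliases \code{Gene.symbol} and \code{adj.P.Val}
#'   are accepted).
#' @param alpha significance cutoff in (0, 1), default 0.05.
#' @return an \code{expression_signature}: list with \code{values} (named
#'   numeric in \{-1, 0, +1\}), \code{alpha}, and \code{n_skipped}.
#' @examples
#' tab <- data.frame(gene = c("BRCA1", "TP53", "EGFR"),
#'                   logFC = c(1.2, -0.5, 3.0),
#'                   adj_p = c(0.01, 0.04, 0.20))
#' discretize_expression(tab)$values   # +1, -1, 0
#' @export
discretize_expression <- function(records, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  records <- normalize_expression_columns(records)

  gene <- tolower(trimws(as.character(records$gene)))
  logfc <- as.numeric(records$logFC)
  adjp <- as.numeric(records$adj_p)

  ok <- nzchar(gene) & !is.na(gene) & is.finite(logfc) &
    !is.na(adjp) & adjp >= 0 & adjp <= 1
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    message(n_skipped, " malformed expression row(s) skipped")
  gene <- gene[ok]; logfc <- logfc[ok]; adjp <- adjp[ok]

  # duplicate probes: keep smallest adj_p, stable on ties
  ord <- order(gene, adjp)
  first <- !duplicated(gene[ord])
  gene <- gene[ord][first]; logfc <- logfc[ord][first]
  adjp <- adjp[ord][first]

  state <- ifelse(adjp > alpha, 0, sign(logfc))
  values <- stats::setNames(as.numeric(state), gene)
  structure(list(values = values, alpha = alpha, n_skipped = n_skipped),
            class = "expression_signature")
}

# accept GEO2R top-table column aliases; return canonical gene/logFC/adj_p
normalize_expression_columns <- function(records) {
  stopifnot(is.data.frame(records))
  nm <- names(records)
  pick <- function(aliases) {
    hit <- nm[tolower(nm) %in% tolower(aliases)]
    if (length(hit) == 0L) NA_character_ else hit[[1L]]
  }
  gene_col <- pick(c("gene", "gene.symbol", "gene_symbol", "id"))
  fc_col <- pick(c("logfc", "log_fc"))
  p_col <- pick(c("adj_p", "adj.p.val", "adj.p.value", "padj", "adj_p_val"))
  missing <- c(gene = gene_col, logFC = fc_col, adj_p = p_col)
  if (anyNA(missing))
    stop("expression table is missing required column(s): ",
         paste(names(missing)[is.na(missing)], collapse = ", "))
  data.frame(gene = records[[gene_col]], logFC = records[[fc_col]],
             adj_p = records[[p_col]], stringsAsFactors = FALSE)
}

#' Align an expression signature to a model's gene order
#'
#' Produces the initial-condition vector x(0): for each model gene, the
#' signature state, or 0 when the gene is absent from the signature.
#' Matched/unmatched gene counts are attached as attributes
#' (\code{n_matched}: model genes found in the signature;
#' \code{n_unmatched}: signature genes absent from the model).
#'
#' @param signature an \code{expression_signature}.
#' @param model a \code{system_model}.
#' @return named numeric vector of length N in model gene order.
#' @export
align_signature <- function(signature, model) {
  stopifnot(inherits(signature, "expression_signature"),
            inherits(model, "system_model"), length(model$genes) >= 1L)
  idx <- match(model$genes, names(signature$values))
  x0 <- ifelse(is.na(idx), 0, signature$values[idx])
  x0 <- stats::setNames(as.numeric(x0), model$genes)
  attr(x0, "n_matched") <- sum(!is.na(idx))
  attr(x0, "n_unmatched") <- sum(!names(signature$values) %in% model$genes)
  x0
}

#' @export
print.expression_signature <- function(x, ...) {
  tab <- table(factor(x$values, levels = c(-1, 0, 1)))
  cat(sprintf(
    "expression_signature: %d genes (down %d / unchanged %d / up %d), alpha = %g\n",
    length(x$values), tab[["-1"]], tab[["0"]], tab[["1"]], x$alpha))
  invisible(x)
}

#' Write a signature as a two-column TSV (gene, state)
#' @param signature an \code{expression_signature}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_signature <- function(signature, path) {
  utils::write.table(
    data.frame(gene = names(signature$values), state = signature$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature TSV written by \code{write_signature}
#' @param path file with columns gene, state.
#' @param alpha cutoff recorded on the object (metadata only).
#' @return an \code{expression_signature}.
#' @export
read_signature <- function(path, alpha = 0.05) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "state") %in% names(tab)))
    stop("signature file must have columns gene, state: ", path)
  if (!all(tab$state %in% c(-1, 0, 1)))
    stop("signature states must be -1, 0, or +1")
  structure(list(values = stats::setNames(as.numeric(tab$state),
                                          tolower(trimws(tab$gene))),
                 alpha = alpha, n_skipped = 0L),
            class = "expression_signature")
}
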