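# Table readers for the three input dialects. All tables are UTF-8,
# header-bearing, tab-delimited by default with comma auto-detection;
# gene identifiers are opaque strings, matched after trim + case-fold.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

read_delim_checked <- function(path, required, file_kind) {
  if (!file.exists(path)) stop(file_kind, " file not found: ", path)
  tab <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, fill = TRUE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop(file_kind, " file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  tab
}

#' Read a signed interaction table
#'
#' Accepts TSV/CSV with header columns \code{source, target, mechanism}
#' and optional \code{confidence}, or SIF (simple interaction format,
#' \code{source relation target...} per line, no header; detected by the
#' \code{.sif} extension) with the relation token used as the mechanism.
#' Rows with empty source/target or out-of-range confidence are skipped
#' with a reported count.
#'
#' @param path input file.
#' @return data.frame of interaction records.
#' @export
read_interactions <- function(path) {
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    rows <- lapply(parts, function(p) {
      if (length(p) < 3L) return(NULL)
      data.frame(source = p[1L], target = p[3:length(p)],
                 mechanism = p[2L], confidence = NA_real_,
                 stringsAsFactors = FALSE)
    })
    skipped <- sum(vapply(rows, is.null, logical(1)))
    if (skipped > 0L) message(skipped, " malformed SIF line(s) skipped")
    return(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
  }
  tab <- read_delim_checked(path, c("source", "target", "mechanism"),
                            "interaction")
  if (!"confidence" %in% names(tab))
    tab$confidence <- rep(NA_real_, nrow(tab))
  tab$confidence <- suppressWarnings(as.numeric(tab$confidence))
  ok <- nzchar(trimws(as.character(tab$source))) &
    nzchar(trimws(as.character(tab$target))) &
    !is.na(tab$mechanism) &
    (is.na(tab$confidence) |
       (tab$confidence >= 0 & tab$confidence <= 1000))
  if (any(!ok)) message(sum(!ok), " malformed interaction row(s) skipped")
  tab[ok, , drop = FALSE]
}

#' Read a differential-expression top-table (GEO2R/limma dialect)
#'
#' Accepts column aliases: gene identifier may be \code{gene},
#' \code{Gene.symbol} or \code{ID}; adjusted p may be \code{adj_p},
#' \code{adj.P.Val} or \code{padj}.
#'
#' @param path input TSV/CSV.
#' @return data.frame with canonical columns gene, logFC, adj_p.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, fill = TRUE)
  normalize_expression_columns(tab)
}

#' Read a drug-target table
#'
#' Requires header columns \code{drug, set_label, gene, mechanism};
#' \code{confidence} optional. Set labels are validated against the
#' D1/D2/D3/unlabeled vocabulary.
#'
#' @param path input TSV/CSV.
#' @return data.frame of drug-target rows.
#' @export
read_drug_table <- function(path) {
  tab <- read_delim_checked(path, c("drug", "set_label", "gene",
                                    "mechanism"), "drug-target")
  if (!"confidence" %in% names(tab))
    tab$confidence <- rep(NA_real_, nrow(tab))
  tab$confidence <- suppressWarnings(as.numeric(tab$confidence))
  bad <- setdiff(unique(tab$set_label), drug_set_labels)
  if (length(bad) > 0L)
    stop("drug-target file '", path, "' has unknown set label(s) ",
         paste(bad, collapse = ", "), "; allowed vocabulary: ",
         paste(drug_set_labels, collapse = ", "))
  ok <- nzchar(trimws(as.character(tab$drug))) &
    nzchar(trimws(as.character(tab$gene))) & !is.na(tab$mechanism)
  if (any(!ok)) message(sum(!ok), " malformed drug-target row(s) skipped")
  tab[ok, , drop = FALSE]
}

#' Assemble a validated pipeline configuration
#'
#' Collects every tunable of the pipeline with the field defaults:
#' expression significance alpha 0.05, interactome confidence floor 500,
#' drug-interaction confidence floor 800, marginal stability (margin 0),
#' signed numerator, sum aggregation. The resolved config is serialized
#' verbatim into every output directory for provenance.
#'
#' @param interactions,expression,drugs input table paths.
#' @param out output directory.
#' @param alpha significance cutoff in (0, 1).
#' @param min_ppi_confidence interactome confidence floor in \[0, 1000\].
#' @param min_drug_confidence drug-interaction floor in \[0, 1000\].
#' @param stability_margin nonnegative extra shrink on the dynamics.
#' @param sign_tol zero threshold for intervention signs.
#' @param solver_tol,max_iter Riccati solver controls.
#' @param aggregation \code{"sum"} or \code{"mean"}.
#' @param abs_numerator use the absolute-value score numerator.
#' @param undefined_as_zero report undefined scores as 0 in the ROC.
#' @param layout adjacency layout, \code{"incoming"} or
#'   \code{"paper-literal"}.
#' @param mechanism_table_path optional override of the packaged table.
#' @param seed integer recorded for provenance.
#' @return a validated \code{run_config} list.
#' @export
run_config <- function(interactions, expression, drugs, out = ".",
                       alpha = 0.05, min_ppi_confidence = 500,
                       min_drug_confidence = 800, stability_margin = 0,
                       sign_tol = 1e-12, solver_tol = 1e-10,
                       max_iter = 10000L, aggregation = "sum",
                       abs_numerator = FALSE, undefined_as_zero = FALSE,
                       layout = "incoming", mechanism_table_path = NULL,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1,
            min_ppi_confidence >= 0, min_ppi_confidence <= 1000,
            min_drug_confidence >= 0, min_drug_confidence <= 1000,
            stability_margin >= 0, sign_tol >= 0, solver_tol > 0,
            max_iter >= 1, aggregation %in% c("sum", "mean"),
            layout %in% c("incoming", "paper-literal"))
  structure(list(interactions = interactions, expression = expression,
                 drugs = drugs, out = out, alpha = alpha,
                 min_ppi_confidence = min_ppi_confidence,
                 min_drug_confidence = min_drug_confidence,
                 stability_margin = stability_margin, sign_tol = sign_tol,
                 solver_tol = solver_tol, max_iter = as.integer(max_iter),
                 aggregation = aggregation, abs_numerator = abs_numerator,
                 undefined_as_zero = undefined_as_zero, layout = layout,
                 mechanism_table_path = mechanism_table_path,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read the three input tables of a configuration
#'
#' @param config a \code{run_config}.
#' @return list with \code{interactions}, \code{expression}, \code{drugs}
#'   data.frames.
#' @export
read_tables <- function(config) {
  stopifnot(inherits(config, "run_config"))
  list(interactions = read_interactions(config$interactions),
       expression = read_expression(config$expression),
       drugs = read_drug_table(config$drugs))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full repurposing pipeline
#'
#' Executes model building, signature discretization, Riccati/LQR
#' intervention, drug quantification, therapeutic scoring, and (when both
#' D1 and D2 drugs are present) ROC evaluation. Writes \code{scores.tsv},
#' \code{hypo.tsv}, \code{roc.json} and \code{meta.json} (resolved config
#' plus solver diagnostics) into \code{config$out}. Errors are re-raised
#' with the failing stage's name attached.
#'
#' @param config a \code{run_config}.
#' @return invisibly, a list with \code{model}, \code{scores} (ranked),
#'   \code{hypo}, \code{roc} (NULL if not computable), \code{solution}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tabs <- stage("read", read_tables(config))
  model <- stage("model", build_model(
    tabs$interactions, min_confidence = config$min_ppi_confidence,
    layout = config$layout, stability_margin = config$stability_margin))
  signature <- stage("signature",
                     discretize_expression(tabs$expression, config$alpha))
  x0 <- align_signature(signature, model)
  sol <- stage("control", solve_dare(model$dynamics, tol = config$solver_tol,
                                     max_iter = config$max_iter))
  hypo <- hypo_treatment(sol, model$dynamics, x0, config$sign_tol)
  mt <- if (is.null(config$mechanism_table_path)) mechanism_table()
        else mechanism_table(config$mechanism_table_path)
  vectors <- stage("treatment", build_treatment_vectors(
    tabs$drugs, model, table = mt, aggregation = config$aggregation,
    min_confidence = config$min_drug_confidence))
  scores <- stage("scoring",
                  score_drugs(vectors, hypo, config$abs_numerator))
  if (config$undefined_as_zero) scores$T_d[is.na(scores$T_d)] <- 0
  scores <- rank_drugs(scores)
  roc <- NULL
  if (sum(scores$set_label == "D1" & !is.na(scores$T_d)) > 0 &&
      sum(scores$set_label == "D2" & !is.na(scores$T_d)) > 0)
    roc <- stage("evaluate", roc_auc(scores))

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(scores, file.path(config$out, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = model$genes, u0 = hypo$u0, sign = hypo$sign_pattern),
    file.path(config$out, "hypo.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roc))
    jsonlite::write_json(
      list(auc = roc$auc, n_positive = roc$n_positive,
           n_negative = roc$n_negative, curve = roc$curve),
      file.path(config$out, "roc.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config = unclass(config),
         diagnostics = list(n_genes = length(model$genes),
                            normalization = model$normalization,
                            riccati_iterations = sol$iterations,
                            riccati_residual = sol$residual,
                            closed_loop_radius = sol$closed_loop_radius,
                            n_matched = attr(x0, "n_matched"),
                            n_unmatched = attr(x0, "n_unmatched"))),
    file.path(config$out, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, scores = scores, hypo = hypo, roc = roc,
                 solution = sol))
}
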