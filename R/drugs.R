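#' Load a drug-mechanism quantification table
#'
#' The default table ships with the package and maps the 37 drug-action
#' vocabulary labels used by DrugBank/DMAP-style exports to values in
#' \{-1, -0.5, 0, 0.5, 1\}: inhibitory actions (Antagonist, Inhibitor,
#' Suppressor, ...) are -1, activating actions (Agonist, Activator,
#' Inducer, ...) are +1, ambiguous or structural actions (Binder, Ligand,
#' Antibody, ...) are 0, and Adduct is 0.5. Labels absent from the table
#' fall back to \code{fallback} (default 0).
#'
#' @param path optional TSV with columns \code{mechanism}, \code{value}
#'   overriding the packaged default.
#' @param fallback value for labels not listed in the table.
#' @return a \code{mechanism_table}: list with \code{mapping} (named
#'   numeric, lower-cased labels) and \code{fallback}.
#' @export
mechanism_table <- function(path = NULL, fallback = 0) {
  if (is.null(path))
    path <- system.file("extdata", "mechanism_table.tsv",
                        package = "lqrepurpose", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  if (!all(c("mechanism", "value") %in% names(tab)))
    stop("mechanism table must have columns mechanism, value: ", path)
  vals <- as.numeric(tab$value)
  if (any(!is.finite(vals)) || any(abs(vals) > 1))
    stop("mechanism values must be finite and within [-1, 1]")
  structure(list(mapping = stats::setNames(vals, tolower(trimws(tab$mechanism))),
                 fallback = fallback),
            class = "mechanism_table")
}

#' Quantify drug-target mechanisms of action
#'
#' Looks each mechanism label up in a \code{\link{mechanism_table}}
#' (case-insensitive). Rows carrying a confidence score below
#' \code{min_confidence} (DMAP-style rows; scale 0--1000) are filtered out
#' and returned as \code{NA}; rows without a score (DrugBank-style rows)
#' always pass.
#'
#' @param mechanism character vector of action labels.
#' @param confidence optional numeric scores; \code{NA} = no score.
#' @param table a \code{mechanism_table} (default: packaged table).
#' @param min_confidence minimum score for score-bearing rows (default 800).
#' @return numeric vector of quantified actions, \code{NA} = filtered.
#' @examples
#' quantify_drug_action("Antagonist")     # -1
#' quantify_drug_action("Adduct")         # 0.5
#' quantify_drug_action("Inducer", 700)   # NA (filtered)
#' @export
quantify_drug_action <- function(mechanism, confidence = NA_real_,
                                 table = mechanism_table(),
                                 min_confidence = 800) {
  stopifnot(inherits(table, "mechanism_table"),
            min_confidence >= 0, min_confidence <= 1000)
  mech <- tolower(trimws(as.character(mechanism)))
  n <- length(mech)
  confidence <- rep_len(as.numeric(confidence), n)
  idx <- match(mech, names(table$mapping))
  value <- ifelse(is.na(idx), table$fallback, table$mapping[idx])
  value[!is.na(confidence) & confidence < min_confidence] <- NA_real_
  value
}

drug_set_labels <- c("D1", "D2", "D3", "unlabeled")

#' Build one drug's treatment vector aligned to a model
#'
#' Quantifies the drug's surviving target interactions and aggregates them
#' per model gene (default: sum, so opposing mechanisms on the same gene
#' cancel; \code{mean} divides by the number of surviving interactions on
#' that gene). Genes the drug does not target are 0. Targets outside the
#' model are counted, not an error.
#'
#' @param profile list with \code{drug} (name), \code{set_label} (one of
#'   D1/D2/D3/unlabeled), and \code{targets}: data.frame with columns
#'   \code{gene}, \code{mechanism}, optionally \code{confidence}.
#' @param model a \code{system_model}.
#' @param table a \code{mechanism_table}.
#' @param aggregation \code{"sum"} (default) or \code{"mean"}.
#' @param min_confidence drug-interaction confidence filter (default 800).
#' @return a \code{treatment_vector}: list with \code{drug},
#'   \code{set_label}, \code{u} (named numeric, model gene order),
#'   \code{n_targets_in_model}, \code{n_targets_outside}.
#' @export
build_treatment_vector <- function(profile, model, table = mechanism_table(),
                                   aggregation = c("sum", "mean"),
                                   min_confidence = 800) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(model, "system_model"), is.list(profile),
            nzchar(profile$drug))
  if (!profile$set_label %in% drug_set_labels)
    stop("drug set label must be one of: ",
         paste(drug_set_labels, collapse = ", "))
  tg <- profile$targets
  u <- stats::setNames(numeric(length(model$genes)), model$genes)
  n_in <- 0L; n_out <- 0L
  if (!is.null(tg) && nrow(tg) > 0L) {
    conf <- if ("confidence" %in% names(tg)) tg$confidence else NA_real_
    value <- quantify_drug_action(tg$mechanism, conf, table, min_confidence)
    gene <- tolower(trimws(as.character(tg$gene)))
    keep <- !is.na(value)
    gene <- gene[keep]; value <- value[keep]
    inside <- gene %in% model$genes
    n_in <- length(unique(gene[inside]))
    n_out <- length(unique(gene[!inside]))
    if (any(inside)) {
      agg <- tapply(value[inside], gene[inside],
                    if (aggregation == "sum") sum else mean)
      u[names(agg)] <- as.numeric(agg)
    }
  }
  structure(list(drug = profile$drug, set_label = profile$set_label, u = u,
                 n_targets_in_model = n_in, n_targets_outside = n_out),
            class = "treatment_vector")
}

#' Split a drug-target table into per-drug profiles
#'
#' @param drug_tab data.frame with columns \code{drug}, \code{set_label},
#'   \code{gene}, \code{mechanism}, optionally \code{confidence}.
#' @return named list of profiles suitable for
#'   \code{\link{build_treatment_vector}}, in order of first appearance.
#' @export
drug_profiles <- function(drug_tab) {
  stopifnot(is.data.frame(drug_tab))
  for (col in c("drug", "set_label", "gene", "mechanism")) {
    if (!col %in% names(drug_tab))
      stop("drug table is missing required column '", col, "'")
  }
  bad <- setdiff(unique(drug_tab$set_label), drug_set_labels)
  if (length(bad) > 0L)
    stop("unknown drug set label(s) ", paste(bad, collapse = ", "),
         "; allowed vocabulary: ", paste(drug_set_labels, collapse = ", "))
  drugs <- unique(drug_tab$drug)
  profiles <- lapply(drugs, function(d) {
    rows <- drug_tab[drug_tab$drug == d, , drop = FALSE]
    lab <- unique(rows$set_label)
    if (length(lab) > 1L)
      stop("drug '", d, "' appears with conflicting set labels")
    list(drug = d, set_label = lab, targets = rows)
  })
  stats::setNames(profiles, drugs)
}

#' Build treatment vectors for every drug in a table
#'
#' @inheritParams drug_profiles
#' @inheritParams build_treatment_vector
#' @return named list of \code{treatment_vector}s.
#' @export
build_treatment_vectors <- function(drug_tab, model,
                                    table = mechanism_table(),
                                    aggregation = c("sum", "mean"),
                                    min_confidence = 800) {
  aggregation <- match.arg(aggregation)
  lapply(drug_profiles(drug_tab), build_treatment_vector, model = model,
         table = table, aggregation = aggregation,
         min_confidence = min_confidence)
}
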