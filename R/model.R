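#' Quantify a protein-protein interaction mechanism
#'
#' Maps a mechanism label to a signed weight: \code{+1} for activation,
#' \code{-1} for inhibition, \code{0} for every other mechanism (catalysis,
#' ptmod, binding, reaction, expression, ...). Rows carrying a confidence
#' score below \code{min_confidence} are filtered out (returned as
#' \code{NA}); rows without a score (curated-pathway edges) always pass.
#'
#' Matching is case-insensitive after whitespace trimming. Labels outside
#' the known interactome vocabulary map to 0 with a warning.
#'
#' @param mechanism character vector of mechanism labels.
#' @param confidence optional numeric vector of confidence scores on the
#'   0--1000 scale; \code{NA} means "no score available".
#' @param min_confidence minimum score required of score-bearing rows
#'   (default 500).
#' @return numeric vector in \{-1, 0, +1\}, with \code{NA} marking filtered
#'   rows.
#' @examples
#' quantify_interaction("activation", 900)        # +1
#' quantify_interaction("catalysis", 900)         # 0
#' quantify_interaction("inhibition", 400)        # NA (filtered)
#' @export
quantify_interaction <- function(mechanism, confidence = NA_real_,
                                 min_confidence = 500) {
  stopifnot(is.numeric(min_confidence), length(min_confidence) == 1L,
            min_confidence >= 0, min_confidence <= 1000)
  mech <- tolower(trimws(as.character(mechanism)))
  n <- length(mech)
  confidence <- rep_len(as.numeric(confidence), n)

  known <- c("activation", "expression", "inhibition", "catalysis",
             "ptmod", "binding", "reaction", "other")
  unknown <- setdiff(unique(mech), known)
  if (length(unknown) > 0L) {
    warning("unknown mechanism label(s) mapped to 0: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }

  value <- numeric(n)
  value[mech == "activation"] <- 1
  value[mech == "inhibition"] <- -1
  value[!is.na(confidence) & confidence < min_confidence] <- NA_real_
  value
}

#' Build the raw signed adjacency matrix from interaction records
#'
#' Assembles the quantified interactome into an N x N matrix over the
#' sorted union of all gene identifiers seen in the surviving records.
#' Parallel edges between the same ordered pair are summed and the entry is
#' clipped to \[-1, 1\], so conflicting evidence can cancel while the matrix
#' stays on the discretized scale.
#'
#' Under the default \code{"incoming"} layout, entry (i, j) holds the effect
#' OF gene j ON gene i, so that \code{A \%*\% x} propagates influence along
#' the directed edges as the dynamics x(t) = A x(t-1) require. The
#' \code{"paper-literal"} layout stores the transpose (entry (i, j) = effect
#' of i on j).
#'
#' @param records data.frame with columns \code{source}, \code{target},
#'   \code{mechanism}, and optionally \code{confidence}.
#' @param min_confidence passed to \code{\link{quantify_interaction}}.
#' @param layout edge-orientation convention, see Details.
#' @return a \code{system_model} with \code{raw_adjacency} set and
#'   \code{dynamics} unset (see \code{\link{normalize_dynamics}}).
#' @export
build_adjacency <- function(records, min_confidence = 500,
                            layout = c("incoming", "paper-literal")) {
  layout <- match.arg(layout)
  stopifnot(is.data.frame(records))
  for (col in c("source", "target", "mechanism")) {
    if (!col %in% names(records))
      stop("interaction table is missing required column '", col, "'")
  }
  src <- tolower(trimws(as.character(records$source)))
  tgt <- tolower(trimws(as.character(records$target)))
  if (any(!nzchar(src)) || any(!nzchar(tgt)))
    stop("interaction records must have non-empty source and target")
  conf <- if ("confidence" %in% names(records))
    as.numeric(records$confidence) else rep(NA_real_, nrow(records))
  if (any(!is.na(conf) & (conf < 0 | conf > 1000)))
    stop("confidence scores must lie in [0, 1000]")

  value <- quantify_interaction(records$mechanism, conf, min_confidence)
  keep <- !is.na(value)
  if (!any(keep))
    stop("empty model: no interaction records survive the confidence filter")
  src <- src[keep]; tgt <- tgt[keep]; value <- value[keep]

  genes <- sort(unique(c(src, tgt)))
  n <- length(genes)
  a <- matrix(0, n, n, dimnames = list(genes, genes))
  i <- match(tgt, genes)   # row = affected gene under "incoming"
  j <- match(src, genes)
  if (layout == "paper-literal") { tmp <- i; i <- j; j <- tmp }
  for (k in seq_along(value)) a[i[k], j[k]] <- a[i[k], j[k]] + value[k]
  a <- pmin(pmax(a, -1), 1)

  structure(list(genes = genes, raw_adjacency = a, dynamics = NULL,
                 normalization = NA_real_, layout = layout),
            class = "system_model")
}

#' Normalize the adjacency into a marginally stable dynamics matrix
#'
#' Divides the raw adjacency by the magnitude of its largest eigenvalue so
#' the open-loop linear dynamics x(t) = A x(t-1) cannot diverge. The
#' largest-magnitude eigenvalue of a signed non-symmetric matrix may be
#' complex; dividing by its modulus is the only reading that keeps the
#' dynamics matrix real. A nilpotent adjacency (all eigenvalues zero) is
#' left unchanged with normalization recorded as 0.
#'
#' With the default \code{stability_margin = 0} the normalized matrix has
#' spectral radius exactly 1 (marginal stability); a positive margin divides
#' by \code{|lambda| * (1 + stability_margin)} for strict stability.
#'
#' @param model a \code{system_model} with \code{raw_adjacency} present.
#' @param stability_margin nonnegative extra shrink factor (default 0).
#' @param tol eigenvalue magnitudes at or below this count as zero.
#' @return the model with \code{dynamics} and \code{normalization} set;
#'   \code{normalization} is the actual divisor used.
#' @export
normalize_dynamics <- function(model, stability_margin = 0, tol = 1e-12) {
  stopifnot(inherits(model, "system_model"), stability_margin >= 0)
  a <- model$raw_adjacency
  if (!all(is.finite(a))) stop("raw adjacency contains non-finite entries")
  rho <- max(Mod(eigen(a, only.values = TRUE)$values))
  if (rho > tol) {
    model$normalization <- rho * (1 + stability_margin)
    model$dynamics <- a / model$normalization
  } else {
    model$normalization <- 0
    model$dynamics <- a
  }
  model
}

#' Build a complete system model from interaction records
#'
#' Convenience wrapper: \code{\link{build_adjacency}} followed by
#' \code{\link{normalize_dynamics}}.
#' @inheritParams build_adjacency
#' @inheritParams normalize_dynamics
#' @return a \code{system_model} with both matrices set.
#' @export
build_model <- function(records, min_confidence = 500,
                        layout = c("incoming", "paper-literal"),
                        stability_margin = 0) {
  normalize_dynamics(build_adjacency(records, min_confidence, layout),
                     stability_margin = stability_margin)
}

#' @export
print.system_model <- function(x, ...) {
  n <- length(x$genes)
  nnz <- sum(x$raw_adjacency != 0)
  cat(sprintf("system_model: %d genes, %d nonzero raw entries\n", n, nnz))
  cat(sprintf("  layout: %s; normalization |lambda|: %s; dynamics %sset\n",
              x$layout,
              if (is.na(x$normalization)) "unset" else
                format(x$normalization, digits = 6),
              if (is.null(x$dynamics)) "un" else ""))
  invisible(x)
}

#' Serialize a system model to a directory
#'
#' Writes \code{genes.txt} (one id per line), \code{raw_adjacency.tsv},
#' \code{dynamics.tsv}, and \code{meta.json} (normalization, layout).
#' @param model a \code{system_model} with dynamics set.
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "system_model"), !is.null(model$dynamics))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(model$genes, file.path(dir, "genes.txt"))
  write_matrix_tsv <- function(m, path) {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  write_matrix_tsv(model$raw_adjacency, file.path(dir, "raw_adjacency.tsv"))
  write_matrix_tsv(model$dynamics, file.path(dir, "dynamics.tsv"))
  jsonlite::write_json(
    list(normalization = model$normalization, layout = model$layout,
         n_genes = length(model$genes)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a system model from a directory written by \code{write_model}
#' @param dir directory path.
#' @return a \code{system_model}.
#' @export
read_model <- function(dir) {
  genes <- readLines(file.path(dir, "genes.txt"))
  read_matrix_tsv <- function(path) {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    dimnames(m) <- list(genes, genes)
    m
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(list(genes = genes,
                 raw_adjacency = read_matrix_tsv(file.path(dir, "raw_adjacency.tsv")),
                 dynamics = read_matrix_tsv(file.path(dir, "dynamics.tsv")),
                 normalization = meta$normalization,
                 layout = meta$layout),
            class = "system_model")
}
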