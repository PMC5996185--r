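#' Therapeutic score of a drug against the optimal intervention
#'
#' Scores the signed agreement between a drug's quantified target-action
#' vector u_d and the sign pattern of the optimal intervention u(0):
#'
#'   T_d = sum_i u_d\[i\] * s\[i\]  /  sum_i |u_d\[i\]| * |s\[i\]|
#'
#' with s = sign(u(0)). The numerator is incremented where the drug acts in
#' the same direction as the ideal intervention and decremented where it
#' opposes it; the denominator normalizes by the total overlapping action,
#' so T_d lies in \[-1, 1\]: +1 = perfectly therapeutic, -1 = perfectly
#' anti-therapeutic. When the drug has no action on any gene the
#' intervention touches, the denominator is 0 and T_d is undefined
#' (returned as \code{NA}, reported distinctly, never silently as 0).
#'
#' \code{abs_numerator = TRUE} wraps the numerator in absolute value,
#' forcing T_d >= 0; the default signed form is the one consistent with a
#' score that distinguishes therapeutic from anti-therapeutic drugs.
#'
#' @param u_d numeric drug-action vector (or a \code{treatment_vector}).
#' @param sign_u0 sign pattern of the optimal intervention, in
#'   \{-1, 0, +1\} (or a \code{hypo_treatment}).
#' @param abs_numerator use the absolute-value numerator variant.
#' @return a \code{therapeutic_score}: list with \code{drug} (may be NA),
#'   \code{set_label}, \code{numerator}, \code{denominator}, \code{T_d}
#'   (\code{NA} when undefined).
#' @examples
#' therapeutic_score(c(1, 0, -1), c(1, -1, 0))$T_d   # 1
#' therapeutic_score(c(1, 1, 0), c(1, -1, 1))$T_d    # 0
#' @export
therapeutic_score <- function(u_d, sign_u0, abs_numerator = FALSE) {
  drug <- NA_character_; set_label <- NA_character_
  n_targets <- NA_integer_
  if (inherits(u_d, "treatment_vector")) {
    drug <- u_d$drug; set_label <- u_d$set_label
    n_targets <- u_d$n_targets_in_model
    u_d <- u_d$u
  }
  if (inherits(sign_u0, "hypo_treatment")) sign_u0 <- sign_u0$sign_pattern
  u_d <- as.numeric(u_d); sign_u0 <- as.numeric(sign_u0)
  if (length(u_d) != length(sign_u0))
    stop("drug vector and intervention sign pattern differ in length")
  num <- sum(u_d * sign_u0)
  if (abs_numerator) num <- abs(num)
  den <- sum(abs(u_d) * abs(sign_u0))
  structure(list(drug = drug, set_label = set_label,
                 n_targets_in_model = n_targets,
                 numerator = num, denominator = den,
                 T_d = if (den > 0) num / den else NA_real_),
            class = "therapeutic_score")
}

#' Score every drug in a panel of treatment vectors
#'
#' @param vectors list of \code{treatment_vector}s (see
#'   \code{\link{build_treatment_vectors}}).
#' @param hypo a \code{hypo_treatment} (or a bare sign pattern).
#' @param abs_numerator see \code{\link{therapeutic_score}}.
#' @return data.frame with columns drug, set_label, n_targets_in_model,
#'   numerator, denominator, T_d (NA where undefined).
#' @export
score_drugs <- function(vectors, hypo, abs_numerator = FALSE) {
  if (length(vectors) == 0L) stop("no drugs to score")
  rows <- lapply(vectors, function(v) {
    s <- therapeutic_score(v, hypo, abs_numerator)
    data.frame(drug = s$drug, set_label = s$set_label,
               n_targets_in_model = s$n_targets_in_model,
               numerator = s$numerator, denominator = s$denominator,
               T_d = s$T_d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank drugs by therapeutic score
#'
#' Descending by T_d; undefined (NA) scores placed last; ties broken
#' alphabetically by drug name so output is deterministic.
#'
#' @param scores data.frame as returned by \code{\link{score_drugs}}.
#' @return the same data.frame, reordered, with a \code{rank} column.
#' @export
rank_drugs <- function(scores) {
  stopifnot(is.data.frame(scores))
  if (nrow(scores) == 0L) {
    scores$rank <- integer(0)
    return(scores)
  }
  ord <- order(-ifelse(is.na(scores$T_d), -Inf, scores$T_d),
               is.na(scores$T_d), scores$drug)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' ROC analysis of approved (D1) versus withdrawn (D2) drug scores
#'
#' Treats D1 as the positive class and computes AUC as the Mann-Whitney
#' pair statistic: (wins + ties/2) / (n1 * n2) over all D1 x D2 score
#' pairs. Undefined scores are excluded with a warning. The ROC curve
#' steps through the distinct score thresholds from high to low and always
#' runs from (0, 0) to (1, 1).
#'
#' @param scores data.frame with columns \code{set_label} and \code{T_d}
#'   (rows with other labels are ignored), or a numeric score vector when
#'   \code{labels} is given.
#' @param labels optional label vector paired with a numeric \code{scores}.
#' @param positive,negative the two class labels (defaults D1, D2).
#' @return a \code{roc_result}: list with \code{auc}, \code{n_positive},
#'   \code{n_negative}, \code{curve} (data.frame fpr, tpr).
#' @examples
#' roc_auc(c(0.2, 0.0, 1.0, -0.2, -0.09),
#'         labels = c("D1", "D1", "D1", "D2", "D2"))$auc   # 1
#' @export
roc_auc <- function(scores, labels = NULL, positive = "D1", negative = "D2") {
  if (is.data.frame(scores)) {
    labels <- scores$set_label
    scores <- scores$T_d
  }
  stopifnot(length(scores) == length(labels))
  keep <- labels %in% c(positive, negative)
  scores <- as.numeric(scores[keep]); labels <- labels[keep]
  if (anyNA(scores)) {
    warning(sum(is.na(scores)),
            " undefined score(s) excluded from ROC", call. = FALSE)
    keep <- !is.na(scores)
    scores <- scores[keep]; labels <- labels[keep]
  }
  pos <- scores[labels == positive]
  neg <- scores[labels == negative]
  n1 <- length(pos); n2 <- length(neg)
  if (n1 == 0L || n2 == 0L)
    stop("ROC needs at least one score in each of '", positive, "' and '",
         negative, "'")

  # midrank form of the Mann-Whitney U statistic (ties count one half)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1)
    curve <- rbind(curve, data.frame(fpr = 1, tpr = 1))
  structure(list(auc = auc, n_positive = n1, n_negative = n2,
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%d positive vs %d negative)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}
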