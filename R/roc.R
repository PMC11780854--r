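#' ROC curve and AUC for structure concordance
#'
#' Scores how well reactivity separates unpaired from paired bases in a
#' reference secondary structure. Following the convention that probing
#' reactivity is high at unpaired bases, the positive class is
#' **unpaired** (a dot in dot-bracket notation) and the score is the
#' reactivity; many toolkits use the opposite convention. Only valid
#' positions enter the computation. Ties across classes receive half
#' credit, so the trapezoidal AUC equals the Mann-Whitney U statistic
#' `[#(pos > neg) + 0.5 * #(pos = neg)] / (n_pos * n_neg)`.
#'
#' @param reactivity A `reactivity_profile`.
#' @param structure A `secondary_structure` of the same RNA and length.
#' @return A `roc_result` object with fields `thresholds` (descending
#'   unique scores), `fpr`, `tpr` (both starting at 0 and ending at 1),
#'   `auc`, `n_pos` and `n_neg`. Use [tidy()] for the curve points,
#'   [glance()] for the summary, [autoplot()] to draw the curve.
#' @export
roc_auc <- function(reactivity, structure) {
  stopifnot(inherits(reactivity, "reactivity_profile"),
            inherits(structure, "secondary_structure"))
  if (nrow(reactivity) != nrow(structure)) {
    abort(sprintf("profile length (%d) and structure length (%d) differ.",
                  nrow(reactivity), nrow(structure)),
          class = "probeval_pairing_error")
  }
  idx <- valid_positions(reactivity)
  scores <- reactivity$reactivity[idx]
  positive <- !structure$paired[idx]   # unpaired bases are the positive class
  roc_from_scores(scores, positive)
}

# Core ROC construction from scores and positive-class labels.
roc_from_scores <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    abort(sprintf(
      "degenerate labels: need both classes, got %d unpaired and %d paired valid positions.",
      n_pos, n_neg),
      class = "probeval_degenerate_labels_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positive[ord]
  # group tied scores so each unique threshold contributes one ROC vertex
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp <- cumsum(p)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(!p)[!duplicated(grp, fromLast = TRUE)]
  thresholds <- s[!duplicated(grp)]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  res <- list(thresholds = thresholds, fpr = fpr, tpr = tpr,
              auc = auc, n_pos = n_pos, n_neg = n_neg)
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (n_unpaired = %d, n_paired = %d)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(threshold = c(Inf, x$thresholds), fpr = x$fpr, tpr = x$tpr)
}

#' @rdname roc_auc
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname roc_auc
#' @param object A `roc_result`.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (paired called reactive)",
      y = "True positive rate (unpaired called reactive)",
      title = sprintf("AUC = %.3f", object$auc)
    )
}
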