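#' Benchmark ranked synergy scores against gold-standard labels
#'
#' Lower (ascending) score means more synergistic, as produced by
#' [normalize_synergies()]. The ROC AUC is computed by the rank-sum
#' (Mann-Whitney) statistic with tied scores receiving average ranks,
#' equivalent to trapezoidal integration of the ROC curve. The PR AUC is
#' average precision (step-wise summation, no linear interpolation, which
#' is known to be biased for PR curves), with tied scores treated as a
#' single threshold block; the baseline PR AUC of an uninformative ranker
#' is the prevalence `n_pos / (n_pos + n_neg)`, and a constant-score
#' ranker attains exactly that value.
#'
#' @param score numeric scores, ascending = more synergistic.
#' @param label logical or 0/1 gold labels (`TRUE`/1 = observed synergy).
#' @return object of class `benchmark_result`: `roc_auc`, `pr_auc`,
#'   `roc_points` (fpr, tpr), `pr_points` (recall, precision), `n_pos`,
#'   `n_neg`.
#' @export
benchmark <- function(score, label) {
  label <- as.logical(label)
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]
  label <- label[keep]
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) {
    stop("gold standard must contain at least one positive and one negative")
  }
  predictor <- -score                       # higher = more synergistic
  r <- rank(predictor)                      # ties -> average ranks
  roc_auc <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(predictor, decreasing = TRUE)
  lab_sorted <- label[ord]
  tp <- cumsum(lab_sorted)
  precision <- tp / seq_along(lab_sorted)
  recall <- tp / n_pos
  # average precision, tie-aware: items sharing a score form one threshold
  # block and every positive in it contributes the block-end precision, so
  # the result does not depend on within-tie ordering and an entirely
  # uninformative (constant-score) ranker scores exactly the prevalence
  block_end <- rev(!duplicated(rev(predictor[ord])))
  end_idx <- which(block_end)
  block_of <- rep(seq_along(end_idx), diff(c(0, end_idx)))
  pr_auc <- sum(lab_sorted * precision[end_idx][block_of]) / n_pos

  fp <- cumsum(!lab_sorted)
  cut <- which(diff(c(predictor[ord], -Inf)) != 0)  # last index per tie block
  roc_points <- data.frame(fpr = c(0, fp[cut] / n_neg),
                           tpr = c(0, tp[cut] / n_pos))
  pr_points <- data.frame(recall = recall, precision = precision)
  structure(list(roc_auc = roc_auc, pr_auc = pr_auc,
                 roc_points = roc_points, pr_points = pr_points,
                 n_pos = n_pos, n_neg = n_neg),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: ROC AUC %.3f, PR AUC %.3f (%d positives, %d negatives; PR baseline %.3f)\n",
              x$roc_auc, x$pr_auc, x$n_pos, x$n_neg,
              x$n_pos / (x$n_pos + x$n_neg)))
  invisible(x)
}

#' Join a normalized synergy table with gold labels and benchmark it
#'
#' @param synergies a [normalize_synergies()] data frame (`pair`,
#'   `normalized`).
#' @param gold data frame with columns `pair` (canonical [pair_key()]) and
#'   `label` (1 = observed synergy). Every scored pair must be labeled.
#' @return a [benchmark()] result; pairs with `NA` normalized score are
#'   excluded.
#' @export
benchmark_synergies <- function(synergies, gold) {
  i <- match(synergies$pair, gold$pair)
  if (anyNA(i)) {
    stop("gold standard is missing label(s) for pair(s): ",
         paste(synergies$pair[is.na(i)], collapse = ", "))
  }
  benchmark(synergies$normalized, gold$label[i])
}

#' Paired bootstrap comparison of two rankers' AUCs
#'
#' Resamples the labeled pairs with replacement, stratified by class
#' (positives and negatives separately, so no resample is degenerate), and
#' recomputes both rankers' ROC and PR AUCs on each resample. The one-sided
#' p-value is the fraction of resamples in which `AUC(A) <= AUC(B)`, i.e.
#' small p supports A ranking better than B.
#'
#' @param score_a,score_b scores over the same labeled pairs (ascending =
#'   more synergistic).
#' @param label gold labels.
#' @param n_resamples bootstrap resamples (10000 for reported comparisons).
#' @return list with `p_roc`, `p_pr`, `n_resamples`, and the observed AUC
#'   differences `delta_roc`, `delta_pr` (A minus B).
#' @export
bootstrap_auc_compare <- function(score_a, score_b, label,
                                  n_resamples = 10000L) {
  label <- as.logical(label)
  pos <- which(label)
  neg <- which(!label)
  stopifnot(length(pos) >= 1, length(neg) >= 1,
            length(score_a) == length(label),
            length(score_b) == length(label))
  obs_a <- benchmark(score_a, label)
  obs_b <- benchmark(score_b, label)
  ge_roc <- 0L
  ge_pr <- 0L
  for (b in seq_len(n_resamples)) {
    idx <- c(pos[sample.int(length(pos), length(pos), replace = TRUE)],
             neg[sample.int(length(neg), length(neg), replace = TRUE)])
    ba <- benchmark(score_a[idx], label[idx])
    bb <- benchmark(score_b[idx], label[idx])
    if (ba$roc_auc <= bb$roc_auc) ge_roc <- ge_roc + 1L
    if (ba$pr_auc <= bb$pr_auc) ge_pr <- ge_pr + 1L
  }
  list(p_roc = ge_roc / n_resamples, p_pr = ge_pr / n_resamples,
       n_resamples = as.integer(n_resamples),
       delta_roc = obs_a$roc_auc - obs_b$roc_auc,
       delta_pr = obs_a$pr_auc - obs_b$pr_auc)
}

#' Parameterization-state agreement statistic
#'
#' For each node whose equation bears a link operator, the percentage of
#' (model, fixed point) observations in which the permissive operator
#' OR-NOT co-occurs with the active state (1) or the restrictive AND-NOT
#' with the inactive state (0). High agreement means the chosen operator
#' and the resulting stable state encode the same activity tendency.
#'
#' @param ensemble a [evolve()] result or list of models; every model must
#'   have at least one fixed point.
#' @return data frame with `node`, `observations`, `agreement` (percent),
#'   covering nodes that bear a link operator in at least one model.
#' @export
agreement_statistic <- function(ensemble) {
  models <- if (inherits(ensemble, "model_ensemble")) ensemble$models else ensemble
  stopifnot(length(models) >= 1)
  nodes <- models[[1]]$nodes
  agree <- setNames(numeric(length(nodes)), nodes)
  total <- setNames(numeric(length(nodes)), nodes)
  for (m in models) {
    att <- fixed_points(m)
    if (att$n == 0) {
      stop("agreement statistic requires every model to have a fixed point")
    }
    has_op <- m$op != .OP_NONE
    if (!any(has_op)) next
    st <- att$fixed_points[, m$nodes[has_op], drop = FALSE]
    op <- m$op[has_op]
    # OR-NOT (2) agrees with state 1, AND-NOT (1) with state 0
    hits <- t(st) == (op == .OP_OR_NOT)
    agree[m$nodes[has_op]] <- agree[m$nodes[has_op]] + rowSums(hits)
    total[m$nodes[has_op]] <- total[m$nodes[has_op]] + att$n
  }
  keep <- total > 0
  data.frame(node = nodes[keep], observations = as.integer(total[keep]),
             agreement = 100 * agree[keep] / total[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}
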