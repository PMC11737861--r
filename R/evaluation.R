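# PR/ROC evaluation, F1-optimal threshold selection, k-fold
# cross-validation, rank-sum group comparisons, and comparator tool
# benchmarking.

check_two_classes <- function(labels) {
  y <- coerce_binary_labels(labels)
  if (sum(y) == 0 || sum(!y) == 0) {
    stop("both classes must be present")
  }
  y
}

#' Precision-recall curve with F1-optimal threshold
#'
#' Evaluates classifier scores at every unique score value (predict positive
#' at score >= threshold). The area is the average precision
#' sum_k (R_k - R_(k-1)) * P_k (step interpolation; trapezoidal integration
#' over the PR points is available as an alternative, linear interpolation
#' in PR space being optimistic). The optimal threshold maximizes F1, ties
#' resolved toward the larger threshold (fewer false positives).
#'
#' @param scores Numeric classifier scores, higher = more pathogenic.
#' @param labels Binary labels (logical, 0/1, or `"LP_P"` vs other).
#' @param method `"step"` (average precision, default) or `"trapezoid"`.
#' @return An `eval_curve` with `points` (threshold, precision, recall, f1),
#'   `auprc`, `optimal_threshold`, `optimal_f1`.
#' @export
pr_curve <- function(scores, labels, method = c("step", "trapezoid")) {
  method <- match.arg(method)
  y <- check_two_classes(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y)
  tp <- vapply(thr, function(t) sum(y & scores >= t), numeric(1))
  pp <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  precision <- tp / pp
  recall <- tp / n_pos
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  auprc <- if (method == "step") {
    sum(diff(c(0, recall)) * precision)
  } else {
    sum(diff(c(0, recall)) * (precision + c(precision[1], utils::head(precision, -1))) / 2)
  }
  best <- which(f1 == max(f1))[1]  # thresholds are descending: first = largest
  structure(
    list(type = "pr",
         points = data.frame(threshold = thr, precision = precision,
                             recall = recall, f1 = f1),
         auprc = auprc, optimal_threshold = thr[best], optimal_f1 = f1[best],
         method = method),
    class = "eval_curve"
  )
}

#' ROC curve with rank-sum AUC
#'
#' The AUC is computed by the rank-sum identity U/(n1*n0) with ties
#' contributing one half, which equals trapezoidal integration of the tied
#' step curve (the equality is exercised as a package property test).
#'
#' @inheritParams pr_curve
#' @return An `eval_curve` with `points` (threshold, fpr, tpr) and `auroc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- check_two_classes(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y)
  n0 <- sum(!y)
  r <- rank(scores)
  auroc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!y] >= t), numeric(1))
  points <- data.frame(threshold = c(-Inf, thr, Inf), fpr = c(1, fpr, 0),
                       tpr = c(1, tpr, 0))
  structure(list(type = "roc", points = points, auroc = auroc),
            class = "eval_curve")
}

#' @export
print.eval_curve <- function(x, ...) {
  if (x$type == "pr") {
    cat(sprintf("PR curve: AUPRC = %.4f (%s), optimal threshold %.4g (F1 = %.4f)\n",
                x$auprc, x$method, x$optimal_threshold, x$optimal_f1))
  } else {
    cat(sprintf("ROC curve: AUROC = %.4f\n", x$auroc))
  }
  invisible(x)
}

f1_at_threshold <- function(scores, labels, threshold = 0.5) {
  y <- coerce_binary_labels(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y)
  if (tp == 0) return(0)
  precision <- tp / sum(pred)
  recall <- tp / sum(y)
  2 * precision * recall / (precision + recall)
}

make_folds <- function(n, k) sample(rep(seq_len(k), length.out = n))

#' k-fold cross-validation of a pathogenicity model
#'
#' Unstratified folds of near-equal size (differing by at most one) are
#' drawn under the given seed; the model is fit on k-1 folds and scored on
#' the held-out fold. Per-fold F1 uses the fixed 0.5 threshold; AUPRC uses
#' the full score range. Folds in which either side lacks a class (or, for
#' the logistic model, whose training side misses a gene level) are redrawn
#' up to a retry cap.
#'
#' @param training Output of [build_training_set()] or its `examples`.
#' @param model_kind `"lrm"` or `"rfm"` (forest folds reuse the 350-tree /
#'   4-variable hyperparameters).
#' @param k Number of folds (8 for the logistic model and 10 for the forest
#'   in the reference analysis).
#' @param seed Fold-assignment seed.
#' @param max_retries Fold redraw cap.
#' @param ... Passed to the fitting function.
#' @return A `cv_result`: `k`, `per_fold` (f1, auprc), `mean_f1`,
#'   `mean_auprc`, `fold_assignment_seed`.
#' @export
cross_validate <- function(training, model_kind = c("lrm", "rfm"), k = 10,
                           seed = 1, max_retries = 20, ...) {
  model_kind <- match.arg(model_kind)
  ex <- if (is.data.frame(training)) training else training$examples
  n <- nrow(ex)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of examples")
  set.seed(seed)
  folds <- NULL
  for (try in seq_len(max_retries)) {
    cand <- make_folds(n, k)
    ok <- all(vapply(seq_len(k), function(f) {
      tr <- ex[cand != f, , drop = FALSE]
      te <- ex[cand == f, , drop = FALSE]
      both <- length(unique(tr$label)) == 2 && length(unique(te$label)) == 2
      if (model_kind == "lrm") {
        both <- both && all(unique(te$gene) %in% unique(tr$gene))
      }
      both
    }, logical(1)))
    if (ok) { folds <- cand; break }
  }
  if (is.null(folds)) {
    stop("could not draw folds with both classes on each side within ",
         max_retries, " attempts")
  }
  per_fold <- data.frame(f1 = numeric(k), auprc = numeric(k))
  for (f in seq_len(k)) {
    tr <- ex[folds != f, , drop = FALSE]
    te <- ex[folds == f, , drop = FALSE]
    model <- if (model_kind == "lrm") {
      fit_lrm(tr, ...)
    } else {
      fit_rfm(tr, ...)
    }
    sc <- predict(model, te)
    per_fold$f1[f] <- f1_at_threshold(sc, te$label, 0.5)
    per_fold$auprc[f] <- pr_curve(sc, te$label)$auprc
  }
  structure(
    list(k = k, per_fold = per_fold, mean_f1 = mean(per_fold$f1),
         mean_auprc = mean(per_fold$auprc), fold_assignment_seed = seed,
         folds = folds),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d): mean F1 = %.3f, mean AUPRC = %.3f\n",
              x$k, x$fold_assignment_seed, x$mean_f1, x$mean_auprc))
  invisible(x)
}

#' Mann-Whitney rank-sum comparison of two score groups
#'
#' U counts the pairs in which a group-a score exceeds a group-b score, with
#' ties contributing one half; the probability of superiority is
#' U/(n_a * n_b). The two-sided p-value uses the exact distribution for
#' small tie-free samples and the tie-corrected normal approximation
#' otherwise.
#'
#' @param group_a,group_b Numeric score vectors.
#' @return A list with `U`, `p_value`, `probability_of_superiority`.
#' @export
rank_sum_compare <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  na <- length(group_a)
  nb <- length(group_b)
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  p <- suppressWarnings(stats::wilcox.test(group_a, group_b)$p.value)
  list(U = U, p_value = p, probability_of_superiority = U / (na * nb))
}

#' Default score-orientation map for comparator in-silico tools
#'
#' `+1` means higher scores indicate pathogenicity; `-1` (SIFT) means lower
#' scores do and the score is negated before evaluation.
#'
#' @return Named numeric vector of orientations.
#' @export
tool_orientation <- function() {
  c(SIFT = -1, PolyPhen2 = 1, REVEL = 1, CADD = 1, VARITY = 1,
    AlphaMissense = 1, PrimateAI = 1, VEST4 = 1, MutPred2 = 1,
    LRM = 1, RFM = 1)
}

#' Benchmark comparator in-silico tools on labelled variants
#'
#' Computes AUPRC and AUROC per tool column after normalizing score
#' direction, with pairwise deletion of missing scores (the number of
#' variants actually used is reported per tool).
#'
#' @param records Data.frame holding one column per tool.
#' @param labels Binary labels aligned with `records` rows.
#' @param tools Character vector of tool column names.
#' @param orientation Named orientation map, see [tool_orientation()];
#'   every tool must have an entry.
#' @return Data.frame (tool, n_used, auprc, auroc), ranked by AUPRC.
#' @export
compare_tools <- function(records, labels, tools,
                          orientation = tool_orientation()) {
  missing_tools <- setdiff(tools, names(records))
  if (length(missing_tools) > 0) {
    stop("tool column(s) absent: ", paste(missing_tools, collapse = ", "))
  }
  no_orient <- setdiff(tools, names(orientation))
  if (length(no_orient) > 0) {
    stop("no orientation entry for tool(s): ",
         paste(no_orient, collapse = ", "))
  }
  y <- coerce_binary_labels(labels)
  rows <- lapply(tools, function(tool) {
    s <- suppressWarnings(as.numeric(records[[tool]])) * orientation[[tool]]
    keep <- !is.na(s)
    data.frame(tool = tool, n_used = sum(keep),
               auprc = pr_curve(s[keep], y[keep])$auprc,
               auroc = roc_curve(s[keep], y[keep])$auroc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auprc), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
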