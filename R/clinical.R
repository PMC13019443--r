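# DXA T-score prediction from spectra (single-response PLS with
# leave-one-subject-out cross-validation and rank search), WHO
# classification, confusion-matrix metrics and pairwise ROC analysis.

#' WHO bone-health classes, in severity order
#' @return `c("Normal", "Osteopenia", "Osteoporosis")`
#' @export
who_classes <- function() c("Normal", "Osteopenia", "Osteoporosis")

#' WHO T-score classification rule
#'
#' Cutoffs at -1.0 and -2.5 T-score units with the standard boundary
#' convention: Normal is T > -1, Osteopenia is -2.5 < T <= -1 (both
#' boundaries belong to the sicker side), Osteoporosis is T <= -2.5. The
#' osteopenia band therefore spans exactly 1.5 T-score units.
#'
#' @param normal_cutoff upper boundary of osteopenia (default -1).
#' @param op_cutoff upper boundary of osteoporosis (default -2.5).
#' @return a list of class `who_rule`.
#' @export
who_rule <- function(normal_cutoff = -1.0, op_cutoff = -2.5) {
  stopifnot(op_cutoff < normal_cutoff)
  structure(list(normal_cutoff = normal_cutoff, op_cutoff = op_cutoff),
            class = "who_rule")
}

#' Classify T-scores into WHO bone-health categories
#'
#' @param t numeric T-score(s); must be finite.
#' @param rule a [who_rule()].
#' @return a factor with levels `Normal`, `Osteopenia`, `Osteoporosis`.
#' @examples
#' classify_who(c(0.05, -1, -2.5, -4.19))
#' @export
classify_who <- function(t, rule = who_rule()) {
  t <- as.numeric(t)
  if (any(!is.finite(t)))
    stop("T-scores must be finite", call. = FALSE)
  cls <- ifelse(t > rule$normal_cutoff, "Normal",
                ifelse(t > rule$op_cutoff, "Osteopenia", "Osteoporosis"))
  factor(cls, levels = who_classes())
}

#' Leave-one-subject-out T-score regression with rank search
#'
#' Single-response PLS regression of DXA T-scores on one representative
#' spectrum per subject (conventionally the D2P1 midpoint site). For
#' every candidate rank a full leave-one-subject-out pass produces
#' per-subject predictions; in the default `"pooled"` mode one rank is
#' chosen as the minimizer of the pooled RMSE of cross-validation
#' (smallest rank on ties), and the reported Pearson r and RMSE_CV are
#' those of the chosen rank's held-out predictions. In `"per_fold"` mode
#' each outer fold instead re-selects its own rank by an inner
#' leave-one-out on the training subjects.
#'
#' @param X numeric N x P matrix, one spectrum per subject.
#' @param tscores numeric N-vector of measured T-scores.
#' @param subjects optional subject ids (default `s1..sN`).
#' @param ranks candidate ranks (default 1:15, capped at feasibility).
#' @param mode `"pooled"` (default) or `"per_fold"`.
#' @return an object of class `tscore_cv`: `predicted` (named), `tscores`,
#'   `chosen_rank` (scalar, or per-subject vector in `"per_fold"` mode),
#'   `ranks`, `rmse_by_rank` (pooled mode), `pearson_r`, `rmse_cv`.
#' @export
fit_tscore_loso <- function(X, tscores, subjects = NULL, ranks = 1:15,
                            mode = c("pooled", "per_fold")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 4) stop("need at least 4 subjects", call. = FALSE)
  stopifnot(length(tscores) == N)
  if (is.null(subjects)) subjects <- paste0("s", seq_len(N))
  ranks <- sort(unique(as.integer(ranks)))
  a_feas <- min(N - 2, ncol(X))  # each fold trains on N-1 rows
  if (min(ranks) > a_feas)
    stop("no candidate rank feasible for N-1 = ", N - 1,
         " training subjects", call. = FALSE)
  ranks <- ranks[ranks <= a_feas]
  a_max <- max(ranks)

  loso_pred_by_rank <- function(Xm, y) {
    # matrix of held-out predictions, rows = subjects, cols = ranks
    n <- nrow(Xm)
    out <- matrix(NA_real_, n, length(ranks))
    for (i in seq_len(n)) {
      fit <- fit_pls2(Xm[-i, , drop = FALSE],
                      matrix(y[-i], ncol = 1), a_max)
      for (j in seq_along(ranks))
        out[i, j] <- predict_at_rank(fit, Xm[i, , drop = FALSE],
                                     min(ranks[j], fit$A))[1, 1]
    }
    out
  }

  if (mode == "pooled") {
    preds <- loso_pred_by_rank(X, tscores)
    rmse_by_rank <- sqrt(colMeans((preds - tscores)^2))
    chosen <- ranks[which.min(rmse_by_rank)]
    predicted <- preds[, which.min(rmse_by_rank)]
  } else {
    predicted <- numeric(N)
    chosen <- integer(N)
    for (i in seq_len(N)) {
      inner <- loso_pred_by_rank(X[-i, , drop = FALSE], tscores[-i])
      inner_rmse <- sqrt(colMeans((inner - tscores[-i])^2))
      a_i <- ranks[which.min(inner_rmse)]
      fit <- fit_pls2(X[-i, , drop = FALSE],
                      matrix(tscores[-i], ncol = 1), a_i)
      predicted[i] <- predict(fit, X[i, , drop = FALSE])[1, 1]
      chosen[i] <- a_i
    }
    rmse_by_rank <- NULL
  }
  names(predicted) <- subjects
  structure(list(predicted = predicted, tscores = tscores,
                 subjects = subjects, ranks = ranks,
                 rmse_by_rank = rmse_by_rank, chosen_rank = chosen,
                 pearson_r = stats::cor(predicted, tscores),
                 rmse_cv = sqrt(mean((predicted - tscores)^2)),
                 mode = mode),
            class = "tscore_cv")
}

#' @export
print.tscore_cv <- function(x, ...) {
  cat(sprintf(paste0("<tscore_cv> %d subjects, mode = %s, rank = %s\n",
                     "  r = %.3f, RMSE_CV = %.3f\n"),
              length(x$predicted), x$mode,
              paste(unique(x$chosen_rank), collapse = "/"),
              x$pearson_r, x$rmse_cv))
  invisible(x)
}

#' 3x3 confusion matrix over WHO classes
#'
#' @param true,predicted class labels (character or factor over
#'   `Normal`, `Osteopenia`, `Osteoporosis`); equal length.
#' @return an integer 3x3 matrix, rows = true class, columns = predicted
#'   class, in fixed class order.
#' @export
confusion <- function(true, predicted) {
  lv <- who_classes()
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("true and predicted lengths differ", call. = FALSE)
  bad <- setdiff(unique(c(true, predicted)), lv)
  if (length(bad) > 0)
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(true) == 0)
    warning("empty input; returning an all-zero confusion matrix")
  cm <- table(factor(true, levels = lv), factor(predicted, levels = lv))
  matrix(as.integer(cm), 3, 3, dimnames = list(true = lv, predicted = lv))
}

#' Per-class one-vs-rest classification metrics
#'
#' Each WHO class in turn is treated as positive and the other two pooled
#' as negative, giving TP/FP/FN/TN and from them precision TP/(TP+FP),
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP) and accuracy
#' (TP+TN)/(TP+FP+TN+FN) over the full cohort denominator. An undefined
#' 0/0 ratio (e.g. precision of a never-predicted class) is reported as
#' `NA` with a warning, never silently as 0.
#'
#' @param cm a 3x3 confusion matrix from [confusion()].
#' @return a data.frame, one row per class: `precision`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
class_metrics <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == 3))
  n <- sum(cm)
  if (n == 0) stop("confusion matrix is empty", call. = FALSE)
  safe_div <- function(num, den, what, cl) {
    if (den == 0) {
      warning(what, " undefined (0/0) for class '", cl, "'; reported NA")
      return(NA_real_)
    }
    num / den
  }
  lv <- rownames(cm)
  rows <- lapply(seq_len(3), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    tn <- n - tp - fp - fn
    data.frame(who_class = lv[k],
               precision = safe_div(tp, tp + fp, "precision", lv[k]),
               sensitivity = safe_div(tp, tp + fn, "sensitivity", lv[k]),
               specificity = safe_div(tn, tn + fp, "specificity", lv[k]),
               accuracy = (tp + tn) / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise ROC curve and AUC
#'
#' One-vs-one ROC between two WHO classes using continuous decision
#' scores in which higher means more diseased (conventionally the
#' negated predicted T-score). The positive class is the more diseased
#' member of the pair. The AUC equals the Mann-Whitney U statistic
#' normalized by n1*n2, with half credit for ties.
#'
#' @param scores numeric decision scores, one per subject.
#' @param classes class label per subject.
#' @param pair two class labels; the later one in WHO severity order is
#'   taken as positive.
#' @return a list: `curve` (data.frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `positive`.
#' @export
pairwise_roc <- function(scores, classes, pair) {
  stopifnot(length(scores) == length(classes), length(pair) == 2)
  classes <- as.character(classes)
  sev <- match(pair, who_classes())
  if (any(is.na(sev))) stop("unknown class in pair", call. = FALSE)
  positive <- pair[which.max(sev)]
  negative <- pair[which.min(sev)]
  sp <- scores[classes == positive]
  sn <- scores[classes == negative]
  if (length(sp) == 0 || length(sn) == 0)
    stop("both classes of the pair must be non-empty among scored ",
         "subjects", call. = FALSE)
  # AUC via pair counting with 0.5 credit for ties
  grid <- outer(sp, sn, `-`)
  auc <- mean((grid > 0) + 0.5 * (grid == 0))
  thr <- c(Inf, sort(unique(c(sp, sn)), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(th) mean(sn >= th), 0),
    tpr = vapply(thr, function(th) mean(sp >= th), 0))
  list(curve = curve, auc = auc, positive = positive,
       negative = negative)
}
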