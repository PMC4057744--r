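# Leave-one-out cross-validation and binary-classification statistics.

#' Confusion matrix of binary calls
#'
#' @param predicted,actual Character vectors of `"D"`/`"N"` calls.
#' @return List of class `gm_confusion` with counts `tp` (predicted D,
#'   actual D), `fp`, `fn`, `tn` and `total`.
#' @export
confusion_matrix <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  ok <- c("D", "N")
  if (!all(predicted %in% ok) || !all(actual %in% ok))
    stop("calls must be \"D\" or \"N\"", call. = FALSE)
  structure(list(
    tp = sum(predicted == "D" & actual == "D"),
    fp = sum(predicted == "D" & actual == "N"),
    fn = sum(predicted == "N" & actual == "D"),
    tn = sum(predicted == "N" & actual == "N"),
    total = length(predicted)
  ), class = "gm_confusion")
}

#' Build a confusion matrix from counts
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A `gm_confusion` list.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total = tp + fp + fn + tn), class = "gm_confusion")
}

#' @export
print.gm_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(predicted = c("D", "N"),
                              actual = c("D", "N")))
  print(m)
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' Balanced binary-classification quality in `[-1, 1]`; robust to unequal
#' class sizes. When any marginal is zero MCC is undefined; 0 is returned
#' with attribute `degenerate = TRUE`.
#'
#' @param cm A `gm_confusion` object.
#' @return Scalar MCC.
#' @export
mcc <- function(cm) {
  margins <- c(cm$tp + cm$fp, cm$tp + cm$fn, cm$tn + cm$fp, cm$tn + cm$fn)
  if (any(margins == 0))
    return(structure(0, degenerate = TRUE))
  (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(prod(margins))
}

#' Sensitivity and specificity
#'
#' `TP/(TP+FN)` and `TN/(TN+FP)`; `NA` sentinel where a denominator is
#' zero.
#'
#' @param cm A `gm_confusion` object.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(cm) {
  c(sensitivity = if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_,
    specificity = if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else NA_real_)
}

#' Chi-squared statistic against random allocation
#'
#' Pearson chi-squared of independence (1 df, no continuity correction) on
#' the 2x2 confusion matrix — the test of whether the classifier does
#' better than random assignment. Satisfies the identity
#' `chi^2 = total * MCC^2`.
#'
#' @param cm A `gm_confusion` object.
#' @return Scalar statistic.
#' @export
chi_squared_vs_random <- function(cm) {
  if (cm$total == 0) stop("empty confusion matrix", call. = FALSE)
  cm$total * as.numeric(mcc(cm))^2
}

#' ROC curve and AUC over normalised scores
#'
#' Higher scores rank as more deleterious. The curve steps through every
#' distinct threshold; the AUC is the trapezoidal area, equivalently the
#' tie-averaged Mann-Whitney probability that a random deleterious variant
#' outscores a random neutral one.
#'
#' @param scores Numeric scores.
#' @param labels `"D"`/`"N"` truth labels (both classes required).
#' @return List with `curve` (data frame `fpr`, `tpr` ordered from (0,0)
#'   to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  is_d <- labels == "D"
  n_d <- sum(is_d); n_n <- sum(!is_d)
  if (n_d == 0L || n_n == 0L)
    stop("ROC needs both classes present", call. = FALSE)
  # tie-averaged rank AUC
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[is_d]) - n_d * (n_d + 1) / 2) / (n_d * n_n)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[is_d] >= t) / n_d, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!is_d] >= t) / n_n, numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  list(curve = curve, auc = auc)
}

#' MCC as a function of the score cut-off
#'
#' Sweeps a grid of cut-offs over the normalised scores, predicting
#' deleterious at or above each cut-off, and reports the MCC at every
#' grid point plus the peak location. The default grid places a point
#' below, between and above every distinct score.
#'
#' @param scores Numeric scores.
#' @param labels `"D"`/`"N"` truth labels.
#' @param grid Optional numeric vector of cut-offs.
#' @return Data frame `cutoff`, `mcc`, with the peak in
#'   `attr(, "peak")`.
#' @export
mcc_sweep <- function(scores, labels, grid = NULL) {
  is_d <- labels == "D"
  if (sum(is_d) == 0L || sum(!is_d) == 0L)
    stop("cut-off sweep needs both classes present", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) < 2L)
    stop("cut-off sweep needs at least two distinct scores", call. = FALSE)
  if (is.null(grid)) {
    mid <- (u[-1] + u[-length(u)]) / 2
    step <- stats::median(diff(u))
    grid <- c(u[1] - step, u, mid, u[length(u)] + step)
    grid <- sort(unique(grid))
  }
  vals <- vapply(grid, function(ct) {
    pred <- ifelse(scores >= ct, "D", "N")
    as.numeric(mcc(confusion_matrix(pred, labels)))
  }, numeric(1))
  out <- data.frame(cutoff = grid, mcc = vals)
  attr(out, "peak") <- out$cutoff[which.max(out$mcc)]
  out
}

#' Leave-one-out cross-validation over gene panels
#'
#' For every gene with at least `min_per_class` labelled variants per
#' class, each variant is classified by a model trained on the remaining
#' variants of the same gene (the held-out variant never enters training).
#' Genes failing the filter are reported with reasons. Fold seeds are
#' derived deterministically from the master seed, so the whole procedure
#' is reproducible.
#'
#' @param panels Named list: one entry per gene, each a list with elements
#'   `alignment` ([gm_alignment()]) and `variants` (data frame).
#' @param mode,r,control Passed to [gm_train()].
#' @param seed Master seed for the per-fold swarm seeds.
#' @param min_per_class Gene inclusion filter (default 3: leaves >= 2 per
#'   class in every training fold, the minimum for a meaningful standard
#'   deviation).
#' @return List of class `gm_loo`: `predictions` (data frame with the
#'   variant columns, `gm`, `score`, `pred`, `fold_train_d`,
#'   `fold_train_n`, `classified`) and `excluded` (data frame `gene`,
#'   `reason`).
#' @export
loo_cv <- function(panels, mode = c("k_only", "all_five"), r = 2.47,
                   control = gm_control(), seed = NULL, min_per_class = 3L) {
  mode <- match.arg(mode)
  predictions <- list()
  excluded <- list()
  for (gene in names(panels)) {
    panel <- panels[[gene]]
    variants <- panel$variants
    labelled <- variants[variants$label %in% c("D", "N"), , drop = FALSE]
    n_d <- sum(labelled$label == "D"); n_n <- sum(labelled$label == "N")
    if (n_d < min_per_class || n_n < min_per_class) {
      excluded[[gene]] <- data.frame(
        gene = gene,
        reason = paste0("insufficient ",
                        if (n_d < min_per_class) "deleterious" else "neutral",
                        " variants (", min(n_d, n_n), " < ", min_per_class, ")"))
      next
    }
    features <- variant_features(panel$alignment, labelled)
    fold_seeds <- derive_seeds(seed, nrow(features))
    for (i in seq_len(nrow(features))) {
      train_feat <- features[-i, , drop = FALSE]
      fit <- gm_train(features = train_feat, mode = mode, r = r,
                      control = control, seed = fold_seeds[[i]], gene = gene,
                      alignment = NULL, variants = NULL)
      row <- labelled[i, , drop = FALSE]
      m <- compute_metrics(features[i, , drop = FALSE], fit$params)
      classified <- fit$valid_orientation && fit$cutoff > 0
      row$gm <- m$gm
      row$score <- if (classified && m$gm > 0) log(m$gm / fit$cutoff)
                   else NA_real_
      row$pred <- if (classified) classify_binary(m$gm, fit$cutoff)
                  else NA_character_
      row$fold_train_d <- sum(train_feat$label == "D")
      row$fold_train_n <- sum(train_feat$label == "N")
      row$classified <- classified
      predictions[[length(predictions) + 1L]] <- row
    }
  }
  if (length(predictions) == 0L)
    stop("no gene passed the inclusion filter of >= ", min_per_class,
         " variants per class", call. = FALSE)
  structure(list(
    predictions = do.call(rbind, c(predictions, make.row.names = FALSE)),
    excluded = if (length(excluded))
      do.call(rbind, c(excluded, make.row.names = FALSE))
    else data.frame(gene = character(), reason = character())
  ), class = "gm_loo")
}

#' @export
print.gm_loo <- function(x, ...) {
  cat("Leave-one-out cross-validation:", nrow(x$predictions),
      "variant folds;", nrow(x$excluded), "gene(s) excluded\n")
  invisible(x)
}

#' Summarise leave-one-out predictions
#'
#' Pools the gene-normalised scores across genes (the purpose of the
#' normalisation) and reports the confusion matrix at the theoretical
#' cut-off (score 0, i.e. GM = C), MCC, sensitivity, specificity, the
#' chi-squared statistic against random allocation, the ROC curve with
#' AUC, and the MCC-vs-cutoff sweep.
#'
#' @param x A `gm_loo` object (or any data frame with `pred`, `label`,
#'   `score`, `classified` columns).
#' @return List of class `gm_evaluation`.
#' @export
evaluation_report <- function(x) {
  pred <- if (inherits(x, "gm_loo")) x$predictions else x
  scored <- pred[!is.na(pred$pred) & !is.na(pred$score), , drop = FALSE]
  cm <- confusion_matrix(scored$pred, scored$label)
  roc <- roc_auc(scored$score, scored$label)
  structure(list(
    confusion = cm,
    mcc = as.numeric(mcc(cm)),
    sensitivity = sensitivity_specificity(cm)[["sensitivity"]],
    specificity = sensitivity_specificity(cm)[["specificity"]],
    chi_squared = chi_squared_vs_random(cm),
    roc = roc$curve,
    auc = roc$auc,
    sweep = mcc_sweep(scored$score, scored$label),
    n_scored = nrow(scored),
    n_unclassified = sum(is.na(pred$pred))
  ), class = "gm_evaluation")
}

#' @export
print.gm_evaluation <- function(x, digits = 4, ...) {
  cat("Binary classification over", x$n_scored, "variants",
      if (x$n_unclassified > 0)
        paste0("(", x$n_unclassified, " unclassified)"), "\n")
  print(x$confusion)
  cat("MCC:", round(x$mcc, digits),
      " sensitivity:", round(x$sensitivity, digits),
      " specificity:", round(x$specificity, digits), "\n")
  cat("chi-squared (1 df) vs random:", round(x$chi_squared, 2), "\n")
  cat("AUC:", round(x$auc, digits),
      " MCC peak at score cut-off", round(attr(x$sweep, "peak"), digits),
      "\n")
  invisible(x)
}
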