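# Sex classification: ROC threshold sweep with Mann-Whitney AUC, binary
# logistic regression (IRLS via stats::glm), and the fixed 45-degree
# cut-off rule (angle above 45 degrees -> female, 45 or below -> male).

#' ROC curve and AUC for a score against sex
#'
#' Sweeps thresholds over the unique score values (ties grouped into one
#' step) with the orientation "higher score predicts the positive class".
#' The AUC equals the Mann-Whitney probability that a random positive
#' outscores a random negative, with half credit for ties; it is reported
#' as-is, so a score that runs counter to its orientation yields an AUC
#' below 0.5 (it is not flipped).
#'
#' @param table a `cohort_table`.
#' @param score name of the score column.
#' @param positive sex label treated as positive (default `"F"`: females
#'   are expected to have the larger lateral angle).
#' @return an object of class `"roc_result"` with `thresholds`, `fpr`,
#'   `tpr`, `auc`, `positive_label`, `orientation`.
#' @export
roc_curve <- function(table, score = "lateral_angle_deg", positive = "F") {
  df <- as.data.frame(table)
  keep <- !is.na(df[[score]]) & !is.na(df$sex)
  s <- df[[score]][keep]
  y <- df$sex[keep] == positive
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("both sex labels must be present among complete cases",
         call. = FALSE)
  o <- order(s, decreasing = TRUE)
  ss <- s[o]; yy <- y[o]
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(rowsum(as.numeric(yy), grp, reorder = FALSE))
  fp <- cumsum(rowsum(as.numeric(!yy), grp, reorder = FALSE))
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  thresholds <- c(Inf, unique(ss))
  # Mann-Whitney AUC with half credit for ties; identical to the
  # trapezoidal area under the tie-grouped sweep.
  r <- rank(s)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(thresholds = as.numeric(thresholds), fpr = as.numeric(fpr),
                 tpr = as.numeric(tpr), auc = auc, positive_label = positive,
                 orientation = "higher-score->positive",
                 n_positive = n1, n_negative = n0, score = score),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC for ", x$score, " (positive = ", x$positive_label, ", ",
      x$orientation, "): AUC = ", format(x$auc, digits = 4L),
      "  [", x$n_positive, " positive / ", x$n_negative, " negative]\n",
      sep = "")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC: %s (AUC = %.3f)", x$score, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-optimal threshold of a ROC curve
#'
#' Convenience: the threshold maximizing `tpr - fpr`.
#'
#' @param roc a `roc_result`.
#' @return a one-row data frame with `threshold`, `tpr`, `fpr`, `youden`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$tpr - roc$fpr
  i <- which.max(j)
  data.frame(threshold = roc$thresholds[i], tpr = roc$tpr[i],
             fpr = roc$fpr[i], youden = j[i])
}

#' Binary logistic regression of sex on one predictor
#'
#' Maximum-likelihood logit fit by iteratively reweighted least squares
#' (tolerance 1e-8 on the deviance change, at most 100 iterations),
#' deterministic from the data. Perfect separation is detected and raised
#' as an explicit error rather than returning silently diverging
#' coefficients.
#'
#' @param table a `cohort_table`.
#' @param predictor name of the predictor column.
#' @param label name of the label column (default `"sex"`).
#' @param positive label modelled as 1.
#' @return an object of class `"logistic_fit"` with a coefficient table,
#'   `converged`, `n_used` and `log_likelihood`.
#' @export
fit_logistic <- function(table, predictor, label = "sex", positive = "F") {
  df <- as.data.frame(table)
  keep <- !is.na(df[[predictor]]) & !is.na(df[[label]])
  x <- df[[predictor]][keep]
  yv <- df[[label]][keep] == positive
  if (all(yv) || !any(yv))
    stop("both classes must be present among complete cases", call. = FALSE)
  if (max(x[!yv]) < min(x[yv]) || max(x[yv]) < min(x[!yv]))
    stop("perfect separation: '", predictor,
         "' splits the classes exactly; logistic coefficients diverge",
         call. = FALSE)
  near_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(yv ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        near_sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (near_sep)
    warning("near-separation: some fitted probabilities are numerically ",
            "0 or 1; estimates may be unstable", call. = FALSE)
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = c("(Intercept)", predictor),
                      estimate = ct[, 1L], se = ct[, 2L], z = ct[, 3L],
                      p = ct[, 4L], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, converged = fit$converged,
                 n_used = length(yv),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 positive_label = positive, predictor = predictor,
                 glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 4L, ...) {
  cat("Logistic regression: P(", x$positive_label, ") ~ ", x$predictor,
      "  [n = ", x$n_used, ", logLik = ",
      format(x$log_likelihood, digits = digits),
      if (!x$converged) ", NOT converged", "]\n", sep = "")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Fixed cut-off sex classification
#'
#' Applies the classic rule exactly: a score strictly above the cut-off
#' classifies female; a score at or below it (including exactly 45
#' degrees under the default) classifies male.
#'
#' @param table a `cohort_table` with known sex labels.
#' @param score score column, by default the lateral angle.
#' @param cutoff cut-off in the score's units (default 45 degrees).
#' @return an object of class `"cutoff_report"` with overall and per-sex
#'   accuracy and the 2x2 confusion table.
#' @export
classify_cutoff <- function(table, score = "lateral_angle_deg", cutoff = 45) {
  df <- as.data.frame(table)
  keep <- !is.na(df[[score]]) & !is.na(df$sex)
  s <- df[[score]][keep]
  truth <- factor(df$sex[keep], levels = c("F", "M"))
  pred <- factor(ifelse(s > cutoff, "F", "M"), levels = c("F", "M"))
  confusion <- table(truth = truth, predicted = pred)
  acc <- mean(pred == truth)
  per_sex <- vapply(c("F", "M"), function(sx) {
    idx <- truth == sx
    if (!any(idx)) NA_real_ else mean(pred[idx] == sx)
  }, numeric(1L))
  structure(list(cutoff = cutoff, rule = "score > cutoff -> F, else M",
                 accuracy = acc, per_sex_accuracy = per_sex,
                 confusion = confusion, n_used = length(s), score = score),
            class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat("Cut-off classification (", x$score, " > ", x$cutoff, " -> F): ",
      "accuracy ", format(x$accuracy, digits = 4L), " on ", x$n_used,
      " specimens (F: ", format(x$per_sex_accuracy[["F"]], digits = 4L),
      ", M: ", format(x$per_sex_accuracy[["M"]], digits = 4L), ")\n",
      sep = "")
  print(x$confusion)
  invisible(x)
}
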