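#' Empirical ROC curve and AUC
#'
#' Fixed orientation: a subject is called positive when its score is greater
#' than or equal to the threshold, so higher scores must indicate the positive
#' class (no automatic direction flipping; the orientation is recorded in the
#' result). Thresholds are the distinct observed scores plus `Inf` (nobody
#' positive). The AUC is the Mann-Whitney concordance probability with ties
#' counted one half, which equals the trapezoid area under the empirical ROC.
#'
#' @param scores Numeric marker values, one per subject (no `NA`).
#' @param labels Binary outcome (logical or 0/1); both classes must occur.
#' @return A list of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `direction` (`">="`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels))
    stop("scores and labels must not contain NA", call. = FALSE)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both outcome classes must be present", call. = FALSE)
  thresholds <- c(sort(unique(scores)), Inf)
  sens <- vapply(thresholds, function(t) sum(scores >= t & labels) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores < t & !labels) / n_neg,
                 numeric(1))
  # Mann-Whitney with half ties: rank-sum formulation, O(n log n)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc, direction = ">=",
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the ROC thresholds; ties
#' on J resolve to the lowest threshold (the most sensitive operating point),
#' deterministically.
#'
#' @param roc A [roc_auc()] result.
#' @return A list of class `cutoff_result`: `threshold`, `youden_j`,
#'   `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  pick <- best[which.min(roc$thresholds[best])]
  structure(list(threshold = roc$thresholds[pick], youden_j = j[pick],
                 sensitivity = roc$sensitivity[pick],
                 specificity = roc$specificity[pick]),
            class = "cutoff_result")
}

#' One-year progression-free survival labels
#'
#' Binary label for discriminating PFS beyond a horizon: `TRUE` when the
#' follow-up time exceeds the horizon, `FALSE` when progression/death occurred
#' at or before it, and `NA` for subjects censored at or before the horizon,
#' whose status is unknown (they are excluded from ROC analyses; the exclusion
#' count is recorded).
#'
#' @param time Follow-up times, days.
#' @param event Event flags (1 = progression/death observed).
#' @param horizon Days (default 365).
#' @return Logical vector with attribute `n_excluded`.
#' @export
label_pfs_over_horizon <- function(time, event, horizon = 365) {
  out <- rep(NA, length(time))
  out[time > horizon] <- TRUE
  out[event == 1 & time <= horizon] <- FALSE
  attr(out, "n_excluded") <- sum(is.na(out))
  out
}

# shared Harrell optimism loop: metric_fn(model, data) must return one number,
# fit_fn(data) a model, valid_fn(data) whether a resample is usable
harrell_optimism <- function(data, fit_fn, metric_fn, valid_fn, n_boot,
                             resample_fn = NULL, max_redraw = 50) {
  n <- nrow(data)
  if (is.null(resample_fn))
    resample_fn <- function(n) sample.int(n, n, replace = TRUE)
  model_full <- fit_fn(data)
  apparent <- metric_fn(model_full, data)
  optimism <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    for (attempt in seq_len(max_redraw + 1)) {
      boot <- data[resample_fn(n), , drop = FALSE]
      if (valid_fn(boot)) break
      n_redrawn <- n_redrawn + 1L
      if (attempt > max_redraw)
        stop("could not draw a usable bootstrap resample after ",
             max_redraw, " redraws", call. = FALSE)
    }
    model_b <- fit_fn(boot)
    optimism[b] <- metric_fn(model_b, boot) - metric_fn(model_b, data)
  }
  structure(list(apparent = apparent, optimism = mean(optimism),
                 corrected = apparent - mean(optimism), n_boot = n_boot,
                 n_redrawn = n_redrawn),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(
    "<validation_result> apparent=%.4f optimism=%.4f corrected=%.4f (n_boot=%d)\n",
    x$apparent, x$optimism, x$corrected, x$n_boot))
  invisible(x)
}

#' Bootstrap optimism-corrected AUC of a logistic model
#'
#' Harrell's internal-validation procedure for the single-covariate logistic
#' model predicting a one-year event: refit on each bootstrap resample (with
#' replacement, no stratification), evaluate the resample-fitted model's AUC
#' on the resample and on the original data, and average the difference.
#' `corrected = apparent - mean(optimism)`. Resamples containing a single
#' outcome class are redrawn (counted in `n_redrawn`).
#'
#' @param scores Numeric marker values (not constant).
#' @param labels Binary outcome; both classes present.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Optional integer seed.
#' @param resample_fn Optional resampling hook `function(n) -> indices`
#'   (used for exactness checks; default bootstrap with replacement).
#' @return A `validation_result`: `apparent`, `optimism`, `corrected`,
#'   `n_boot`, `n_redrawn`, plus `seed`.
#' @export
bootstrap_optimism_auc <- function(scores, labels, n_boot = 1000,
                                   seed = NULL, resample_fn = NULL) {
  labels <- as.logical(labels)
  stopifnot(n_boot >= 1)
  if (sd(scores) == 0)
    stop("degenerate data: scores are constant", call. = FALSE)
  if (sum(labels) == 0 || sum(!labels) == 0)
    stop("both outcome classes must be present", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  data <- data.frame(score = scores, label = labels)
  fit_fn <- function(d)
    suppressWarnings(glm(label ~ score, family = binomial(), data = d))
  metric_fn <- function(model, d)
    roc_auc(predict(model, newdata = d, type = "link"), d$label)$auc
  valid_fn <- function(d) sum(d$label) > 0 && sum(!d$label) > 0
  out <- harrell_optimism(data, fit_fn, metric_fn, valid_fn, n_boot,
                          resample_fn = resample_fn)
  out$seed <- seed
  out
}

#' Harrell's concordance index of a risk score
#'
#' Probability that, among usable patient pairs (pairs whose ordering of
#' failure times is observable under censoring), the patient with the higher
#' risk score fails earlier; tied scores count one half.
#'
#' @param risk Numeric risk scores (higher = higher risk, e.g. a Cox linear
#'   predictor).
#' @param data Data frame with `time` and `event`.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_cindex <- function(risk, data) {
  check_survival_input(data)
  cc <- survival::concordance(
    survival::Surv(time, event) ~ risk,
    data = data.frame(time = data$time, event = data$event, risk = risk),
    reverse = TRUE)
  unname(cc$concordance)
}

cindex_of_lp <- harrell_cindex

#' Bootstrap optimism-corrected Harrell C-index of a Cox model
#'
#' Same optimism schema as [bootstrap_optimism_auc()], with [cox_fit()] as the
#' model and Harrell's concordance of the linear predictor (usable pairs, ties
#' one half) as the metric. Resamples without any event are redrawn, at most
#' 50 times.
#'
#' @param data Data frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate names.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Optional integer seed.
#' @param resample_fn Optional resampling hook (see
#'   [bootstrap_optimism_auc()]).
#' @return A `validation_result` with `seed`.
#' @export
bootstrap_optimism_cindex <- function(data, covariates, n_boot = 1000,
                                      seed = NULL, resample_fn = NULL) {
  check_survival_input(data)
  stopifnot(n_boot >= 1)
  if (sum(data$event) == 0) stop("no events in the data", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit_fn <- function(d) cox_fit(d, covariates)
  metric_fn <- function(model, d)
    cindex_of_lp(predict(model$fit, newdata = d, type = "lp"), d)
  valid_fn <- function(d) sum(d$event) > 0
  out <- harrell_optimism(data, fit_fn, metric_fn, valid_fn, n_boot,
                          resample_fn = resample_fn, max_redraw = 50)
  out$seed <- seed
  out
}
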