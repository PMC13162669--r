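#' Dichotomize patient scores at the cohort median
#'
#' `high` means score greater than or equal to the median (midpoint convention
#' for even counts), so a cohort of 23 distinct scores splits 11 low / 12 high
#' (the median observation joins the high group). Missing scores stay `NA`.
#'
#' @param values Numeric per-patient scores (at least 2 defined).
#' @return Factor with levels `c("low", "high")`; attribute `cutoff` holds the
#'   median used.
#' @export
dichotomize_at_median <- function(values) {
  defined <- values[!is.na(values)]
  if (length(defined) < 2)
    stop("need at least 2 defined values to dichotomize", call. = FALSE)
  med <- median(defined)
  if (all(defined == defined[1]))
    warning("all values are equal; every patient is labeled 'high'",
            call. = FALSE)
  out <- factor(ifelse(values >= med, "high", "low"),
                levels = c("low", "high"))
  attr(out, "cutoff") <- med
  out
}

check_survival_input <- function(data) {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  if (nrow(data) == 0) stop("empty survival input", call. = FALSE)
  if (any(data$time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(data$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (observed)", call. = FALSE)
  invisible(data)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function (censoring at an event
#' time leaves the subject at risk for that event, the standard convention).
#'
#' @param data Data frame with `time` (days, positive) and `event` (0/1).
#' @return Tibble with one row per distinct event/censoring time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(data) {
  check_survival_input(data)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance; two-sided p from
#' the chi-square distribution with 1 df. A cohort without any event yields a
#' zero statistic with a `no_events` flag rather than an error.
#'
#' @param groups Factor/vector with exactly two levels, one label per subject.
#' @param data Data frame with `time` and `event`, same order as `groups`.
#' @return List: `statistic` (chi-square), `p_value`, `no_events` flag.
#' @export
logrank_test <- function(groups, data) {
  check_survival_input(data)
  groups <- factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) == 0))
    stop("log-rank test needs exactly 2 groups with >= 1 subject each",
         call. = FALSE)
  if (sum(data$event) == 0)
    return(list(statistic = 0, p_value = 1, no_events = TRUE))
  sd <- survival::survdiff(survival::Surv(data$time, data$event) ~ groups)
  list(statistic = unname(sd$chisq),
       p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       no_events = FALSE)
}

#' Cox proportional hazards fit
#'
#' Maximum partial-likelihood estimation (Efron tie handling by default) with
#' Wald 95% confidence intervals and p-values, plus Harrell's C-index of the
#' fitted linear predictor. Monotone likelihood (a covariate that perfectly
#' orders the events, driving its coefficient to infinity) is reported as a
#' non-convergence error naming the covariate.
#'
#' @param data Data frame with `time`, `event` and the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A list of class `cox_fit_result`: `terms` (tibble with
#'   `term`, `coefficient`, `hazard_ratio`, `ci_low`, `ci_high`, `p_value`),
#'   `c_index`, `n`, `n_events`, `ties`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_survival_input(data)
  if (sum(data$event) == 0) stop("no events in the data", call. = FALSE)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("covariate(s) not in data: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  infinite_warning <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        infinite_warning <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (infinite_warning || any(!is.finite(co[, "coef"])) ||
      any(abs(co[, "coef"]) > 20)) {
    worst <- rownames(co)[which.max(abs(co[, "coef"]))]
    stop("Cox fit did not converge (monotone likelihood); covariate: ",
         worst, call. = FALSE)
  }
  z <- qnorm(0.975)
  terms <- tibble::tibble(
    term = rownames(co),
    coefficient = unname(co[, "coef"]),
    hazard_ratio = unname(exp(co[, "coef"])),
    ci_low = unname(exp(co[, "coef"] - z * co[, "se(coef)"])),
    ci_high = unname(exp(co[, "coef"] + z * co[, "se(coef)"])),
    p_value = unname(co[, "Pr(>|z|)"]))
  structure(list(terms = terms,
                 c_index = unname(fit$concordance["concordance"]),
                 n = nrow(data), n_events = sum(data$event), ties = ties,
                 fit = fit),
            class = "cox_fit_result")
}

#' @export
print.cox_fit_result <- function(x, ...) {
  cat(sprintf("<cox_fit_result> n=%d, events=%d, ties=%s, C-index=%.3f\n",
              x$n, x$n_events, x$ties, x$c_index))
  print(x$terms)
  invisible(x)
}

#' Univariate-to-multivariate Cox screening
#'
#' Fits a univariate Cox model per candidate covariate; candidates with a
#' univariate Wald p below `alpha` enter one multivariate model together.
#' A candidate whose univariate fit fails (e.g. monotone likelihood) is
#' recorded with the error message and excluded, not fatal. An empty selection
#' yields a report without a multivariate model, flagged.
#'
#' @param data Data frame with `time`, `event` and candidate columns.
#' @param candidates Character vector (>= 2) of candidate covariate names.
#' @param alpha Univariate selection threshold (default 0.05).
#' @param ties Tie handling passed to [cox_fit()].
#' @return A list of class `cox_screening`: `univariate` (tibble `term`,
#'   `coefficient`, `hazard_ratio`, `ci_low`, `ci_high`, `p_value`, `error`),
#'   `selected` (character), `multivariate` ([cox_fit()] result or `NULL`),
#'   `alpha`.
#' @export
screen_univariate_multivariate <- function(data, candidates, alpha = 0.05,
                                           ties = "efron") {
  if (length(candidates) < 2)
    stop("need at least 2 candidate covariates", call. = FALSE)
  uni <- lapply(candidates, function(cv) {
    res <- tryCatch(cox_fit(data, cv, ties = ties), error = identity)
    if (inherits(res, "error")) {
      tibble::tibble(term = cv, coefficient = NA_real_,
                     hazard_ratio = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, p_value = NA_real_,
                     error = conditionMessage(res))
    } else {
      cbind(res$terms[1, ], tibble::tibble(error = NA_character_))
    }
  })
  uni <- tibble::as_tibble(do.call(rbind, uni))
  selected <- uni$term[!is.na(uni$p_value) & uni$p_value < alpha]
  multivariate <- if (length(selected))
    cox_fit(data, selected, ties = ties) else NULL
  structure(list(univariate = uni, selected = selected,
                 multivariate = multivariate, alpha = alpha),
            class = "cox_screening")
}
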