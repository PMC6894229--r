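#' ROC-threshold-driven survival analysis
#'
#' ROC analysis against relapse yes/no identifies optimal dichotomization
#' thresholds (Youden criterion, optionally confirmed by a maximal-Wald
#' Cox scan); dichotomized markers then enter Kaplan-Meier, log-rank and
#' Cox proportional-hazards analyses, including forward-Wald multivariable
#' selection with a backward fallback for unstable models.  Dichotomization
#' is always "value >= cutoff is the high stratum".
#'
#' @name survival-outcomes
NULL

#' ROC curve points
#'
#' Candidate thresholds are the midpoints between consecutive sorted
#' unique scores, plus -Inf/+Inf sentinels; a positive call is
#' `score >= threshold`.  Points are returned in increasing
#' false-positive-rate order.
#'
#' @param score Numeric marker values.
#' @param label Binary outcome (0/1, logical, or two-level factor; the
#'   larger/second level is the positive class).
#' @return Data frame `threshold`, `fpr`, `tpr` of class `roc_points`.
#' @export
roc_points <- function(score, label) {
  y <- if (is.logical(label)) as.integer(label)
       else if (is.factor(label) || is.character(label)) {
         lv <- sort(unique(as.character(label)))
         if (length(lv) != 2) stop("label must be binary")
         as.integer(as.character(label) == lv[2])
       } else as.integer(label)
  if (length(unique(y)) != 2) stop("both label values must be present")
  if (length(score) != length(y)) stop("score and label sizes differ")
  u <- sort(unique(score))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(score >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & y == 0) / n0, numeric(1))
  out <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  out <- out[order(out$fpr, out$tpr), ]
  rownames(out) <- NULL
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Trapezoid area under the [roc_points()] curve; identical to the
#' Mann-Whitney U statistic divided by `n1 * n0` with ties counted 1/2.
#'
#' @param roc A `roc_points` data frame.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

#' Youden-optimal threshold
#'
#' The threshold maximizing Youden's `J = tpr - fpr`; ties are broken
#' toward higher specificity (lower fpr), then toward the lower threshold.
#'
#' @param roc A `roc_points` data frame.
#' @return List with `threshold`, `j`, `tpr`, `fpr`.
#' @export
youden_threshold <- function(roc) {
  j <- roc$tpr - roc$fpr
  o <- order(-j, roc$fpr, roc$threshold)
  best <- o[1]
  list(threshold = roc$threshold[best], j = j[best],
       tpr = roc$tpr[best], fpr = roc$fpr[best])
}

# records: data.frame with columns time, event
.check_records <- function(records) {
  if (any(records$time < 0)) stop("negative survival times")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_(t_i <= t) (1 - d_i / n_i)` over the distinct event times,
#' right-continuous with `S(0) = 1`.
#'
#' @param records Data frame with `time` and `event` columns.
#' @return Data frame `time`, `n_at_risk`, `n_events`, `survival`, one row
#'   per distinct event or censoring time.
#' @export
km_estimate <- function(records) {
  .check_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_at_risk = fit$n.risk,
             n_events = fit$n.event, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' @param records Data frame with `time` and `event`.
#' @param group Two-level grouping vector.
#' @return List with `chisq` (1 df) and `p_value`.
#' @export
logrank_test <- function(records, group) {
  .check_records(records)
  if (length(unique(group)) < 2) stop("need at least 2 groups")
  if (sum(records$event) == 0) stop("no events; log-rank undefined")
  d <- data.frame(time = records$time, event = records$event,
                  group = as.character(group))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd_fit$n) - 1
  list(chisq = unname(sd_fit$chisq),
       p_value = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Breslow-ties Cox regression (Efron available via `ties`) with Wald
#' statistics, hazard ratios and 95% confidence intervals.  Monotone
#' likelihood -- a covariate pattern with zero events on one side driving
#' the coefficient to infinity -- is detected at `|coef| > 15` (or a
#' non-converged fit) and reported as an infinite hazard ratio together
#' with a likelihood-ratio p-value, since the Wald p is then undefined.
#'
#' @param records Data frame with `time` and `event`.
#' @param covariates Data frame or matrix of covariates aligned with
#'   `records` (binary markers coded 0/1 or continuous values).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Object of class `cox_fit`: data frame `term`, `coef`, `se`,
#'   `wald`, `p_value`, `hr`, `ci_lo`, `ci_hi`, `monotone`, `singular`
#'   (collinear terms dropped by the fitter), with the underlying
#'   `survival::coxph` fit and the likelihood-ratio p-value as attributes.
#'   Constant covariates are reported with coefficient 0 and hazard
#'   ratio 1.
#' @export
cox_fit <- function(records, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  .check_records(records)
  if (sum(records$event) == 0) stop("no events; Cox model undefined")
  x <- as.data.frame(covariates)
  if (any(!vapply(x, is.numeric, logical(1)))) {
    stop("covariates must be numeric (code factors beforehand)")
  }
  if (any(!is.finite(as.matrix(x)))) stop("non-finite covariates")
  constant <- vapply(x, function(v) stats::var(v) == 0, logical(1))
  if (all(constant)) {
    # no information: every constant covariate has coefficient 0, HR 1
    out <- data.frame(
      term = names(x), coef = 0, se = NA_real_, wald = 0, p_value = 1,
      hr = 1, ci_lo = NA_real_, ci_hi = NA_real_, monotone = FALSE,
      singular = FALSE, stringsAsFactors = FALSE
    )
    return(structure(out, class = c("cox_fit", "data.frame"),
                     coxph = NULL, lrt_p = 1, converged = TRUE))
  }
  const_terms <- names(x)[constant]
  x <- x[, !constant, drop = FALSE]
  d <- cbind(data.frame(.time = records$time, .event = records$event), x)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(x)), collapse = " + ")
  ))
  fit <- suppressWarnings(
    survival::coxph(fml, data = d, ties = ties,
                    control = survival::coxph.control(iter.max = 100))
  )
  s <- summary(fit)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  singular <- is.na(cf)
  cf[singular] <- NA_real_
  se[singular] <- NA_real_
  monotone <- !singular & (abs(cf) > 15 | !is.finite(se))
  lrt_p <- unname(s$logtest["pvalue"])
  out <- data.frame(
    term = names(cf),
    coef = unname(cf),
    se = unname(se),
    wald = unname((cf / se)^2),
    p_value = unname(2 * stats::pnorm(-abs(cf / se))),
    hr = unname(exp(cf)),
    ci_lo = unname(exp(cf - 1.96 * se)),
    ci_hi = unname(exp(cf + 1.96 * se)),
    monotone = unname(monotone),
    singular = unname(singular),
    stringsAsFactors = FALSE
  )
  if (length(const_terms) > 0) {
    out <- rbind(out, data.frame(
      term = const_terms, coef = 0, se = NA_real_, wald = 0, p_value = 1,
      hr = 1, ci_lo = NA_real_, ci_hi = NA_real_, monotone = FALSE,
      singular = FALSE, stringsAsFactors = FALSE
    ))
  }
  mono <- out$monotone
  if (any(mono)) {
    out$hr[mono & out$coef > 0] <- Inf
    out$hr[mono & out$coef < 0] <- 0
    out$p_value[mono] <- lrt_p
    out$wald[mono] <- NA_real_
  }
  structure(out, class = c("cox_fit", "data.frame"),
            coxph = fit, lrt_p = lrt_p, converged = fit$iter < 100)
}

#' Confirm a dichotomization cutoff by a maximal-Wald Cox scan
#'
#' Fits a univariate Cox model for each candidate cutoff applied as
#' `value >= cutoff` and returns the candidate with the largest Wald
#' statistic (the minimal-p confirmation of a ROC-derived threshold).
#' Candidates that leave zero events on either side are skipped.
#'
#' @param values Continuous marker values.
#' @param records Data frame with `time` and `event` aligned with `values`.
#' @param candidates Numeric vector of candidate cutoffs.
#' @param roc_threshold Optional ROC-derived threshold to report agreement
#'   with.
#' @return List with `cutoff`, `wald`, `p_value`, `scan` (per-candidate
#'   table) and, when `roc_threshold` is given, `agrees_with_roc`.
#' @export
cox_threshold_confirm <- function(values, records, candidates,
                                  roc_threshold = NULL) {
  .check_records(records)
  rows <- lapply(candidates, function(ct) {
    hi <- as.numeric(values >= ct)
    ev_hi <- sum(records$event[hi == 1])
    ev_lo <- sum(records$event[hi == 0])
    if (length(unique(hi)) < 2 || (ev_hi + ev_lo) == 0) {
      return(data.frame(cutoff = ct, wald = NA_real_, p_value = NA_real_))
    }
    f <- cox_fit(records, data.frame(high = hi))
    data.frame(cutoff = ct,
               wald = if (f$monotone[1]) Inf else f$wald[1],
               p_value = f$p_value[1])
  })
  scan <- do.call(rbind, rows)
  if (all(is.na(scan$wald))) {
    stop("no candidate cutoff yields events on both sides")
  }
  best <- which.max(ifelse(is.na(scan$wald), -Inf, scan$wald))
  out <- list(cutoff = scan$cutoff[best], wald = scan$wald[best],
              p_value = scan$p_value[best], scan = scan)
  if (!is.null(roc_threshold)) {
    out$agrees_with_roc <- isTRUE(all.equal(out$cutoff, roc_threshold))
  }
  out
}

#' Forward-Wald Cox covariate selection
#'
#' Starting from the null model, repeatedly adds the candidate covariate
#' with the largest Wald statistic among those entering at `p <
#' entry_level`, refitting the joint model each round, until no candidate
#' qualifies.  If a step produces an unstable model (monotone likelihood
#' or a singular information matrix) the procedure falls back to backward
#' elimination: start from the full model and drop the largest-p covariate
#' until all remaining satisfy `p < stay_level`.  The full decision trace
#' is returned.
#'
#' @param records Data frame with `time` and `event`.
#' @param covariates Data frame of candidate covariates (numeric).
#' @param entry_level Forward entry significance level (default 0.05).
#' @param stay_level Backward stay level (default 0.10).
#' @return List with `fit` (a [cox_fit()] or `NULL` for the null model),
#'   `selected` (character vector), `method` (`"forward"` or
#'   `"backward"`), and `trace` (data frame of steps).
#' @export
forward_wald_selection <- function(records, covariates,
                                   entry_level = 0.05, stay_level = 0.10) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2) stop("need at least 2 candidate covariates")
  trace <- list()
  note <- function(step, action, term, p) {
    trace[[length(trace) + 1]] <<- data.frame(
      step = step, action = action, term = term, p_value = p,
      stringsAsFactors = FALSE
    )
  }
  selected <- character(0)
  unstable <- FALSE
  saw_singular <- FALSE
  step <- 0
  repeat {
    step <- step + 1
    remaining <- setdiff(names(covariates), selected)
    if (length(remaining) == 0) break
    cand <- lapply(remaining, function(v) {
      f <- tryCatch(
        cox_fit(records, covariates[, c(selected, v), drop = FALSE]),
        error = function(e) NULL
      )
      if (is.null(f)) return(list(term = v, wald = NA, p = NA,
                                  mono = TRUE, sing = TRUE))
      row <- which(f$term == v | f$term == sprintf("`%s`", v))
      list(term = v, wald = f$wald[row], p = f$p_value[row],
           mono = any(f$monotone), sing = any(f$singular))
    })
    if (any(vapply(cand, function(z) isTRUE(z$sing), logical(1)))) {
      saw_singular <- TRUE
    }
    monos <- vapply(cand, function(z) isTRUE(z$mono), logical(1))
    walds <- vapply(cand, function(z) {
      if (is.null(z$wald) || is.na(z$wald)) -Inf else z$wald
    }, numeric(1))
    ps <- vapply(cand, function(z) {
      if (is.null(z$p) || is.na(z$p)) 1 else z$p
    }, numeric(1))
    qualifying <- which(ps < entry_level & is.finite(walds))
    if (length(qualifying) == 0) {
      # monotone-likelihood "significance" or a singular information
      # matrix along the way marks the model unstable and triggers the
      # backward fallback
      if (any(monos & ps < entry_level) || saw_singular) unstable <- TRUE
      break
    }
    pick <- qualifying[which.max(walds[qualifying])]
    if (monos[pick]) { unstable <- TRUE; break }
    selected <- c(selected, cand[[pick]]$term)
    note(step, "add", cand[[pick]]$term, ps[pick])
  }
  method <- "forward"
  if (unstable) {
    method <- "backward"
    selected <- names(covariates)
    repeat {
      if (length(selected) == 0) break
      f <- tryCatch(
        cox_fit(records, covariates[, selected, drop = FALSE]),
        error = function(e) NULL
      )
      if (is.null(f)) { selected <- selected[-length(selected)]; next }
      ps <- f$p_value
      # drop degenerate terms first, then the largest p
      drop_idx <- if (any(f$monotone | f$singular)) which(f$monotone | f$singular)[1]
                  else if (max(ps) >= stay_level) which.max(ps)
                  else NA_integer_
      if (is.na(drop_idx)) break
      dropped <- gsub("`", "", f$term[drop_idx])
      note(length(trace) + 1, "drop", dropped, ps[drop_idx])
      selected <- setdiff(selected, dropped)
    }
  }
  fit <- if (length(selected) > 0) {
    cox_fit(records, covariates[, selected, drop = FALSE])
  } else NULL
  list(
    fit = fit, selected = selected, method = method,
    trace = if (length(trace) > 0) do.call(rbind, trace)
            else data.frame(step = integer(0), action = character(0),
                            term = character(0), p_value = numeric(0))
  )
}
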