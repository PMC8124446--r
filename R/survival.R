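#' Cox proportional-hazards fit
#'
#' Fits a (possibly multivariate) Cox model by partial-likelihood
#' maximization with Efron tie handling (Breslow available), returning the
#' hazard ratio, Wald 95% confidence interval and p-value per covariate.
#' Zero-variance covariates cannot move the partial likelihood and are
#' reported as HR 1, p 1 with a warning; monotone likelihoods (perfect
#' separation) raise an error naming the covariate.
#'
#' @param data data.frame with columns `time` (> 0), `event` (0/1) and the
#'   covariates.
#' @param covariates character vector of covariate column names; factors are
#'   expanded to treatment contrasts.
#' @param ties `"efron"` or `"breslow"`.
#' @return data.frame of class `cox_result`: one row per model term with
#'   `term`, `beta`, `se`, `hr`, `ci_low`, `ci_high`, `p`, plus `loglik`,
#'   `n`, `n_events` attributes repeated as columns.
#' @export
fit_cox <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  data <- data[stats::complete.cases(data[, c("time", "event", covariates)]), ,
               drop = FALSE]
  if (sum(data$event) < 2) stop("need at least 2 events to fit a Cox model")
  is_const <- vapply(covariates, function(v) {
    x <- data[[v]]
    length(unique(x)) < 2
  }, logical(1))
  const_terms <- covariates[is_const]
  if (any(is_const)) {
    warning("constant covariate(s) ", paste(const_terms, collapse = ", "),
            ": reported as HR 1", call. = FALSE)
  }
  fit_terms <- covariates[!is_const]
  rows <- list()
  ll <- NA_real_
  if (length(fit_terms)) {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(fit_terms, collapse = " + ")))
    fit <- survival::coxph(f, data = data, ties = ties, x = TRUE,
                           control = survival::coxph.control(iter.max = 100))
    beta <- stats::coef(fit)
    if (anyNA(beta)) stop("non-identifiable covariate(s): ",
                          paste(names(beta)[is.na(beta)], collapse = ", "))
    # separation guard on the standardized scale (a covariate measured in
    # tiny units legitimately has a large raw coefficient)
    scale_x <- apply(fit$x, 2, stats::sd)
    sep <- abs(beta) * scale_x > 15
    if (any(sep)) {
      stop("monotone partial likelihood (perfect separation) for covariate ",
           paste(names(beta)[sep], collapse = ", "))
    }
    se <- sqrt(diag(fit$var))
    ll <- fit$loglik[2]
    rows[[1]] <- data.frame(term = names(beta), beta = unname(beta),
                            se = unname(se))
  }
  if (length(const_terms)) {
    rows[[length(rows) + 1]] <- data.frame(term = const_terms, beta = 0,
                                           se = NA_real_)
  }
  out <- do.call(rbind, rows)
  out$hr <- exp(out$beta)
  out$ci_low <- exp(out$beta - 1.96 * out$se)
  out$ci_high <- exp(out$beta + 1.96 * out$se)
  out$p <- ifelse(is.na(out$se), 1,
                  2 * stats::pnorm(-abs(out$beta / out$se)))
  out$loglik <- ll
  out$n <- nrow(data)
  out$n_events <- sum(data$event)
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Cox fit with a time-dependent transplant covariate
#'
#' Expands each record to counting-process `(start, stop]` rows in which the
#' transplant indicator switches from 0 to 1 at the patient's transplant
#' time (`NA` transplant time means never transplanted), then fits the Cox
#' model over the expanded risk sets. With no transplanted patient this
#' reduces exactly to [fit_cox()] without the variable.
#'
#' @param data data.frame with `time`, `event`, a `transplant_time` column
#'   (months, or `NA`), and the fixed covariates.
#' @param covariates fixed covariate names.
#' @param timedep_name name for the transplant indicator term.
#' @inheritParams fit_cox
#' @return a `cox_result` data.frame (see [fit_cox()]).
#' @export
fit_cox_timedep <- function(data, covariates,
                            timedep_name = "transplant",
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event", "transplant_time") %in% names(data)))
  tt <- data$transplant_time
  if (any(!is.na(tt) & tt >= data$time)) {
    stop("transplant_time must be strictly before the event/censoring time")
  }
  if (any(!is.na(tt) & tt < 0)) stop("transplant_time must be non-negative")
  if (!any(!is.na(tt))) {
    # degenerate time-dependence: nobody transplanted, the indicator is
    # identically zero and the model reduces to the fit without it
    return(fit_cox(data, covariates, ties = ties))
  }
  has_tt <- !is.na(tt) & tt > 0
  pre <- data[has_tt, , drop = FALSE]
  rows <- rbind(
    data.frame(tstart = 0, tstop = ifelse(is.na(tt), data$time,
                                          ifelse(tt > 0, tt, data$time)),
               ev = ifelse(has_tt, 0, data$event),
               td = ifelse(!is.na(tt) & tt == 0, 1, 0),
               data[, covariates, drop = FALSE]),
    if (any(has_tt)) data.frame(tstart = tt[has_tt], tstop = pre$time,
                                ev = pre$event, td = 1,
                                pre[, covariates, drop = FALSE])
  )
  names(rows)[names(rows) == "td"] <- timedep_name
  f <- stats::as.formula(paste(
    "survival::Surv(tstart, tstop, ev) ~",
    paste(c(covariates, timedep_name), collapse = " + ")))
  fit <- survival::coxph(f, data = rows, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("non-identifiable term(s) in time-dependent Cox model: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  se <- sqrt(diag(fit$var))
  out <- data.frame(term = names(beta), beta = unname(beta),
                    se = unname(se))
  out$hr <- exp(out$beta)
  out$ci_low <- exp(out$beta - 1.96 * out$se)
  out$ci_high <- exp(out$beta + 1.96 * out$se)
  out$p <- 2 * stats::pnorm(-abs(out$beta / out$se))
  out$loglik <- fit$loglik[2]
  out$n <- nrow(data)
  out$n_events <- sum(data$event)
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' @param data data.frame with `time`, `event` and optionally a grouping
#'   column.
#' @param group optional name of the grouping column.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `surv`;
#'   each group starts at S(0) = 1 and the curve only drops at event times.
#' @export
kaplan_meier <- function(data, group = NULL) {
  if (is.null(group)) {
    data$.g <- "all"; group <- ".g"
  }
  out <- do.call(rbind, lapply(split(data, data[[group]]), function(d) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    data.frame(group = d[[group]][1],
               time = c(0, fit$time),
               n_risk = c(nrow(d), fit$n.risk),
               n_event = c(0, fit$n.event),
               surv = c(1, fit$surv))
  }))
  rownames(out) <- NULL
  out
}

#' Log-rank test between two (or more) groups
#'
#' @param data data.frame with `time`, `event` and the grouping column.
#' @param group name of the grouping column.
#' @return list with `chisq`, `df` and `p`.
#' @export
logrank_test <- function(data, group) {
  g <- factor(data[[group]])
  if (nlevels(droplevels(g)) < 2) stop("log-rank test needs two non-empty groups")
  if (sum(data$event) < 1) stop("log-rank test needs at least one event")
  data$.g <- droplevels(g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ .g, data = data)
  df <- length(sd$n) - 1
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median split into low/high groups
#'
#' Values strictly above the median are labelled `"high"`; values at or
#' below the median (including ties at the median) are `"low"`. With an even
#' number of distinct values this gives equal halves (e.g. n = 22 splits
#' 11/11). All-equal input cannot be split and raises an error.
#'
#' @param values numeric vector (length >= 2).
#' @return factor with levels `low`, `high`, same order as `values`.
#' @export
median_split <- function(values) {
  stopifnot(length(values) >= 2, !anyNA(values))
  if (length(unique(values)) < 2) stop("all values equal: no median split")
  m <- stats::median(values)
  factor(ifelse(values > m, "high", "low"), levels = c("low", "high"))
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down Holm correction: p-values sorted ascending, the i-th multiplied
#' by (m - i + 1), enforced monotone non-decreasing and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Spearman rank correlation test
#'
#' @param x,y numeric vectors (>= 3 complete pairs, non-constant).
#' @return list with `rho` and `p`.
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("Spearman correlation needs at least 3 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("Spearman correlation undefined for constant input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-sample Student's t-test
#'
#' Classic pooled-variance two-tailed Student's t-test by default; Welch's
#' unequal-variance variant via `var_equal = FALSE`.
#'
#' @param x numeric values.
#' @param g two-level grouping vector.
#' @param var_equal pool variances (classic Student) or not (Welch).
#' @return list with `t`, `df`, `p` and the two group means.
#' @export
students_t_test <- function(x, g, var_equal = TRUE) {
  g <- factor(g)
  if (nlevels(droplevels(g)) != 2) stop("t-test needs exactly two groups")
  tt <- stats::t.test(x ~ g, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       means = tt$estimate)
}
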