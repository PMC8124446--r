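#' Specification of a simulated survival/expression cohort
#'
#' Event times follow a proportional-hazards model with exponential (or
#' Weibull) baseline: the per-patient log hazard is linear in the
#' standardized log exclusion score and/or in standardized planted-gene
#' expression, with optional ISS-stage effects and a time-dependent
#' transplant effect. Censoring is independent exponential. Expression is
#' drawn per gene around a gene-specific mean on the log2 scale, with
#' optional per-cohort batch shifts; a configurable fraction of genes is
#' "not expressed" (mean below the log2 = 8 screening threshold).
#'
#' @param n_patients cohort size (>= 2).
#' @param score_log_hazard planted log hazard ratio per unit standardized
#'   log exclusion score.
#' @param baseline_hazard baseline event rate per month (> 0).
#' @param censoring_rate independent exponential censoring rate per month
#'   (0 disables censoring).
#' @param weibull_shape Weibull shape (1 = exponential baseline).
#' @param n_genes number of expression features (0 for none).
#' @param planted_genes gene ids with a direct survival effect.
#' @param gene_log_hazard log hazard ratio per SD of each planted gene.
#' @param confounded_genes gene ids correlated with ISS stage but without a
#'   direct effect (for mediation checks).
#' @param confounding_loading correlation loading of confounded genes on the
#'   standardized ISS stage.
#' @param iss_log_hazard length-2 vector: log hazard ratios of ISS II and
#'   III versus I.
#' @param low_expr_frac fraction of genes drawn with mean below log2 = 8
#'   (removed by the expression filter).
#' @param transplant_rate per-month rate at which patients receive an
#'   autologous transplant (0 = none).
#' @param transplant_log_hazard hazard change at transplant.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        score_log_hazard = 0,
                        baseline_hazard = 0.02,
                        censoring_rate = 0.01,
                        weibull_shape = 1,
                        n_genes = 0,
                        planted_genes = character(0),
                        gene_log_hazard = 0,
                        confounded_genes = character(0),
                        confounding_loading = 0.8,
                        iss_log_hazard = c(0, 0),
                        low_expr_frac = 0,
                        transplant_rate = 0,
                        transplant_log_hazard = 0) {
  stopifnot(n_patients >= 2, baseline_hazard > 0, censoring_rate >= 0,
            weibull_shape > 0, n_genes >= 0, length(iss_log_hazard) == 2,
            transplant_rate >= 0, low_expr_frac >= 0, low_expr_frac < 1)
  gene_ids <- if (n_genes > 0) sprintf("g%04d", seq_len(n_genes))
  else character(0)
  if (!all(planted_genes %in% gene_ids)) {
    stop("planted_genes must be a subset of the generated gene ids (g0001...)")
  }
  if (!all(confounded_genes %in% gene_ids)) {
    stop("confounded_genes must be a subset of the generated gene ids")
  }
  structure(c(as.list(environment())), class = "cohort_spec")
}

#' Generate one survival cohort (optionally with expression)
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (local RNG).
#' @param cohort_id identifier recorded in the output.
#' @return list with `survival` (data.frame: `patient_id`, `time`, `event`,
#'   `iss`, `transplant_time`, `score`, `log_score`) and `expression`
#'   (genes x patients matrix, or `NULL`). Times are months.
#' @export
generate_survival_cohort <- function(spec, seed, cohort_id = "cohort1") {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(seed, {
    n <- spec$n_patients
    log_score <- rnorm(n)
    iss <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    z_iss <- (iss - mean(iss)) / max(sd(iss), 1e-8)

    expr <- NULL
    z_genes <- NULL
    if (spec$n_genes > 0) {
      z_genes <- matrix(rnorm(spec$n_genes * n), spec$n_genes, n,
                        dimnames = list(spec$gene_ids, NULL))
      for (g in spec$confounded_genes) {
        lo <- spec$confounding_loading
        z_genes[g, ] <- lo * z_iss + sqrt(1 - lo^2) * rnorm(n)
      }
      n_low <- round(spec$low_expr_frac * spec$n_genes)
      mu <- runif(spec$n_genes, 8.5, 11)
      if (n_low > 0) {
        low_idx <- setdiff(seq_len(spec$n_genes),
                           match(c(spec$planted_genes, spec$confounded_genes),
                                 spec$gene_ids))
        low_idx <- head(low_idx, n_low)
        mu[low_idx] <- runif(length(low_idx), 6, 7.5)
      }
      mu[match(c(spec$planted_genes, spec$confounded_genes),
               spec$gene_ids)] <- 10
      expr <- mu + z_genes
    }

    lp <- spec$score_log_hazard * log_score +
      spec$iss_log_hazard[1] * (iss == 2) + spec$iss_log_hazard[2] * (iss == 3)
    for (g in spec$planted_genes) {
      lp <- lp + spec$gene_log_hazard * z_genes[g, ]
    }
    h <- spec$baseline_hazard * exp(lp)
    stopifnot(all(h > 0))

    # event time under a hazard that may change at the transplant time
    e <- rexp(n)
    tt_cand <- if (spec$transplant_rate > 0) {
      rexp(n, spec$transplant_rate)
    } else rep(Inf, n)
    gam <- exp(spec$transplant_log_hazard)
    cum_at_tt <- h * tt_cand # cumulative hazard reached at candidate transplant
    t_event <- ifelse(e < cum_at_tt, e / h,
                      tt_cand + (e - cum_at_tt) / (h * gam))
    if (spec$weibull_shape != 1) {
      t_event <- t_event^(1 / spec$weibull_shape)
      tt_cand <- tt_cand^(1 / spec$weibull_shape)
    }
    cens <- if (spec$censoring_rate > 0) rexp(n, spec$censoring_rate)
    else rep(Inf, n)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
    transplant_time <- ifelse(is.finite(tt_cand) & tt_cand < time, tt_cand,
                              NA_real_)

    surv <- data.frame(
      patient_id = sprintf("%s_p%04d", cohort_id, seq_len(n)),
      time = time, event = event, iss = iss,
      transplant_time = transplant_time,
      score = exp(log_score), log_score = log_score
    )
    if (!is.null(expr)) colnames(expr) <- surv$patient_id
    list(survival = surv, expression = expr)
  })
}

#' Expression cohort container
#'
#' @param expression genes x patients matrix (log2 scale).
#' @param survival survival data.frame with one row per patient, aligned to
#'   the expression columns.
#' @param cohort_id identifier.
#' @param role `"discovery"`, `"validation"` or `"second_validation"`.
#' @return list of class `expression_cohort`.
#' @export
expression_cohort <- function(expression, survival, cohort_id,
                              role = c("discovery", "validation",
                                       "second_validation")) {
  role <- match.arg(role)
  stopifnot(is.matrix(expression), all(is.finite(expression)),
            ncol(expression) == nrow(survival))
  structure(list(expression = expression, survival = survival,
                 cohort_id = cohort_id, role = role),
            class = "expression_cohort")
}

#' Generate a multi-cohort screening dataset
#'
#' Draws each cohort from the same [cohort_spec()] (planted genes keep their
#' effect and a high mean everywhere) and then applies per-cohort batch
#' shifts: a global additive offset and multiplicative scale on every gene,
#' emulating separately processed trial cohorts.
#'
#' @param cohorts data.frame with columns `cohort_id`, `role`
#'   (`discovery` / `validation` / `second_validation`) and `n`.
#' @param spec a [cohort_spec()] describing the shared gene layout and
#'   effects (its `n_patients` is ignored; per-cohort `n` is used).
#' @param seed integer seed.
#' @param batch_shift_sd,batch_scale_sd spread of the per-cohort additive
#'   offset and of the log multiplicative scale.
#' @return list of [expression_cohort()] objects.
#' @export
generate_screen_cohorts <- function(cohorts, spec, seed,
                                    batch_shift_sd = 1,
                                    batch_scale_sd = 0.2) {
  stopifnot(all(c("cohort_id", "role", "n") %in% names(cohorts)),
            all(cohorts$role %in% c("discovery", "validation",
                                    "second_validation")))
  with_local_seed(seed, {
    shifts <- rnorm(nrow(cohorts), 0, batch_shift_sd)
    scales <- exp(rnorm(nrow(cohorts), 0, batch_scale_sd))
    sub_seeds <- sample.int(.Machine$integer.max %/% 2, nrow(cohorts))
  })
  out <- vector("list", nrow(cohorts))
  for (i in seq_len(nrow(cohorts))) {
    sp <- spec
    sp$n_patients <- cohorts$n[i]
    # second validation cohort carries transplant times
    if (cohorts$role[i] == "second_validation" && sp$transplant_rate == 0) {
      sp$transplant_rate <- 0.02
    }
    co <- generate_survival_cohort(sp, sub_seeds[i], cohorts$cohort_id[i])
    expr <- co$expression
    if (is.null(expr)) stop("spec must request n_genes > 0 for a screen")
    mu <- rowMeans(expr)
    expr <- (expr - mu) * scales[i] + mu + shifts[i]
    out[[i]] <- expression_cohort(expr, co$survival, cohorts$cohort_id[i],
                                  cohorts$role[i])
  }
  names(out) <- cohorts$cohort_id
  out
}
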