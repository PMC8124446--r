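#' Expression screening filter
#'
#' A gene is kept only when it is annotated and expressed in every cohort: a
#' gene with log2 expression below `min_log2` in at least `min_frac` of any
#' single cohort's patients is excluded.
#'
#' @param cohorts list of [expression_cohort()] objects.
#' @param annotation optional character vector of annotated gene ids; genes
#'   absent from it are excluded. `NULL` treats all genes as annotated.
#' @param min_log2 expression threshold (log2 scale).
#' @param min_frac patient fraction at or above which a gene counts as not
#'   expressed ("at least 50%" is a closed bound).
#' @return character vector of retained gene ids (order of the first
#'   cohort's rows).
#' @export
filter_genes <- function(cohorts, annotation = NULL, min_log2 = 8,
                         min_frac = 0.5) {
  stopifnot(length(cohorts) >= 1)
  genes <- Reduce(intersect, lapply(cohorts, function(co) {
    rownames(co$expression)
  }))
  if (!is.null(annotation)) genes <- intersect(genes, annotation)
  keep <- rep(TRUE, length(genes))
  for (co in cohorts) {
    frac_low <- rowMeans(co$expression[genes, , drop = FALSE] < min_log2)
    keep <- keep & (frac_low < min_frac)
  }
  if (!any(keep)) stop("no genes retained by the expression filter")
  genes[keep]
}

#' Batch equalization across cohorts
#'
#' Rescales every gene within every cohort so that all cohorts share the
#' same per-gene mean and variance (targets: the pooled mean over all
#' patients and the pooled within-cohort variance). Genes with zero variance
#' in some cohort are centered to the target mean there, with a message.
#'
#' @param cohorts list of [expression_cohort()] objects (shared gene ids).
#' @return the cohorts with equalized expression matrices.
#' @export
batch_equalize <- function(cohorts) {
  stopifnot(length(cohorts) >= 1)
  genes <- Reduce(intersect, lapply(cohorts, function(co) {
    rownames(co$expression)
  }))
  if (!length(genes)) stop("no shared genes across cohorts")
  mats <- lapply(cohorts, function(co) co$expression[genes, , drop = FALSE])
  ns <- vapply(mats, ncol, integer(1))
  means <- vapply(mats, rowMeans, numeric(length(genes)))
  vars <- vapply(mats, function(m) apply(m, 1, stats::var),
                 numeric(length(genes)))
  means <- matrix(means, nrow = length(genes))
  vars <- matrix(vars, nrow = length(genes))
  t_mean <- as.numeric(means %*% ns) / sum(ns)
  w <- pmax(ns - 1, 1)
  t_var <- as.numeric(vars %*% w) / sum(w)
  n_flat <- 0L
  for (i in seq_along(cohorts)) {
    s <- sqrt(vars[, i])
    flat <- s <= 0
    n_flat <- n_flat + sum(flat)
    s[flat] <- 1
    scaled <- (mats[[i]] - means[, i]) / s * sqrt(t_var) + t_mean
    scaled[flat, ] <- t_mean[flat]
    cohorts[[i]]$expression <- scaled
  }
  if (n_flat > 0) {
    message(n_flat, " zero-variance gene/cohort combination(s) centered only")
  }
  cohorts
}

pool_cohorts <- function(cohorts, role) {
  sel <- Filter(function(co) co$role == role, cohorts)
  if (!length(sel)) stop("no cohort with role '", role, "'")
  genes <- Reduce(intersect, lapply(sel, function(co) rownames(co$expression)))
  expr <- do.call(cbind, lapply(sel, function(co) {
    co$expression[genes, , drop = FALSE]
  }))
  surv <- do.call(rbind, lapply(sel, function(co) {
    cbind(co$survival, cohort_id = co$cohort_id)
  }))
  # canonical patient order: sorted ids, so results are invariant to input
  # permutations
  ord <- order(surv$patient_id)
  list(expression = expr[, ord, drop = FALSE],
       survival = surv[ord, , drop = FALSE])
}

standardize_train <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s <= 0] <- 1
  list(X = sweep(sweep(X, 2, m), 2, s, "/"), mean = m, sd = s)
}

#' Stage 1: list-level ridge-Cox test with double-loop cross-testing
#'
#' For each gene list, every discovery patient receives an out-of-sample
#' ridge-Cox risk score from a model that never saw them: a leave-one-out
#' outer loop, inside which the ridge penalty is chosen by event-stratified
#' 10-fold cross-validated partial likelihood. The vector of out-of-sample
#' risk scores is tested against overall survival by univariate Cox (Wald
#' test), giving the list's discovery p-value; a single model trained on all
#' discovery patients scores the validation patients for the validation
#' p-value. Both p-value families are Holm-adjusted over the lists, and a
#' list passes when significant in both sets.
#'
#' @param cohorts batch-equalized list of [expression_cohort()] objects with
#'   `discovery` and `validation` roles.
#' @param gene_lists named list of gene-id character vectors (the seven
#'   immune-evasion categories in the standard layout).
#' @param genes_retained genes surviving [filter_genes()].
#' @param alpha family-wise significance level.
#' @param nfolds inner cross-validation folds.
#' @param grid ridge penalty grid.
#' @param seed seed for fold assignment (folds are keyed to the sorted
#'   patient order, so results are invariant to input permutation).
#' @return data.frame: `list_name`, `n_genes`, `p_discovery`,
#'   `p_discovery_holm`, `p_validation`, `p_validation_holm`, `passed`.
#' @export
stage1_list_test <- function(cohorts, gene_lists, genes_retained,
                             alpha = 0.05, nfolds = 10, grid = lambda_grid(),
                             seed = 1) {
  disc <- pool_cohorts(cohorts, "discovery")
  val <- pool_cohorts(cohorts, "validation")
  out <- data.frame(list_name = names(gene_lists),
                    n_genes = NA_integer_, p_discovery = NA_real_,
                    p_validation = NA_real_)
  for (li in seq_along(gene_lists)) {
    genes <- intersect(gene_lists[[li]], genes_retained)
    out$n_genes[li] <- length(genes)
    if (!length(genes)) {
      message("list '", names(gene_lists)[li],
              "' has no retained genes: skipped")
      next
    }
    X <- t(disc$expression[genes, , drop = FALSE])
    time <- disc$survival$time
    status <- disc$survival$event
    n <- nrow(X)
    # folds fixed once over the whole leave-one-out loop, keyed to the
    # sorted patient order (pool_cohorts sorts by patient id)
    foldid <- make_cv_folds(status, nfolds, seed)$foldid
    ord <- order(time, disc$survival$patient_id)
    loo <- cpp_stage1_loo(X[ord, , drop = FALSE], time[ord], status[ord],
                          as.integer(foldid[ord]),
                          sort(grid, decreasing = TRUE))
    risk <- numeric(n)
    risk[ord] <- as.numeric(loo$risk)
    out$p_discovery[li] <- cox_p_of_score(time, status, risk)

    st <- standardize_train(X)
    sel <- select_lambda_cv(st$X, time, status, grid = grid,
                            nfolds = nfolds, seed = seed)
    fit <- ridge_cox(st$X, time, status, sel$lambda)
    Xv <- t(val$expression[genes, , drop = FALSE])
    risk_v <- as.numeric(sweep(sweep(Xv, 2, st$mean), 2, st$sd, "/") %*%
                           fit$beta)
    out$p_validation[li] <- cox_p_of_score(val$survival$time,
                                           val$survival$event, risk_v)
  }
  tested <- !is.na(out$p_discovery)
  out$p_discovery_holm <- NA_real_
  out$p_validation_holm <- NA_real_
  out$p_discovery_holm[tested] <- holm_adjust(out$p_discovery[tested])
  out$p_validation_holm[tested] <- holm_adjust(out$p_validation[tested])
  out$passed <- tested & out$p_discovery_holm < alpha &
    out$p_validation_holm < alpha
  out
}

# univariate Cox Wald p of a risk-score vector, on the standardized scale
# (shrunken null scores can be numerically tiny); constant score gives p = 1
cox_p_of_score <- function(time, status, score) {
  s <- stats::sd(score)
  if (!is.finite(s) || s <= 0) return(1)
  d <- data.frame(time = time, event = status,
                  score = (score - mean(score)) / s)
  res <- tryCatch(suppressWarnings(fit_cox(d, "score")),
                  error = function(e) NULL)
  if (!is.null(res)) return(res$p[res$term == "score"])
  # monotone likelihood (the Wald test degenerates): fall back to the
  # score test, which is defined at beta = 0
  fit0 <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ score, data = d))
  stats::pchisq(fit0$score, 1, lower.tail = FALSE)
}

#' Stage 2: per-gene Cox in discovery and validation, ISS-adjusted
#'
#' Each gene of the lists that passed stage 1 is tested by univariate Cox on
#' per-SD standardized expression in the discovery set (Holm over genes);
#' survivors are re-tested in the validation set (Holm over survivors); and
#' those survivors are tested again in an ISS-stage-adjusted multivariate
#' Cox on the validation set (Holm). A gene passes when significant in all
#' three.
#'
#' @inheritParams stage1_list_test
#' @param genes character vector of genes entering stage 2.
#' @return data.frame with per-gene HRs (per SD), confidence intervals, raw
#'   and Holm-adjusted p per sub-step, and `passed`.
#' @export
stage2_gene_tests <- function(cohorts, genes, alpha = 0.05) {
  disc <- pool_cohorts(cohorts, "discovery")
  val <- pool_cohorts(cohorts, "validation")
  res <- data.frame(gene = genes)
  d_fit <- per_gene_cox(disc, genes)
  res[c("hr_discovery", "ci_low_discovery", "ci_high_discovery",
        "p_discovery")] <- d_fit
  res$p_discovery_holm <- holm_adjust(res$p_discovery)
  surv1 <- res$p_discovery_holm < alpha

  res[c("hr_validation", "ci_low_validation", "ci_high_validation",
        "p_validation")] <- NA_real_
  res$p_validation_holm <- NA_real_
  if (any(surv1)) {
    v_fit <- per_gene_cox(val, genes[surv1])
    res[surv1, c("hr_validation", "ci_low_validation", "ci_high_validation",
                 "p_validation")] <- v_fit
    res$p_validation_holm[surv1] <- holm_adjust(res$p_validation[surv1])
  }
  surv2 <- surv1 & !is.na(res$p_validation_holm) &
    res$p_validation_holm < alpha

  res[c("hr_multivariate", "ci_low_multivariate", "ci_high_multivariate",
        "p_multivariate")] <- NA_real_
  res$p_multivariate_holm <- NA_real_
  if (any(surv2)) {
    m_fit <- per_gene_cox(val, genes[surv2], adjust_iss = TRUE)
    res[surv2, c("hr_multivariate", "ci_low_multivariate",
                 "ci_high_multivariate", "p_multivariate")] <- m_fit
    res$p_multivariate_holm[surv2] <- holm_adjust(res$p_multivariate[surv2])
  }
  res$passed <- surv2 & !is.na(res$p_multivariate_holm) &
    res$p_multivariate_holm < alpha
  res
}

# per-SD univariate (or ISS-adjusted) Cox per gene on a pooled cohort
per_gene_cox <- function(pool, genes, adjust_iss = FALSE,
                         timedep = FALSE) {
  out <- data.frame(hr = rep(NA_real_, length(genes)), ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_)
  for (i in seq_along(genes)) {
    x <- as.numeric(pool$expression[genes[i], ])
    z <- (x - mean(x)) / max(stats::sd(x), 1e-12)
    d <- data.frame(time = pool$survival$time, event = pool$survival$event,
                    gene = z)
    covs <- "gene"
    if (adjust_iss) {
      d$iss <- factor(pool$survival$iss, levels = 1:3)
      covs <- c("gene", "iss")
    }
    fit <- if (timedep) {
      d$transplant_time <- pool$survival$transplant_time
      fit_cox_timedep(d, covs)
    } else fit_cox(d, covs)
    g <- fit[fit$term == "gene", ]
    out[i, ] <- c(g$hr, g$ci_low, g$ci_high, g$p)
  }
  out
}

#' Stage 3: multivariate validation with ISS and time-dependent transplant
#'
#' Each stage-2 survivor is tested in the second validation cohort with a
#' Cox model containing the gene (per SD), ISS stage, and the time-dependent
#' autologous-transplant indicator (counting-process expansion); Holm over
#' the tested genes.
#'
#' @inheritParams stage2_gene_tests
#' @return data.frame with per-gene adjusted HR, CI, `p`, `p_holm`,
#'   `passed`.
#' @export
stage3_multivariate <- function(cohorts, genes, alpha = 0.05) {
  sv <- pool_cohorts(cohorts, "second_validation")
  if (!length(genes)) {
    return(data.frame(gene = character(0), hr = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p = numeric(0), p_holm = numeric(0),
                      passed = logical(0)))
  }
  res <- data.frame(gene = genes)
  fit <- per_gene_cox(sv, genes, adjust_iss = TRUE, timedep = TRUE)
  res[c("hr", "ci_low", "ci_high", "p")] <- fit
  res$p_holm <- holm_adjust(res$p)
  res$passed <- res$p_holm < alpha
  res
}

#' Run the full three-stage screen
#'
#' Expression filter, batch equalization, list-level ridge-Cox stage,
#' per-gene discovery/validation stage, and the multivariate second
#' validation, Holm-corrected at every stage. Genes only move forward from
#' a stage they passed, so the final list is monotone in the stages.
#'
#' @inheritParams stage1_list_test
#' @param annotation optional annotated-gene vector for [filter_genes()].
#' @return list with `retained_genes`, `stage1`, `stage2`, `stage3` tables
#'   and `final_genes`.
#' @export
run_screen <- function(cohorts, gene_lists, annotation = NULL, alpha = 0.05,
                       nfolds = 10, grid = lambda_grid(), seed = 1) {
  retained <- filter_genes(cohorts, annotation)
  eq <- batch_equalize(cohorts)
  s1 <- stage1_list_test(eq, gene_lists, retained, alpha, nfolds, grid, seed)
  genes2 <- intersect(unlist(gene_lists[s1$list_name[s1$passed]],
                             use.names = FALSE), retained)
  s2 <- if (length(genes2)) stage2_gene_tests(eq, genes2, alpha) else {
    data.frame(gene = character(0))
  }
  genes3 <- if (nrow(s2)) s2$gene[s2$passed] else character(0)
  s3 <- stage3_multivariate(eq, genes3, alpha)
  list(retained_genes = retained, stage1 = s1, stage2 = s2, stage3 = s3,
       final_genes = if (nrow(s3)) s3$gene[s3$passed] else character(0))
}
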