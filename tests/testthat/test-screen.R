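small_cohorts <- function(seed = 1, n_genes = 12, planted = character(0),
                          hr = 1, ns = c(80, 60, 50), low = 0) {
  sp <- cohort_spec(n_patients = 10, n_genes = n_genes,
                    planted_genes = planted,
                    gene_log_hazard = log(hr), low_expr_frac = low,
                    iss_log_hazard = c(0.2, 0.5))
  cdf <- data.frame(cohort_id = c("d1", "v1", "s1"),
                    role = c("discovery", "validation", "second_validation"),
                    n = ns)
  generate_screen_cohorts(cdf, sp, seed = seed)
}

test_that("the expression filter drops unexpressed and unannotated genes", {
  cos <- small_cohorts(seed = 2, n_genes = 20, low = 0.3)
  kept <- filter_genes(cos)
  # genes that are low in some cohort are gone
  expect_lt(length(kept), 20)
  for (g in kept) {
    for (co in cos) {
      expect_lt(mean(co$expression[g, ] < 8), 0.5)
    }
  }
  # exact boundary: a gene below threshold in exactly half the patients
  co1 <- cos[[1]]
  gb <- kept[1]
  half <- seq_len(ncol(co1$expression)) <= ncol(co1$expression) / 2
  co1$expression[gb, half] <- 7
  cos1 <- cos; cos1[[1]] <- co1
  expect_false(gb %in% filter_genes(cos1))
  # annotation restriction
  expect_equal(filter_genes(cos, annotation = kept[1:3]), kept[1:3])
  expect_error(filter_genes(cos, annotation = "nope"), "no genes")
})

test_that("batch equalization matches cohort means and variances", {
  cos <- small_cohorts(seed = 3)
  eq <- batch_equalize(cos)
  genes <- rownames(eq[[1]]$expression)
  m <- vapply(eq, function(co) rowMeans(co$expression),
              numeric(length(genes)))
  v <- vapply(eq, function(co) apply(co$expression, 1, var),
              numeric(length(genes)))
  expect_lt(max(abs(m[, 1] - m[, 2])), 1e-10)
  expect_lt(max(abs(m[, 1] - m[, 3])), 1e-10)
  expect_lt(max(abs(v[, 1] - v[, 2])), 1e-10)
  # a single cohort passes through with its own moments as targets
  eq1 <- batch_equalize(cos[1])
  expect_equal(eq1[[1]]$expression, cos[[1]]$expression, tolerance = 1e-10)
  # cohort labels stop predicting expression after equalization
  ps <- vapply(genes, function(g) {
    students_t_test(c(eq[[1]]$expression[g, ], eq[[2]]$expression[g, ]),
                    rep(c("a", "b"), c(80, 60)))$p
  }, numeric(1))
  expect_gt(min(ps), 0.9) # equalized exactly, so t ~ 0
})

test_that("stage 1 is deterministic and invariant to patient permutation", {
  cos <- batch_equalize(small_cohorts(seed = 4))
  lists <- list(A = sprintf("g%04d", 1:6), B = sprintf("g%04d", 7:12))
  kept <- filter_genes(cos)
  s1 <- stage1_list_test(cos, lists, kept, seed = 5)
  s2 <- stage1_list_test(cos, lists, kept, seed = 5)
  expect_identical(s1, s2)
  # permute patients within each cohort
  cos_p <- lapply(cos, function(co) {
    perm <- sample(ncol(co$expression))
    co$expression <- co$expression[, perm]
    co$survival <- co$survival[perm, ]
    co
  })
  s3 <- stage1_list_test(cos_p, lists, kept, seed = 5)
  expect_equal(s1$p_discovery, s3$p_discovery, tolerance = 1e-12)
  expect_equal(s1$p_validation, s3$p_validation, tolerance = 1e-12)
})

test_that("stage 2 inverts hazard ratios under a sign flip", {
  cos <- batch_equalize(small_cohorts(seed = 6, planted = "g0001", hr = 0.6,
                                      ns = c(150, 120, 80)))
  s2 <- stage2_gene_tests(cos, c("g0001", "g0002"), alpha = 1)
  cos_f <- lapply(cos, function(co) {
    co$expression["g0001", ] <- -co$expression["g0001", ]
    co
  })
  s2f <- stage2_gene_tests(cos_f, c("g0001", "g0002"), alpha = 1)
  expect_equal(s2f$hr_discovery[1], 1 / s2$hr_discovery[1],
               tolerance = 1e-9)
})

test_that("stage 3 reduces to the ISS-adjusted model with no transplants", {
  cos <- small_cohorts(seed = 7)
  sv <- cos$s1
  sv$survival$transplant_time <- NA_real_
  cos$s1 <- sv
  s3 <- stage3_multivariate(cos, "g0001", alpha = 0.05)
  pool <- vistamm:::pool_cohorts(cos, "second_validation")
  x <- as.numeric(pool$expression["g0001", ])
  z <- (x - mean(x)) / sd(x)
  d <- data.frame(time = pool$survival$time, event = pool$survival$event,
                  gene = z, iss = factor(pool$survival$iss, levels = 1:3))
  ref <- fit_cox(d, c("gene", "iss"))
  expect_equal(s3$hr[1], ref$hr[ref$term == "gene"], tolerance = 1e-9)
})

test_that("the full screen keeps stage monotonicity and recovers a planted gene", {
  cos <- small_cohorts(seed = 8, n_genes = 14, planted = "g0001", hr = 0.55,
                       ns = c(260, 200, 200))
  lists <- list(A = sprintf("g%04d", 1:7), B = sprintf("g%04d", 8:14))
  res <- run_screen(cos, lists, seed = 3)
  # monotone: stage 2 genes come from passed lists, stage 3 from stage 2
  genes_passed_lists <- unlist(lists[res$stage1$list_name[res$stage1$passed]],
                               use.names = FALSE)
  expect_true(all(res$stage2$gene %in% genes_passed_lists))
  expect_true(all(res$stage3$gene %in% res$stage2$gene[res$stage2$passed]))
  expect_true(all(res$final_genes %in% res$stage3$gene))
  # the strongly planted gene survives to the end in this configuration
  expect_true("g0001" %in% res$final_genes)
})

test_that("null screens rarely let genes through (family-wise control)", {
  passed <- 0
  tested <- 0
  for (r in 1:25) {
    cos <- small_cohorts(seed = 900 + r, n_genes = 8, ns = c(60, 50, 40))
    lists <- list(A = sprintf("g%04d", 1:4), B = sprintf("g%04d", 5:8))
    res <- run_screen(cos, lists, seed = r)
    passed <- passed + length(res$final_genes)
    tested <- tested + 8
  }
  # Holm at every stage keeps the expected false-positive count tiny
  expect_lte(passed, 0.05 * tested)
})
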