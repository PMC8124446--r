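#!/usr/bin/env Rscript
# Screening arm: simulate discovery (n = 1000), validation (n = 600) and
# second-validation (n = 700, with transplant times) expression cohorts in
# which one immune gene among 101 carries a protective HR of 0.75 per SD,
# then run the three-stage screen (list-level ridge Cox with double-loop
# cross-testing, per-gene discovery/validation Cox, ISS- and
# transplant-adjusted multivariate validation; Holm at each stage).
# Writes the per-stage tables under results/screen/. Takes a few minutes:
# stage 1 fits ~250 ridge models inside every leave-one-out iteration.

suppressMessages(library(vistamm))

seed <- 20260927L
out_dir <- "results/screen"

sp <- cohort_spec(n_patients = 10, n_genes = 101, planted_genes = "g0101",
                  gene_log_hazard = log(0.75), iss_log_hazard = c(0.3, 0.7),
                  low_expr_frac = 0.1)
cdf <- data.frame(
  cohort_id = c("disc1", "disc2", "val1", "val2", "second_val"),
  role = c("discovery", "discovery", "validation", "validation",
           "second_validation"),
  n = c(600, 400, 300, 300, 700))
cohorts <- generate_screen_cohorts(cdf, sp, seed = seed)
gene_lists <- split(sprintf("g%04d", 1:101), rep(1:7, length.out = 101))
names(gene_lists) <- paste0("list", 1:7)
message("planted gene g0101 sits in ",
        names(Filter(function(g) "g0101" %in% g, gene_lists)))

res <- run_screen_report(cohorts, gene_lists,
                         config = run_config(seed = seed),
                         out_dir = out_dir)

cat("\n== three-stage screen ==\n")
cat("genes retained by the expression filter:",
    length(res$retained_genes), "/ 101\n")
print(res$stage1[, c("list_name", "n_genes", "p_discovery_holm",
                     "p_validation_holm", "passed")])
cat("stage 2: ", nrow(res$stage2), " genes tested, ",
    sum(res$stage2$passed), " passed\n", sep = "")
if (nrow(res$stage3)) {
  cat("stage 3 (ISS + time-dependent transplant adjusted):\n")
  print(res$stage3)
}
cat("final genes:", paste(res$final_genes, collapse = ", "), "\n")
cat("tables written to ", out_dir, "\n")
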