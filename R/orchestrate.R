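#' Run configuration
#'
#' One serializable object holding every tunable of a run: image-pipeline
#' parameters, spatial parameters, survival/screen settings and the seed.
#' Unknown keys are rejected so a config file cannot silently misspell a
#' parameter.
#'
#' @param pipeline named list of [pipeline_params()] overrides.
#' @param spatial named list: `eps` (ratio pseudocount).
#' @param survival named list: `alpha`.
#' @param screen named list: `alpha`, `nfolds`, `lambda_range`,
#'   `lambda_points`.
#' @param seed integer seed for every stochastic step.
#' @return list of class `run_config`.
#' @export
run_config <- function(pipeline = list(), spatial = list(eps = 0.1),
                       survival = list(alpha = 0.05),
                       screen = list(alpha = 0.05, nfolds = 10,
                                     lambda_range = c(1e-2, 1e4),
                                     lambda_points = 25),
                       seed = 1) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown ", where, " config key(s): ", paste(bad, collapse = ", "))
    }
  }
  check_keys(pipeline, names(formals(pipeline_params)), "pipeline")
  check_keys(spatial, c("eps"), "spatial")
  check_keys(survival, c("alpha"), "survival")
  check_keys(screen, c("alpha", "nfolds", "lambda_range", "lambda_points"),
             "screen")
  structure(list(pipeline = pipeline, spatial = spatial, survival = survival,
                 screen = screen, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("pipeline", "spatial", "survival", "screen", "seed")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Spatial arm: images to exclusion-score survival report
#'
#' Runs the image pipeline on every region of every patient, builds
#' per-patient spatial profiles, splits patients at the median exclusion
#' score and compares overall survival between the halves (Kaplan-Meier,
#' log-rank, Cox on the binary group - the primary read-out - and on the
#' continuous log score). Patients present in the images but absent from
#' the survival table are excluded with a logged count.
#'
#' @param images named list: `patient_id -> list of [multiplex_image()]`
#'   (one element per imaged region).
#' @param survival_table data.frame with `patient_id`, `time`, `event`.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, profile/KM/Cox tables, the
#'   resolved config and a run log are written there.
#' @return list with `profiles`, `scores` (per-patient data.frame including
#'   the group label), `km`, `logrank`, `cox_group`, `cox_log_score`.
#' @export
run_spatial <- function(images, survival_table, config = run_config(),
                        out_dir = NULL) {
  stopifnot(is.list(images), !is.null(names(images)))
  params <- do.call(pipeline_params, config$pipeline)
  eps <- config$spatial$eps

  known <- names(images) %in% survival_table$patient_id
  if (any(!known)) {
    message(sum(!known), " imaged patient(s) missing from the survival ",
            "table: excluded (", paste(names(images)[!known], collapse = ", "),
            ")")
    images <- images[known]
  }
  if (!length(images)) stop("no imaged patient has survival data")

  profiles <- lapply(names(images), function(pid) {
    regions <- lapply(images[[pid]], process_region, params = params)
    patient_spatial_profile(regions, pid,
                            images[[pid]][[1]]$pixel_edge_um, eps)
  })
  names(profiles) <- names(images)

  scores <- data.frame(
    patient_id = names(profiles),
    exclusion_score = vapply(profiles, function(p) p$exclusion_score,
                             numeric(1))
  )
  scores <- merge(scores, survival_table[, c("patient_id", "time", "event")],
                  by = "patient_id", sort = TRUE)
  usable <- !is.na(scores$exclusion_score)
  if (any(!usable)) {
    message(sum(!usable), " patient(s) without a defined exclusion score ",
            "excluded from the survival comparison")
  }
  sc <- scores[usable, , drop = FALSE]
  sc$group <- median_split(sc$exclusion_score)
  sc$log_score <- log(sc$exclusion_score)

  km <- kaplan_meier(sc, "group")
  lr <- logrank_test(sc, "group")
  sc$group_high <- as.integer(sc$group == "high")
  cox_group <- fit_cox(sc, "group_high")
  cox_log <- fit_cox(sc, "log_score")

  out <- list(profiles = profiles, scores = sc, km = km, logrank = lr,
              cox_group = cox_group, cox_log_score = cox_log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dens <- do.call(rbind, lapply(profiles, function(p) {
      cbind(patient_id = p$patient_id, p$density)
    }))
    write_result_csv(dens, file.path(out_dir, "patient_densities.csv"))
    write_result_csv(sc, file.path(out_dir, "exclusion_scores.csv"))
    write_result_csv(km, file.path(out_dir, "kaplan_meier.csv"))
    write_result_csv(rbind(cox_group, cox_log),
                     file.path(out_dir, "cox_results.csv"))
    write_run_config(config, file.path(out_dir, "config.yaml"))
    writeLines(c(
      paste("patients analyzed:", nrow(sc)),
      paste("log-rank chi-square:", signif(lr$chisq, 6), "p:",
            signif(lr$p, 6)),
      paste("config digest:",
            paste(utils::head(unlist(config), 20), collapse = ","))
    ), file.path(out_dir, "run_log.txt"))
  }
  out
}

#' Screen arm with file output
#'
#' Thin wrapper over [run_screen()] that also writes the per-stage tables,
#' the resolved configuration and a log to a directory.
#'
#' @inheritParams run_screen
#' @param config a [run_config()] (its `screen` settings and `seed` drive
#'   the run).
#' @param out_dir optional output directory.
#' @return the [run_screen()] result.
#' @export
run_screen_report <- function(cohorts, gene_lists, config = run_config(),
                              annotation = NULL, out_dir = NULL) {
  scr <- config$screen
  grid <- lambda_grid(scr$lambda_points, scr$lambda_range)
  res <- run_screen(cohorts, gene_lists, annotation = annotation,
                    alpha = scr$alpha, nfolds = scr$nfolds, grid = grid,
                    seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_csv(res$stage1, file.path(out_dir, "stage1_lists.csv"))
    if (nrow(res$stage2)) {
      write_result_csv(res$stage2, file.path(out_dir, "stage2_genes.csv"))
    }
    if (nrow(res$stage3)) {
      write_result_csv(res$stage3, file.path(out_dir, "stage3_genes.csv"))
    }
    write_run_config(config, file.path(out_dir, "config.yaml"))
    writeLines(c(
      paste("genes retained by expression filter:",
            length(res$retained_genes)),
      paste("lists passing stage 1:",
            paste(res$stage1$list_name[res$stage1$passed], collapse = ", ")),
      paste("final genes:", paste(res$final_genes, collapse = ", "))
    ), file.path(out_dir, "run_log.txt"))
  }
  res
}
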