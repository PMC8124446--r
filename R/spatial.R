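#' Phenotype definitions used for spatial read-outs
#'
#' Single markers plus the composite VISTA+CD11b+ phenotype (both markers
#' positive, regardless of the others).
#' @return named list mapping phenotype name to required-marker set.
#' @export
spatial_phenotypes <- function() {
  list(CD138 = "CD138", CD8 = "CD8", CD11b = "CD11b", VISTA = "VISTA",
       "VISTA+CD11b" = c("VISTA", "CD11b"))
}

# logical selector: cells positive for every marker of the phenotype
cells_with_phenotype <- function(cells, phenotype,
                                 phenotypes = spatial_phenotypes()) {
  need <- if (phenotype %in% names(phenotypes)) phenotypes[[phenotype]]
  else phenotype
  sel <- rep(TRUE, nrow(cells))
  for (m in need) {
    col <- paste0("pos_", m)
    if (!col %in% names(cells)) stop("no marker flag column '", col, "'")
    sel <- sel & cells[[col]]
  }
  sel
}

#' Compartmentalized cell densities for one region
#'
#' Density of each phenotype in each compartment: the number of cells of
#' that phenotype assigned to the compartment divided by the compartment
#' area in mm^2. A zero-area compartment yields `NA` densities (logged).
#'
#' @param cells phenotyped cell table from [phenotype_cells()].
#' @param seg segmentation result carrying `tumor` and `stroma` masks.
#' @param pixel_edge_um pixel edge length (um).
#' @param phenotypes named list as [spatial_phenotypes()].
#' @return data.frame: `phenotype`, `compartment`, `n_cells`, `area_mm2`,
#'   `density` (cells/mm^2).
#' @export
compute_densities <- function(cells, seg, pixel_edge_um = 0.2421,
                              phenotypes = spatial_phenotypes()) {
  px_mm2 <- (pixel_edge_um / 1000)^2
  areas <- c(tumor = sum(seg$tumor) * px_mm2, stroma = sum(seg$stroma) * px_mm2)
  out <- expand.grid(phenotype = names(phenotypes),
                     compartment = c("tumor", "stroma"),
                     stringsAsFactors = FALSE)
  out$n_cells <- NA_integer_
  out$area_mm2 <- areas[out$compartment]
  out$density <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- cells_with_phenotype(cells, out$phenotype[i], phenotypes) &
      !is.na(cells$compartment) & cells$compartment == out$compartment[i]
    out$n_cells[i] <- sum(sel)
    if (out$area_mm2[i] > 0) {
      out$density[i] <- out$n_cells[i] / out$area_mm2[i]
    }
  }
  if (any(areas == 0)) {
    message("zero-area compartment(s): ",
            paste(names(areas)[areas == 0], collapse = ", "),
            "; densities set to NA")
  }
  out
}

#' Mean nearest-neighbor distance between phenotypes in a compartment
#'
#' For every source-phenotype cell in the compartment, the Euclidean
#' distance between cell-area centers to the nearest target-phenotype cell
#' in the same compartment, averaged over source cells. When source and
#' target phenotypes coincide the cell itself is excluded. Returns `NA`
#' (with a log message) when there is no source or no target cell.
#'
#' @param cells phenotyped cell table.
#' @param from,to phenotype names (see [spatial_phenotypes()]).
#' @param compartment `"tumor"` or `"stroma"`.
#' @param pixel_edge_um pixel edge length (um).
#' @return mean distance in micrometers, or `NA`.
#' @export
mean_nn_distance <- function(cells, from, to, compartment,
                             pixel_edge_um = 0.2421) {
  in_comp <- !is.na(cells$compartment) & cells$compartment == compartment
  src <- which(in_comp & cells_with_phenotype(cells, from))
  tgt <- which(in_comp & cells_with_phenotype(cells, to))
  if (!length(src) || !length(tgt)) {
    message("no ", if (!length(src)) from else to, " cells in ", compartment,
            ": nearest-neighbor distance undefined")
    return(NA_real_)
  }
  px <- cbind(cells$centroid_row, cells$centroid_col)
  d <- vapply(src, function(i) {
    cand <- setdiff(tgt, i)
    if (!length(cand)) return(NA_real_)
    sqrt(min((px[cand, 1] - px[i, 1])^2 + (px[cand, 2] - px[i, 2])^2))
  }, numeric(1))
  if (all(is.na(d))) {
    message("no valid neighbor pairs for ", from, " -> ", to, " in ",
            compartment)
    return(NA_real_)
  }
  mean(d, na.rm = TRUE) * pixel_edge_um
}

#' Preferential localization ratio
#'
#' Ratio of tumor to stroma density for a phenotype, with an additive
#' pseudocount that keeps the ratio finite when a compartment is empty.
#'
#' @param densities density table from [compute_densities()] (or averaged
#'   across regions).
#' @param phenotype phenotype name.
#' @param eps pseudocount in cells/mm^2 (0 allowed).
#' @return dimensionless tumor/stroma ratio, or `NA` if a density is missing.
#' @export
preferential_localization <- function(densities, phenotype, eps = 0.1) {
  d_t <- densities$density[densities$phenotype == phenotype &
                             densities$compartment == "tumor"]
  d_s <- densities$density[densities$phenotype == phenotype &
                             densities$compartment == "stroma"]
  if (!length(d_t) || !length(d_s) || is.na(d_t) || is.na(d_s)) {
    return(NA_real_)
  }
  (d_t + eps) / (d_s + eps)
}

#' VISTA-associated T-cell exclusion score
#'
#' Product of the preferential tumor localization of VISTA+CD11b+ cells and
#' the preferential stroma localization of CD8+ T cells:
#' \deqn{score = \frac{d_{VISTA+CD11b+, tumor}}{d_{VISTA+CD11b+, stroma}}
#'   \times \frac{d_{CD8, stroma}}{d_{CD8, tumor}}}
#' (each ratio with pseudocount `eps`). A high score means myeloid
#' VISTA+CD11b+ cells concentrate in the tumor while CD8 T cells are held in
#' the stroma. The score is invariant under a common positive rescaling of
#' all densities (exactly so when `eps = 0`) and swapping the compartments
#' of both phenotypes maps it to its reciprocal.
#'
#' @param densities density table with both phenotypes in both compartments.
#' @param eps pseudocount in cells/mm^2.
#' @return dimensionless score, `NA` if any constituent is missing.
#' @export
exclusion_score <- function(densities, eps = 0.1) {
  pl_vc <- preferential_localization(densities, "VISTA+CD11b", eps)
  pl_cd8 <- preferential_localization(densities, "CD8", eps)
  if (is.na(pl_vc) || is.na(pl_cd8)) return(NA_real_)
  pl_vc / pl_cd8
}

#' Per-patient spatial profile
#'
#' Averages region-level densities and nearest-neighbor distances across a
#' patient's image regions (densities first, ratios on the averages), then
#' derives preferential-localization ratios and the exclusion score.
#'
#' @param region_results list of per-region results as returned by
#'   [process_region()] (each with `cells` and `seg`).
#' @param patient_id identifier.
#' @param pixel_edge_um pixel edge length (um).
#' @param eps pseudocount for ratios.
#' @param nn_pairs optional data.frame (`from`, `to`, `compartment`) of
#'   nearest-neighbor summaries to compute.
#' @return list of class `patient_spatial_profile`: `patient_id`, `density`
#'   (region-averaged table), `nn_distance`, `pref_localization`,
#'   `exclusion_score`.
#' @export
patient_spatial_profile <- function(region_results, patient_id,
                                    pixel_edge_um = 0.2421, eps = 0.1,
                                    nn_pairs = NULL) {
  dens_list <- lapply(region_results, function(rr) {
    compute_densities(rr$cells, rr$seg, pixel_edge_um)
  })
  dens <- dens_list[[1]][, c("phenotype", "compartment")]
  dmat <- vapply(dens_list, function(d) d$density, numeric(nrow(dens)))
  dmat <- matrix(dmat, nrow = nrow(dens))
  dens$density <- rowMeans(dmat, na.rm = TRUE)
  dens$density[is.nan(dens$density)] <- NA_real_

  nn <- NULL
  if (is.null(nn_pairs)) {
    nn_pairs <- expand.grid(from = c("VISTA+CD11b", "CD8"),
                            to = c("CD8", "VISTA+CD11b"),
                            compartment = c("tumor", "stroma"),
                            stringsAsFactors = FALSE)
    nn_pairs <- nn_pairs[nn_pairs$from != nn_pairs$to, ]
  }
  if (nrow(nn_pairs)) {
    nn <- nn_pairs
    nn$mean_um <- vapply(seq_len(nrow(nn)), function(i) {
      per_region <- vapply(region_results, function(rr) {
        suppressMessages(mean_nn_distance(rr$cells, nn$from[i], nn$to[i],
                                          nn$compartment[i], pixel_edge_um))
      }, numeric(1))
      if (all(is.na(per_region))) NA_real_ else mean(per_region, na.rm = TRUE)
    }, numeric(1))
  }

  pl <- vapply(names(spatial_phenotypes()), function(ph) {
    preferential_localization(dens, ph, eps)
  }, numeric(1))

  structure(list(patient_id = patient_id, density = dens, nn_distance = nn,
                 pref_localization = pl,
                 exclusion_score = exclusion_score(dens, eps)),
            class = "patient_spatial_profile")
}

#' @export
print.patient_spatial_profile <- function(x, ...) {
  cat("<patient_spatial_profile>", x$patient_id, "- exclusion score:",
      signif(x$exclusion_score, 4), "\n")
  invisible(x)
}
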