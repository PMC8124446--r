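markers_of_interest <- function(params) names(params$phenotype_thresholds)

# per-label area, centroid and per-channel mean intensity
measure_labels <- function(labels, channels) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(NULL)
  lab <- labels[idx]
  n_lab <- max(lab)
  area <- tabulate(lab, nbins = n_lab)
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  present <- which(area > 0)
  out <- data.frame(
    cell_id = present,
    area_px2 = area[present],
    centroid_row = (rowsum(as.numeric(rows), lab)[, 1] / area[present]),
    centroid_col = (rowsum(as.numeric(cols), lab)[, 1] / area[present])
  )
  for (nm in names(channels)) {
    v <- channels[[nm]][idx]
    out[[paste0("mean_", nm)]] <- rowsum(v, lab)[, 1] / area[present]
  }
  out
}

#' Phenotype segmented cells
#'
#' Measures every cell region (area, cell-area centroid, per-channel mean
#' normalized intensity), removes megakaryocytes (VISTA-positive regions
#' larger than the upper area gate; see [exclude_megakaryocytes()]), keeps
#' cells whose area lies within the closed gate
#' `[cell_area_min_px2, cell_area_max_px2]`, calls a marker positive when the
#' mean normalized intensity strictly exceeds its threshold, and assigns each
#' cell to tumor or stroma by the location of its nucleus centroid (cells
#' whose centroid falls outside both compartments are attached to the nearest
#' compartment pixel).
#'
#' @param cells_mask integer cell label matrix from [segment_cells()].
#' @param norm normalized [multiplex_image()].
#' @param seg list with `tumor` and `stroma` masks (from [segment_tissue()])
#'   and `nucleus_labels` (from [segment_nuclei()]); [process_region()]
#'   assembles this automatically.
#' @param params a [pipeline_params()].
#' @return data.frame with one row per phenotyped cell: `region_id`,
#'   `cell_id`, nucleus and cell-area centroids, `area_px2`, per-channel
#'   `mean_*` columns, logical `pos_*` marker flags, and `compartment`.
#'   Attribute `n_megakaryocytes` counts the excluded giant VISTA+ cells.
#' @export
phenotype_cells <- function(cells_mask, norm, seg,
                            params = pipeline_params()) {
  meas <- measure_labels(cells_mask, norm$channels)
  empty <- data.frame(region_id = character(0), cell_id = integer(0))
  if (is.null(meas)) return(structure(empty, n_megakaryocytes = 0L))

  nuc <- measure_labels(seg$nucleus_labels, norm$channels[1])
  meas$nucleus_row <- nuc$centroid_row[match(meas$cell_id, nuc$cell_id)]
  meas$nucleus_col <- nuc$centroid_col[match(meas$cell_id, nuc$cell_id)]

  meas <- exclude_megakaryocytes(meas, params)
  n_mk <- attr(meas, "n_megakaryocytes")

  keep <- meas$area_px2 >= params$cell_area_min_px2 &
    meas$area_px2 <= params$cell_area_max_px2
  meas <- meas[keep, , drop = FALSE]
  if (!nrow(meas)) {
    return(structure(empty, n_megakaryocytes = n_mk))
  }

  for (m in markers_of_interest(params)) {
    col <- paste0("mean_", m)
    if (!col %in% names(meas)) next
    meas[[paste0("pos_", m)]] <- meas[[col]] > params$phenotype_thresholds[[m]]
  }

  meas$compartment <- assign_compartment(meas$nucleus_row, meas$nucleus_col,
                                         seg$tumor, seg$stroma)
  meas$region_id <- norm$region_id
  rownames(meas) <- NULL
  structure(meas, n_megakaryocytes = n_mk)
}

# compartment of the nucleus centroid; centroids on removed components are
# attached to the nearest retained compartment pixel (ties go to tumor)
assign_compartment <- function(rows, cols, tumor, stroma) {
  ri <- pmin(pmax(round(rows), 1L), nrow(tumor))
  ci <- pmin(pmax(round(cols), 1L), ncol(tumor))
  at <- cbind(ri, ci)
  out <- ifelse(tumor[at], "tumor", ifelse(stroma[at], "stroma", NA))
  if (anyNA(out)) {
    has_t <- any(tumor); has_s <- any(stroma)
    d_t <- if (has_t) EBImage::distmap(!tumor) else NULL
    d_s <- if (has_s) EBImage::distmap(!stroma) else NULL
    miss <- which(is.na(out))
    for (i in miss) {
      dt <- if (has_t) d_t[ri[i], ci[i]] else Inf
      ds <- if (has_s) d_s[ri[i], ci[i]] else Inf
      out[i] <- if (is.infinite(dt) && is.infinite(ds)) NA
      else if (dt <= ds) "tumor" else "stroma"
    }
  }
  out
}

#' Megakaryocyte exclusion
#'
#' Very large VISTA-expressing cells (morphologically megakaryocytes) are
#' removed before the general area gate: any region whose mean VISTA exceeds
#' the VISTA phenotype threshold and whose area exceeds `cell_area_max_px2`
#' is dropped and counted. Large VISTA-negative regions are left to the
#' general area gate and are not flagged.
#'
#' @param cells measured cell table (with `area_px2` and `mean_VISTA`).
#' @param params a [pipeline_params()].
#' @return the table without megakaryocytes; attribute `n_megakaryocytes`
#'   holds the number removed.
#' @export
exclude_megakaryocytes <- function(cells, params = pipeline_params()) {
  if (!nrow(cells) || !"mean_VISTA" %in% names(cells)) {
    return(structure(cells, n_megakaryocytes = 0L))
  }
  mk <- cells$area_px2 > params$cell_area_max_px2 &
    cells$mean_VISTA > params$phenotype_thresholds[["VISTA"]]
  if (any(mk)) {
    message(sum(mk), " megakaryocyte(s) excluded (VISTA+ regions > ",
            params$cell_area_max_px2, " px^2)")
  }
  structure(cells[!mk, , drop = FALSE], n_megakaryocytes = sum(mk))
}

#' Run the full image pipeline on one region
#'
#' Normalization, foreground detection, tumor/stroma segmentation, nucleus
#' and Voronoi cell segmentation, phenotyping and megakaryocyte exclusion,
#' as one deterministic function of the image and parameters.
#'
#' @param img a raw [multiplex_image()] with at least the DAPI, CD138, CD8,
#'   CD11b and VISTA channels.
#' @param params a [pipeline_params()].
#' @return list with `cells` (phenotyped cell table), `seg` (class
#'   `mm_segmentation`: `foreground`, `tumor`, `stroma`, `nucleus_labels`,
#'   `cell_labels`), and `norm` (the normalized image).
#' @export
process_region <- function(img, params = pipeline_params()) {
  check_channels(img)
  norm <- normalize_image(img, params)
  fg <- detect_foreground(norm, params)
  tis <- segment_tissue(norm, fg, params)
  nuclei <- segment_nuclei(img$channels$DAPI, params)
  cells_mask <- segment_cells(nuclei, fg)
  seg <- structure(list(foreground = fg, tumor = tis$tumor,
                        stroma = tis$stroma, nucleus_labels = nuclei,
                        cell_labels = cells_mask,
                        region_id = img$region_id),
                   class = "mm_segmentation")
  cells <- phenotype_cells(cells_mask, norm, seg, params)
  list(cells = cells, seg = seg, norm = norm)
}
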