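label_components8 <- function(mask) {
  cpp_label_components8(mask)
}

# drop 8-connected components whose area is <= min_area (strict "larger than"
# retention); returns the filtered logical mask
filter_small_components <- function(mask, min_area) {
  lab <- label_components8(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas > min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Foreground detection
#'
#' A pixel is foreground when its normalized intensity exceeds the threshold
#' in any channel; 8-connected foreground components not larger than
#' `min_region_area_px2` are then discarded.
#'
#' @param norm a normalized [multiplex_image()] (output of
#'   [normalize_image()]).
#' @param params a [pipeline_params()].
#' @return logical matrix.
#' @export
detect_foreground <- function(norm, params = pipeline_params()) {
  stopifnot(inherits(norm, "multiplex_image"))
  fg <- Reduce(`|`, lapply(norm$channels,
                           function(ch) ch > params$foreground_threshold))
  filter_small_components(fg, params$min_region_area_px2)
}

#' Tumor/stroma tissue segmentation
#'
#' The CD138 channel is smoothed with a Gaussian filter (sigma 10 px by
#' default); foreground pixels where the smoothed signal exceeds the tissue
#' threshold form the tumor compartment, the rest the stroma. Both
#' compartments are subjected to the same component-size rule as the
#' foreground: tumor components not larger than `min_region_area_px2` are
#' reassigned to stroma and vice versa, so tumor and stroma always partition
#' the foreground.
#'
#' @param norm a normalized [multiplex_image()] containing a CD138 channel.
#' @param foreground logical foreground mask from [detect_foreground()].
#' @param params a [pipeline_params()].
#' @return list with logical matrices `tumor` and `stroma`.
#' @export
segment_tissue <- function(norm, foreground, params = pipeline_params()) {
  stopifnot(inherits(norm, "multiplex_image"),
            "CD138" %in% names(norm$channels))
  sm <- EBImage::gblur(norm$channels$CD138,
                       sigma = params$tissue_gaussian_sigma_px)
  tumor <- foreground & (sm > params$tissue_threshold)
  tumor <- filter_small_components(tumor, params$min_region_area_px2)
  stroma <- foreground & !tumor
  stroma <- filter_small_components(stroma, params$min_region_area_px2)
  tumor <- foreground & !stroma
  list(tumor = tumor, stroma = stroma)
}

#' Nucleus segmentation
#'
#' Raw DAPI is background corrected, thresholded (Otsu by default, or an
#' absolute threshold), cleared of sub-nuclear specks, and split into single
#' nuclei by a watershed on the Euclidean distance transform.
#'
#' @param raw_dapi raw DAPI channel matrix.
#' @param params a [pipeline_params()].
#' @return integer label matrix; 0 is background.
#' @export
segment_nuclei <- function(raw_dapi, params = pipeline_params()) {
  stopifnot(is.matrix(raw_dapi))
  corr <- pmax(raw_dapi - estimate_background(raw_dapi, params), 0)
  mx <- max(corr)
  if (mx <= 1e-8 * max(raw_dapi, 1e-12)) {
    warning("blank DAPI channel: no nuclei found", call. = FALSE)
    return(matrix(0L, nrow(raw_dapi), ncol(raw_dapi)))
  }
  thr <- params$dapi_threshold
  if (is.null(thr)) thr <- EBImage::otsu(corr, range = c(0, mx))
  mask <- corr > thr
  mask <- filter_small_components(mask, params$min_nucleus_area_px2)
  if (!any(mask)) {
    warning("no nuclei above the DAPI threshold", call. = FALSE)
    return(matrix(0L, nrow(raw_dapi), ncol(raw_dapi)))
  }
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                            ext = 1)
  matrix(as.integer(lab), nrow(raw_dapi), ncol(raw_dapi))
}

#' Voronoi cell segmentation
#'
#' Every foreground pixel is assigned to the nearest nucleus region
#' (Euclidean distance to the region's closest pixel); background pixels stay
#' 0. Ties between equidistant nuclei go to the lowest label, so the result
#' is deterministic and labels are bijective with nuclei.
#'
#' @param nuclei integer nucleus label matrix from [segment_nuclei()].
#' @param foreground logical foreground mask.
#' @return integer cell label matrix.
#' @export
segment_cells <- function(nuclei, foreground) {
  stopifnot(all(dim(nuclei) == dim(foreground)))
  n_lab <- max(nuclei)
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  if (n_lab == 0L) {
    if (any(foreground)) {
      warning("no nuclei: foreground left unassigned", call. = FALSE)
    }
    return(out)
  }
  best_d <- matrix(Inf, nrow(nuclei), ncol(nuclei))
  for (l in seq_len(n_lab)) {
    if (!any(nuclei == l)) next
    d <- EBImage::distmap(nuclei != l)
    upd <- d < best_d # strict: ties keep the lower label
    best_d[upd] <- d[upd]
    out[upd] <- l
  }
  out[!foreground] <- 0L
  out
}
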