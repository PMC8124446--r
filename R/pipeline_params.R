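#' Image-pipeline parameters
#'
#' All tunable constants of the image pipeline. Defaults implement the
#' standard analysis: foreground where any normalized channel exceeds 0.2,
#' keeping only regions larger than 5000 px^2 (293 um^2 at a 0.2421 um pixel
#' edge); tumor where the 10 px Gaussian-smoothed CD138 channel exceeds 0.2;
#' cells phenotyped when their area lies in [500, 5000] px^2 with marker
#' thresholds 0.5 (CD138) and 1.5 (CD8, CD11b, VISTA) on mean normalized
#' intensity; VISTA-positive regions above the upper area gate are excluded
#' as megakaryocytes.
#'
#' @param foreground_threshold normalized intensity above which a pixel is
#'   foreground (in any channel).
#' @param min_region_area_px2 strict lower size bound for foreground (and
#'   tumor/stroma) connected components, px^2; components of this size or
#'   smaller are removed (8-connectivity).
#' @param tissue_gaussian_sigma_px Gaussian sigma for CD138 smoothing.
#' @param tissue_threshold smoothed-CD138 level separating tumor from stroma.
#' @param cell_area_min_px2,cell_area_max_px2 closed-interval area gate for
#'   phenotyped cells.
#' @param phenotype_thresholds named vector of mean-intensity thresholds;
#'   strict (mean must exceed the threshold).
#' @param background_method `"polyfit"` (robust low-quantile polynomial
#'   surface fit, the default) or `"tophat"` (morphological opening).
#' @param background_quantile minimum fraction of pixels assumed signal-free
#'   (fallback support for the iterative background re-fit).
#' @param dark_quantile per-channel quantile defining "dark"; pixels dark in
#'   every channel form the signal-free support the background surfaces are
#'   fit on. The imaged field must keep at least this fraction free of
#'   tissue.
#' @param background_degree polynomial surface degree.
#' @param tophat_radius structuring-disc radius (px) for `"tophat"`.
#' @param norm_quantile quantile of positive background-corrected pixels used
#'   as the per-channel normalization scale. It must sit inside the dim
#'   (nonspecific) signal population for the fixed phenotype thresholds to be
#'   meaningful; the median (0.5) is robust whenever specifically stained
#'   cells make up less than half of a channel's signal pixels. Signal
#'   pixels are those above a noise floor of 5 robust SDs estimated from
#'   the negative background-correction residuals.
#' @param dapi_threshold absolute threshold on background-corrected DAPI, or
#'   `NULL` for Otsu.
#' @param min_nucleus_area_px2 specks below this size are not nuclei.
#' @param watershed_tolerance minimum object height in the distance-map
#'   watershed that separates touching nuclei.
#' @return a list of class `pipeline_params`.
#' @export
pipeline_params <- function(foreground_threshold = 0.2,
                            min_region_area_px2 = 5000,
                            tissue_gaussian_sigma_px = 10,
                            tissue_threshold = 0.2,
                            cell_area_min_px2 = 500,
                            cell_area_max_px2 = 5000,
                            phenotype_thresholds = c(CD138 = 0.5, CD8 = 1.5,
                                                     CD11b = 1.5,
                                                     VISTA = 1.5),
                            background_method = c("polyfit", "tophat"),
                            background_quantile = 0.25,
                            dark_quantile = 0.35,
                            background_degree = 2,
                            tophat_radius = 50,
                            norm_quantile = 0.5,
                            dapi_threshold = NULL,
                            min_nucleus_area_px2 = 40,
                            watershed_tolerance = 1) {
  background_method <- match.arg(background_method)
  stopifnot(foreground_threshold > 0, tissue_threshold > 0,
            all(phenotype_thresholds > 0),
            cell_area_min_px2 < cell_area_max_px2,
            norm_quantile > 0, norm_quantile < 1)
  structure(as.list(environment()), class = "pipeline_params")
}
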