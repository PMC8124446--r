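#' Pixel/area unit conversions
#'
#' The imaging platform's pixel edge length ties pixel-squared areas to
#' physical areas: with the default edge of 0.2421 um, 5000 px^2 corresponds
#' to 293 um^2 and 500 px^2 to 29.3 um^2 (the cell-area gates used in
#' phenotyping).
#'
#' @param area_px2 area in squared pixels.
#' @param area_um2 area in squared micrometers.
#' @param pixel_edge_um length of one pixel edge in micrometers.
#' @return the converted area.
#' @examples
#' px2_to_um2(5000) # ~293 um^2
#' @export
px2_to_um2 <- function(area_px2, pixel_edge_um = 0.2421) {
  stopifnot(pixel_edge_um > 0)
  area_px2 * pixel_edge_um^2
}

#' @rdname px2_to_um2
#' @export
um2_to_px2 <- function(area_um2, pixel_edge_um = 0.2421) {
  stopifnot(pixel_edge_um > 0)
  area_um2 / pixel_edge_um^2
}

#' @rdname px2_to_um2
#' @param area_px2_ref,area_um2_ref a known pixel/physical area pair.
#' @export
derive_pixel_edge_um <- function(area_px2_ref = 5000, area_um2_ref = 293) {
  sqrt(area_um2_ref / area_px2_ref)
}
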