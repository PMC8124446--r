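#' Write / read a multiplex image as multi-page TIFF plus JSON metadata
#'
#' Channels are stored as 32-bit float TIFF pages. Because TIFF float
#' storage here is defined on [0, 1], each channel is divided by a recorded
#' per-channel gain (its maximum); the gain, channel names, pixel size and
#' region id live in a JSON sidecar next to the TIFF (`<path>.json`), and
#' reading restores the original values.
#'
#' @param img a [multiplex_image()].
#' @param path TIFF file path (the sidecar is `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_multiplex_image <- function(img, path) {
  stopifnot(inherits(img, "multiplex_image"))
  gains <- vapply(img$channels, function(ch) max(ch, 1e-12), numeric(1))
  pages <- mapply(function(ch, g) ch / g, img$channels, gains,
                  SIMPLIFY = FALSE)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- list(channels = names(img$channels), gains = unname(gains),
               pixel_edge_um = img$pixel_edge_um, region_id = img$region_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_multiplex_image
#' @export
read_multiplex_image <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("missing metadata sidecar: ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels)) {
    stop("TIFF page count does not match the recorded channel names")
  }
  channels <- mapply(function(p, g) p * g, pages, meta$gains,
                     SIMPLIFY = FALSE)
  names(channels) <- meta$channels
  multiplex_image(channels, meta$pixel_edge_um, meta$region_id)
}

#' Write a cell table (or any result table) as CSV
#' @param x data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  drop <- vapply(x, is.list, logical(1))
  utils::write.csv(x[, !drop, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
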