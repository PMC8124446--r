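#' Multichannel fluorescence image container
#'
#' A named list of equally-sized non-negative channel rasters plus pixel-size
#' metadata. The core phenotyping panel requires channels DAPI, CD138, CD8,
#' CD11b and VISTA; additional channels (e.g. an autofluorescence channel) are
#' carried along and participate in foreground detection but not phenotyping.
#'
#' @param channels named list of numeric matrices, all with identical
#'   dimensions and non-negative values.
#' @param pixel_edge_um pixel edge length in micrometers (> 0).
#' @param region_id identifier of the imaged region (one region of one
#'   patient's section).
#' @return an object of class `multiplex_image`.
#' @export
multiplex_image <- function(channels, pixel_edge_um = 0.2421,
                            region_id = "region1") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) stop("all channels must share dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) {
      stop("channel '", nm, "' is not a numeric matrix")
    }
    if (anyNA(ch) || any(ch < 0)) {
      stop("channel '", nm, "' must be finite and non-negative")
    }
  }
  stopifnot(is.numeric(pixel_edge_um), pixel_edge_um > 0)
  structure(
    list(channels = channels, pixel_edge_um = pixel_edge_um,
         region_id = as.character(region_id)),
    class = "multiplex_image"
  )
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<multiplex_image> region", x$region_id, "-", d[1], "x", d[2],
      "px,", length(x$channels), "channels (",
      paste(names(x$channels), collapse = ", "), "), pixel edge",
      x$pixel_edge_um, "um\n")
  invisible(x)
}

#' @param img a `multiplex_image`.
#' @param required channel names that must be present.
#' @rdname multiplex_image
#' @export
check_channels <- function(img, required = c("DAPI", "CD138", "CD8", "CD11b",
                                             "VISTA")) {
  missing <- setdiff(required, names(img$channels))
  if (length(missing)) {
    stop("image region '", img$region_id, "' is missing channel(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(img)
}
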