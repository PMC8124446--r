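#' Specification for a synthetic multiplex image
#'
#' Describes the ground-truthed image the generator renders: a smooth tissue
#' blob containing a tumor sub-region (dense CD138+ plasma cells), immune
#' cells with requested phenotypes placed on jittered compartment grids,
#' plus a smooth polynomial background field and additive Gaussian noise.
#'
#' Cells are placed on a jittered square grid spanning the tissue (grid gap
#' larger than the cell diameter) so cells never overlap and downstream
#' Voronoi cell areas stay within the phenotyping gates; grid sites are
#' classified as tumor or stroma by the compartment under them, and sites
#' not taken by a requested phenotype are filled with CD138+ plasma cells
#' (tumor) or marker-negative "filler" cells, keeping cell regions bounded. Each cell
#' contributes a truncated-Gaussian DAPI nucleus, a bright uniform disk on
#' the channels of its positive markers, and a dim nonspecific disk on the
#' other marker channels; an autofluorescence channel carries a uniform
#' tissue carpet so the whole section is foreground.
#'
#' @param shape image dimensions `c(rows, cols)` in pixels.
#' @param pixel_edge_um pixel edge length (um).
#' @param tumor_frac fraction of tissue assigned to the tumor compartment.
#' @param counts data.frame with columns `phenotype` (one of "CD138", "CD8",
#'   "CD11b", "VISTA", "VISTA+CD11b", "none"), `compartment` ("tumor" or
#'   "stroma") and `n`.
#' @param n_plasma number of CD138+ plasma cells in the tumor, or `NULL` to
#'   fill all remaining tumor grid sites (the default, which makes the tumor
#'   CD138-dense as tissue segmentation assumes).
#' @param fill if `TRUE`, remaining grid sites become marker-negative filler
#'   cells (nucleus only plus nonspecific staining).
#' @param n_megakaryocytes number of very large VISTA-bright cells planted in
#'   the stroma (excluded by the pipeline's megakaryocyte rule).
#' @param cell_radius,nucleus_radius cell and nucleus radii in pixels
#'   (nucleus must be smaller than cell).
#' @param grid_spacing,grid_jitter grid geometry in pixels; the jittered
#'   gap `grid_spacing - 2 * grid_jitter` must exceed the cell diameter.
#' @param tumor_margin minimum distance (px) of the tumor region from the
#'   tissue boundary, so tumor cells never sit on the tissue edge where
#'   Voronoi regions inflate.
#' @param amplitudes named list of rendering amplitudes (design units):
#'   `dapi` nucleus peak, `af` tissue carpet, `dim` nonspecific disk on
#'   CD8/CD11b/VISTA, `bright` specific disk (CD8/CD11b/VISTA), and
#'   `cd138_bright` (plasma-cell disks; the normalization scale pins on
#'   the plasma population) and `cd138_shed` (dim shed-CD138 level on
#'   non-plasma cells inside the tumor, which keeps the smoothed tumor
#'   region contiguous while staying far below the phenotype threshold).
#' @param bg_amplitude peak of the smooth quadratic background field.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (design units; the dim nonspecific level is 1).
#' @param gains named per-channel multiplicative gains applied to the final
#'   raster (channel normalization must undo them).
#' @return a list of class `image_spec`.
#' @export
image_spec <- function(shape = c(512L, 512L),
                       pixel_edge_um = 0.2421,
                       tumor_frac = 0.4,
                       counts = default_cell_counts(),
                       n_plasma = NULL,
                       fill = TRUE,
                       n_megakaryocytes = 1L,
                       cell_radius = 20,
                       nucleus_radius = 8,
                       grid_spacing = 48,
                       tumor_margin = 45,
                       grid_jitter = 3,
                       amplitudes = list(dapi = 3, af = 1, dim = 1,
                                         bright = 8, cd138_bright = 1,
                                         cd138_shed = 0.4),
                       bg_amplitude = 0.3,
                       noise_sd = 0.05,
                       gains = c(DAPI = 0.8, CD138 = 1.6, CD8 = 0.6,
                                 CD11b = 1.2, VISTA = 0.9, AF = 1.1)) {
  stopifnot(length(shape) == 2, all(shape >= 64), pixel_edge_um > 0,
            tumor_frac > 0, tumor_frac < 1,
            nucleus_radius < cell_radius,
            grid_spacing - 2 * grid_jitter > 2 * cell_radius)
  counts <- as.data.frame(counts)
  stopifnot(all(c("phenotype", "compartment", "n") %in% names(counts)))
  bad <- setdiff(counts$phenotype,
                 c("CD138", "CD8", "CD11b", "VISTA", "VISTA+CD11b", "none"))
  if (length(bad)) stop("unknown phenotype(s): ", paste(bad, collapse = ", "))
  stopifnot(all(counts$compartment %in% c("tumor", "stroma")),
            all(counts$n >= 0))
  structure(list(shape = as.integer(shape), pixel_edge_um = pixel_edge_um,
                 tumor_frac = tumor_frac, counts = counts,
                 n_plasma = n_plasma, fill = isTRUE(fill),
                 n_megakaryocytes = as.integer(n_megakaryocytes),
                 cell_radius = cell_radius, nucleus_radius = nucleus_radius,
                 grid_spacing = grid_spacing, tumor_margin = tumor_margin,
                 grid_jitter = grid_jitter,
                 amplitudes = amplitudes, bg_amplitude = bg_amplitude,
                 noise_sd = noise_sd, gains = gains),
            class = "image_spec")
}

#' @rdname image_spec
#' @export
default_cell_counts <- function() {
  data.frame(
    phenotype   = c("CD8", "CD8", "CD11b", "CD11b", "VISTA+CD11b",
                    "VISTA+CD11b", "VISTA"),
    compartment = c("tumor", "stroma", "tumor", "stroma", "tumor", "stroma",
                    "stroma"),
    n           = c(3L, 6L, 2L, 3L, 5L, 2L, 1L)
  )
}

marker_sets <- function() {
  list("CD138" = "CD138", "CD8" = "CD8", "CD11b" = "CD11b",
       "VISTA" = "VISTA", "VISTA+CD11b" = c("VISTA", "CD11b"),
       "none" = character(0), "megakaryocyte" = "VISTA")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# additive uniform disk centered at (r0, c0)
add_disk <- function(mat, r0, c0, radius, amp) {
  nr <- nrow(mat); nc <- ncol(mat)
  rs <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cs <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  mat[rs, cs] <- mat[rs, cs] + amp * (d2 <= radius^2)
  mat
}

# additive 2-D Gaussian truncated at 3 sigma
add_gaussian <- function(mat, r0, c0, sigma, amp) {
  nr <- nrow(mat); nc <- ncol(mat)
  rad <- 3 * sigma
  rs <- max(1L, floor(r0 - rad)):min(nr, ceiling(r0 + rad))
  cs <- max(1L, floor(c0 - rad)):min(nc, ceiling(c0 + rad))
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  g <- amp * exp(-d2 / (2 * sigma^2))
  g[d2 > rad^2] <- 0
  mat[rs, cs] <- mat[rs, cs] + g
  mat
}

# smooth wavy-boundary ellipse occupying the image center
make_tissue_mask <- function(shape) {
  nr <- shape[1]; nc <- shape[2]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  ar <- 0.42 * nr; ac <- 0.42 * nc
  ph <- runif(3, 0, 2 * pi)
  am <- runif(3, 0.02, 0.06)
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  theta <- atan2((r - cr) / ar, (c - cc) / ac)
  mod <- 1 + am[1] * sin(2 * theta + ph[1]) + am[2] * sin(3 * theta + ph[2]) +
    am[3] * sin(5 * theta + ph[3])
  ((r - cr) / ar)^2 + ((c - cc) / ac)^2 <= mod^2
}

# tumor = top `frac` quantile of a smoothed random field within tissue
make_tumor_mask <- function(tissue, frac, eroded = tissue, sigma = 30) {
  field <- matrix(rnorm(length(tissue)), nrow(tissue))
  sm <- EBImage::gblur(field, sigma = sigma)
  region <- tissue & eroded
  target <- min(frac * sum(tissue) / max(sum(region), 1), 0.95)
  thr <- stats::quantile(sm[region], 1 - target, names = FALSE)
  region & (sm > thr)
}

# jittered square-grid sites whose cell disk fits inside `inside_mask` and
# whose center lies in `center_mask`
grid_sites <- function(center_mask, inside_dist, spacing, jitter,
                       cell_radius) {
  nr <- nrow(center_mask); nc <- ncol(center_mask)
  r0 <- runif(1, 0, spacing); c0 <- runif(1, 0, spacing)
  rows <- seq(1 + r0, nr, by = spacing)
  cols <- seq(1 + c0, nc, by = spacing)
  pts <- expand.grid(row = rows, col = cols)
  valid <- function(p) {
    inb <- p$row >= 1 & p$row <= nr & p$col >= 1 & p$col <= nc
    ok <- inb
    ri <- pmin(pmax(round(p$row), 1L), nr)
    ci <- pmin(pmax(round(p$col), 1L), nc)
    ok[inb] <- center_mask[cbind(ri, ci)][inb] &
      inside_dist[cbind(ri, ci)][inb] > cell_radius
    ok
  }
  jit <- pts
  jit$row <- jit$row + runif(nrow(pts), -jitter, jitter)
  jit$col <- jit$col + runif(nrow(pts), -jitter, jitter)
  # a jittered site that leaves the mask reverts to its raw grid point, so
  # jitter never creates interior vacancies
  ok_j <- valid(jit)
  pts[ok_j, ] <- jit[ok_j, ]
  pts[valid(pts), , drop = FALSE]
}

#' Generate a ground-truthed synthetic multiplex image
#'
#' Renders the image described by an [image_spec()] and returns both the
#' multichannel raster and the exact ground truth (cell positions, marker
#' sets, compartments, tissue and tumor masks). Identical spec and seed give
#' bit-identical output.
#'
#' @param spec an [image_spec()].
#' @param seed integer seed; the generator neither reads nor disturbs the
#'   caller's RNG state.
#' @param region_id identifier stored in the image.
#' @return list with elements `image` (a [multiplex_image()]) and `truth`
#'   (class `image_ground_truth`: `cells` data.frame with `cell_id`, `row`,
#'   `col`, `phenotype`, `markers` (list column), radii, `compartment`,
#'   `is_megakaryocyte`; plus `tissue_mask`, `tumor_mask`, `shape`,
#'   `pixel_edge_um`, `seed`).
#' @export
generate_image <- function(spec, seed, region_id = "region1") {
  stopifnot(inherits(spec, "image_spec"))
  with_local_seed(seed, {
    nr <- spec$shape[1]; nc <- spec$shape[2]
    tissue <- make_tissue_mask(spec$shape)
    inside0 <- EBImage::distmap(tissue)
    tumor <- make_tumor_mask(tissue, spec$tumor_frac,
                             eroded = inside0 > spec$tumor_margin)
    stroma <- tissue & !tumor
    inside <- inside0

    sites <- grid_sites(tissue, inside, spec$grid_spacing,
                        spec$grid_jitter, spec$cell_radius)
    in_tum <- tumor[cbind(round(sites$row), round(sites$col))]
    tum_sites <- sites[in_tum, , drop = FALSE]
    str_sites <- sites[!in_tum, , drop = FALSE]

    cells <- data.frame(row = numeric(0), col = numeric(0),
                        phenotype = character(0))
    mk <- NULL
    if (spec$n_megakaryocytes > 0) {
      mk_radius <- 45
      clear <- mk_radius + spec$cell_radius
      at <- cbind(round(str_sites$row), round(str_sites$col))
      d_tum <- if (any(tumor)) EBImage::distmap(!tumor) else
        matrix(Inf, nr, nc)
      ok <- which(inside[at] > mk_radius)
      # prefer sites far from the tumor so the cleared footprint costs as
      # few tumor sites as possible
      ok <- ok[order(d_tum[at][ok], decreasing = TRUE)]
      if (length(ok) < spec$n_megakaryocytes) {
        stop("packing failure: cannot place ", spec$n_megakaryocytes,
             " megakaryocyte(s) of radius ", mk_radius,
             " px in the stroma; enlarge the image or tissue")
      }
      take <- ok[seq_len(spec$n_megakaryocytes)]
      mk <- data.frame(row = str_sites$row[take], col = str_sites$col[take],
                       phenotype = "megakaryocyte")
      # clear sites under the megakaryocyte footprint
      for (s in list(c("str_sites"), c("tum_sites"))) {
        ss <- get(s)
        if (!nrow(ss)) next
        d2 <- outer(ss$row, mk$row, "-")^2 + outer(ss$col, mk$col, "-")^2
        assign(s, ss[apply(d2, 1, min) >= clear^2, , drop = FALSE])
      }
      # ring of replacement sites just outside the cleared footprint, so the
      # vacancy never inflates a neighboring Voronoi region past the area
      # gate
      ring_r <- clear + 2
      for (m in seq_len(nrow(mk))) {
        ang <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = 8)[-8]
        ring <- data.frame(row = mk$row[m] + ring_r * sin(ang),
                           col = mk$col[m] + ring_r * cos(ang))
        ri <- round(ring$row); ci <- round(ring$col)
        okr <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
        okr[okr] <- tissue[cbind(ri, ci)][okr] &
          inside[cbind(ri, ci)][okr] > spec$cell_radius
        ring <- ring[okr, , drop = FALSE]
        all_sites <- rbind(tum_sites[c("row", "col")],
                           str_sites[c("row", "col")])
        for (k in seq_len(nrow(ring))) {
          d2 <- (all_sites$row - ring$row[k])^2 +
            (all_sites$col - ring$col[k])^2
          if (!length(d2) || min(d2) >= (2.1 * spec$cell_radius)^2) {
            in_t <- tumor[round(ring$row[k]), round(ring$col[k])]
            if (in_t) tum_sites <- rbind(tum_sites, ring[k, ])
            else str_sites <- rbind(str_sites, ring[k, ])
            all_sites <- rbind(all_sites, ring[k, c("row", "col")])
          }
        }
      }
    }

    # close grid vacancies (failed sites at the wavy tissue boundary, or
    # cleared megakaryocyte footprints): as long as some eligible pixel is
    # more than ~1.15 grid spacings from every site, plant a filler site at
    # the farthest such pixel, so no Voronoi region can outgrow the area gate
    eligible <- tissue & (inside > spec$cell_radius)
    el_idx <- which(eligible)
    if (length(el_idx)) {
      el_r <- (el_idx - 1L) %% nr + 1L
      el_c <- (el_idx - 1L) %/% nr + 1L
      all_r <- c(tum_sites$row, str_sites$row, if (!is.null(mk)) mk$row)
      all_c <- c(tum_sites$col, str_sites$col, if (!is.null(mk)) mk$col)
      gap_max <- 1.15 * spec$grid_spacing
      for (extra in 1:40) {
        d2min <- rep(Inf, length(el_idx))
        for (k in seq_along(all_r)) {
          d2min <- pmin(d2min, (el_r - all_r[k])^2 + (el_c - all_c[k])^2)
        }
        w <- which.max(d2min)
        if (d2min[w] <= gap_max^2) break
        new_site <- data.frame(row = as.numeric(el_r[w]),
                               col = as.numeric(el_c[w]))
        if (tumor[el_r[w], el_c[w]]) {
          tum_sites <- rbind(tum_sites, new_site)
        } else {
          str_sites <- rbind(str_sites, new_site)
        }
        all_r <- c(all_r, new_site$row); all_c <- c(all_c, new_site$col)
      }
    }

    # marker cells prefer sites away from the tumor/stroma boundary so
    # their ground-truth compartment is unambiguous under the smoothed
    # CD138 segmentation (cells at the frontier are ambiguous in any real
    # analysis); plasma and filler cells take any site
    d_tb <- EBImage::distmap(tumor) # distance to non-tumor
    d_ts <- if (any(tumor)) EBImage::distmap(!tumor) else
      matrix(Inf, nr, nc) # distance to tumor
    boundary_margin <- 1.2 * spec$cell_radius
    take_sites <- function(sites, n, what, compartment,
                           prefer_interior = FALSE) {
      if (n > nrow(sites)) {
        stop("packing failure: requested ", n, " ", what, " cells in the ",
             compartment, " but only ", nrow(sites),
             " grid sites remain at spacing ", spec$grid_spacing, " px")
      }
      pool <- seq_len(nrow(sites))
      if (prefer_interior && n > 0) {
        at <- cbind(round(sites$row), round(sites$col))
        dd <- if (compartment == "tumor") d_tb[at] else d_ts[at]
        interior <- which(dd > boundary_margin)
        if (length(interior) >= n) pool <- interior
      }
      idx <- if (n > 0) pool[sample.int(length(pool), n)] else integer(0)
      list(taken = sites[idx, , drop = FALSE],
           rest = if (n > 0) sites[-idx, , drop = FALSE] else sites)
    }

    for (i in seq_len(nrow(spec$counts))) {
      ph <- spec$counts$phenotype[i]
      cp <- spec$counts$compartment[i]
      n <- spec$counts$n[i]
      if (cp == "tumor") {
        got <- take_sites(tum_sites, n, ph, "tumor", prefer_interior = TRUE)
        tum_sites <- got$rest
      } else {
        got <- take_sites(str_sites, n, ph, "stroma", prefer_interior = TRUE)
        str_sites <- got$rest
      }
      if (n > 0) {
        cells <- rbind(cells, data.frame(row = got$taken$row,
                                         col = got$taken$col, phenotype = ph))
      }
    }
    n_plasma <- if (is.null(spec$n_plasma)) nrow(tum_sites) else spec$n_plasma
    got <- take_sites(tum_sites, n_plasma, "CD138", "tumor")
    tum_sites <- got$rest
    if (n_plasma > 0) {
      cells <- rbind(cells, data.frame(row = got$taken$row,
                                       col = got$taken$col,
                                       phenotype = "CD138"))
    }
    if (spec$fill) {
      rest <- rbind(tum_sites, str_sites)
      if (nrow(rest)) {
        cells <- rbind(cells, data.frame(row = rest$row, col = rest$col,
                                         phenotype = "none"))
      }
    }
    if (!is.null(mk)) cells <- rbind(cells, mk)

    is_mk <- cells$phenotype == "megakaryocyte"
    cells$cell_id <- seq_len(nrow(cells))
    cells$nucleus_radius <- ifelse(is_mk, 28, spec$nucleus_radius)
    cells$cell_radius <- ifelse(is_mk, 45, spec$cell_radius)
    cells$is_megakaryocyte <- is_mk
    cells$compartment <- ifelse(tumor[cbind(round(cells$row),
                                            round(cells$col))],
                                "tumor", "stroma")
    sets <- marker_sets()
    cells$markers <- I(unname(sets[cells$phenotype]))

    # ---- render channels (design units) ----
    zero <- matrix(0, nr, nc)
    ch <- list(DAPI = zero, CD138 = zero, CD8 = zero, CD11b = zero,
               VISTA = zero, AF = zero)
    amp <- spec$amplitudes
    ch$AF <- amp$af * tissue
    for (i in seq_len(nrow(cells))) {
      r0 <- cells$row[i]; c0 <- cells$col[i]
      ch$DAPI <- add_gaussian(ch$DAPI, r0, c0, cells$nucleus_radius[i] / 2,
                              amp$dapi)
      mk_cell <- cells$is_megakaryocyte[i]
      rad <- cells$cell_radius[i]
      mks <- cells$markers[[i]]
      for (m in c("CD8", "CD11b", "VISTA")) {
        a <- if (m %in% mks) amp$bright else amp$dim
        if (mk_cell) a <- if (m %in% mks) amp$bright else 0
        if (a > 0) ch[[m]] <- add_disk(ch[[m]], r0, c0, rad, a)
      }
      if ("CD138" %in% mks && !mk_cell) {
        # membrane disk plus a brighter nucleus-proximal core, so the mean
        # stays above threshold even when a Voronoi region runs large
        ch$CD138 <- add_disk(ch$CD138, r0, c0, rad, amp$cd138_bright)
        ch$CD138 <- add_disk(ch$CD138, r0, c0, 0.6 * rad,
                             3 * amp$cd138_bright)
      } else if (!mk_cell && cells$compartment[i] == "tumor" &&
                 !is.null(amp$cd138_shed) && amp$cd138_shed > 0) {
        # shed CD138 on non-plasma tumor cells: keeps the smoothed tumor
        # mask contiguous across their regions
        ch$CD138 <- add_disk(ch$CD138, r0, c0, rad, amp$cd138_shed)
      }
    }

    # smooth quadratic background field scaled to [0, bg_amplitude]
    if (spec$bg_amplitude > 0) {
      u <- matrix(seq(-1, 1, length.out = nr), nr, nc)
      v <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
      co <- runif(6, -1, 1)
      bg <- co[1] + co[2] * u + co[3] * v + co[4] * u^2 + co[5] * u * v +
        co[6] * v^2
      bg <- (bg - min(bg)) / max(max(bg) - min(bg), .Machine$double.eps)
      bg <- spec$bg_amplitude * bg
    } else bg <- zero

    for (nm in names(ch)) {
      x <- ch[[nm]] + bg
      if (spec$noise_sd > 0) x <- x + rnorm(length(x), 0, spec$noise_sd)
      g <- if (nm %in% names(spec$gains)) spec$gains[[nm]] else 1
      ch[[nm]] <- pmax(x * g, 0)
    }

    truth <- structure(
      list(cells = cells[, c("cell_id", "row", "col", "phenotype", "markers",
                             "nucleus_radius", "cell_radius", "compartment",
                             "is_megakaryocyte")],
           tissue_mask = tissue, tumor_mask = tumor, shape = spec$shape,
           pixel_edge_um = spec$pixel_edge_um, seed = seed),
      class = "image_ground_truth")
    list(image = multiplex_image(ch, spec$pixel_edge_um, region_id),
         truth = truth)
  })
}

#' @export
print.image_ground_truth <- function(x, ...) {
  cat("<image_ground_truth>", nrow(x$cells), "cells on a", x$shape[1], "x",
      x$shape[2], "px image; tumor fraction of tissue:",
      round(sum(x$tumor_mask) / max(sum(x$tissue_mask), 1), 2), "\n")
  tab <- table(x$cells$phenotype, x$cells$compartment)
  print(tab)
  invisible(x)
}
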