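# construct a synthetic segmentation directly: label blocks with known mean
# intensities, so threshold semantics are tested in isolation
block_setup <- function(vals, areas = rep(900, length(vals[[1]]))) {
  # vals: named list of per-cell channel means; cells laid out as blocks
  n_cells <- length(vals[[1]])
  side <- ceiling(sqrt(areas))
  dim_px <- 300
  labels <- matrix(0L, dim_px, dim_px)
  nuclei <- matrix(0L, dim_px, dim_px)
  channels <- lapply(vals, function(v) matrix(0, dim_px, dim_px))
  r0 <- 5
  for (i in seq_len(n_cells)) {
    rows <- r0:(r0 + side[i] - 1)
    cols <- 5:(5 + ceiling(areas[i] / side[i]) - 1)
    sel <- cbind(rep(rows, length(cols)), rep(cols, each = length(rows)))
    sel <- sel[seq_len(areas[i]), , drop = FALSE]
    labels[sel] <- i
    nuclei[sel[1:25, , drop = FALSE]] <- i
    for (nm in names(vals)) channels[[nm]][sel] <- vals[[nm]][i]
    r0 <- r0 + side[i] + 5
  }
  norm <- multiplex_image(channels)
  seg <- list(tumor = matrix(TRUE, dim_px, dim_px),
              stroma = matrix(FALSE, dim_px, dim_px),
              nucleus_labels = nuclei)
  list(labels = labels, norm = norm, seg = seg)
}

test_that("marker positivity follows the per-channel thresholds", {
  s <- block_setup(list(DAPI = c(1, 1, 1),
                        CD138 = c(0.6, 0, 0.2),
                        CD8 = c(0, 0.2, 1.4),
                        CD11b = c(0, 1.6, 1.6),
                        VISTA = c(0, 1.6, 1.51)))
  cells <- phenotype_cells(s$labels, s$norm, s$seg)
  expect_equal(nrow(cells), 3L)
  # cell 1: mean CD138 = 0.6 > 0.5, everything else off
  expect_true(cells$pos_CD138[1]); expect_false(cells$pos_CD8[1])
  # cell 2: VISTA and CD11b at 1.6 > 1.5, CD8 at 0.2 below
  expect_true(cells$pos_VISTA[2]); expect_true(cells$pos_CD11b[2])
  expect_false(cells$pos_CD8[2])
  # thresholds are strict: 1.4 fails, 1.51 passes
  expect_false(cells$pos_CD8[3]); expect_true(cells$pos_VISTA[3])
})

test_that("the cell area gate is a closed interval", {
  s <- block_setup(list(DAPI = c(1, 1, 1, 1), CD138 = c(0.6, 0.6, 0.6, 0.6),
                        CD8 = c(0, 0, 0, 0), CD11b = c(0, 0, 0, 0),
                        VISTA = c(0, 0, 0, 0)),
                   areas = c(400, 500, 5000, 5200))
  cells <- phenotype_cells(s$labels, s$norm, s$seg)
  expect_setequal(cells$cell_id, c(2L, 3L)) # 400 and 5200 dropped
})

test_that("megakaryocyte exclusion removes only large VISTA+ regions", {
  s <- block_setup(list(DAPI = c(1, 1, 1), CD138 = c(0, 0, 0),
                        CD8 = c(0, 0, 0), CD11b = c(0, 0, 0),
                        VISTA = c(2, 0.2, 2)),
                   areas = c(8000, 8000, 3000))
  expect_message(cells <- phenotype_cells(s$labels, s$norm, s$seg),
                 "megakaryocyte")
  # VISTA+ 8000 px^2 removed and flagged; VISTA- 8000 dropped by the general
  # gate but not flagged; VISTA+ 3000 retained
  expect_equal(attr(cells, "n_megakaryocytes"), 1L)
  expect_equal(cells$cell_id, 3L)
  expect_true(cells$pos_VISTA[1])
})

test_that("raising gates or thresholds never increases counts", {
  g <- generate_image(small_image_spec(), seed = 19)
  r <- suppressMessages(process_region(g$image))
  n0 <- nrow(r$cells)
  p2 <- pipeline_params(cell_area_min_px2 = 1500)
  cells2 <- phenotype_cells(r$seg$cell_labels, r$norm, r$seg, p2)
  expect_lte(nrow(cells2), n0)
  p3 <- pipeline_params(phenotype_thresholds = c(CD138 = 0.5, CD8 = 3,
                                                 CD11b = 1.5, VISTA = 1.5))
  cells3 <- phenotype_cells(r$seg$cell_labels, r$norm, r$seg, p3)
  expect_lte(sum(cells3$pos_CD8), sum(r$cells$pos_CD8))
})

test_that("phenotype recovery meets its bounds on synthetic images", {
  # noiseless, non-touching cells: exact recovery
  g0 <- generate_image(image_spec(noise_sd = 0, bg_amplitude = 0.2),
                       seed = 29)
  r0 <- suppressMessages(process_region(g0$image))
  expect_equal(phenotype_recovery(g0$truth, r0$cells), 1)
  # default noise: at least 95%
  g1 <- generate_image(image_spec(), seed = 31)
  r1 <- suppressMessages(process_region(g1$image))
  expect_gte(phenotype_recovery(g1$truth, r1$cells), 0.95)
  # the planted megakaryocyte is excluded
  expect_gte(attr(r1$cells, "n_megakaryocytes"), 1L)
})
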