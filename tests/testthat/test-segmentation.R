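zero_channels <- function(n = 200) {
  z <- matrix(0, n, n)
  list(DAPI = z, CD138 = z, CD8 = z, CD11b = z, VISTA = z)
}

# build an already-normalized image (bypassing normalize_image) for
# threshold-level tests
as_norm <- function(channels, ...) multiplex_image(channels, ...)

test_that("foreground detection applies threshold and size filter", {
  p <- pipeline_params()
  # all channels zero: empty mask
  img <- as_norm(zero_channels())
  expect_false(any(detect_foreground(img, p)))
  # one channel at 0.3 everywhere on 200x200: whole image (40000 > 5000)
  ch <- zero_channels()
  ch$CD8 <- matrix(0.3, 200, 200)
  expect_true(all(detect_foreground(as_norm(ch), p)))
  # a 60x60 blob at 0.5 (3600 px^2 <= 5000) is removed
  ch <- zero_channels()
  ch$CD8[50:109, 50:109] <- 0.5
  expect_false(any(detect_foreground(as_norm(ch), p)))
  # a blob just over the limit survives: 71x71 = 5041 > 5000
  ch <- zero_channels()
  ch$CD8[50:120, 50:120] <- 0.5
  expect_equal(sum(detect_foreground(as_norm(ch), p)), 71L * 71L)
})

test_that("tissue segmentation partitions foreground into tumor and stroma", {
  p <- pipeline_params()
  ch <- zero_channels()
  ch$CD138[, 1:100] <- 1 # left half CD138-bright
  ch$CD8 <- matrix(0.3, 200, 200) # everything foreground
  img <- as_norm(ch)
  fg <- detect_foreground(img, p)
  tis <- segment_tissue(img, fg, p)
  # partition invariants
  expect_false(any(tis$tumor & tis$stroma))
  expect_true(all((tis$tumor | tis$stroma) == fg))
  # boundary within 3 sigma of the true split at column 100
  tumor_cols <- which(apply(tis$tumor, 2, any))
  expect_lt(abs(max(tumor_cols) - 100), 3 * p$tissue_gaussian_sigma_px)
  expect_true(all(tis$tumor[, 1:70]))
  expect_true(all(tis$stroma[, 130:200]))
})

test_that("tissue segmentation handles the saturated and empty CD138 cases", {
  p <- pipeline_params()
  ch <- zero_channels()
  ch$CD8 <- matrix(0.3, 200, 200)
  img0 <- as_norm(ch)
  fg <- detect_foreground(img0, p)
  tis0 <- segment_tissue(img0, fg, p)
  expect_false(any(tis0$tumor))
  expect_true(all(tis0$stroma == fg))
  ch$CD138 <- matrix(1, 200, 200)
  img1 <- as_norm(ch)
  tis1 <- segment_tissue(img1, fg, p)
  expect_true(all(tis1$tumor == fg))
  expect_false(any(tis1$stroma))
})

test_that("small tumor islands are reassigned so the partition stays total", {
  p <- pipeline_params()
  ch <- zero_channels()
  ch$CD8 <- matrix(0.3, 200, 200)
  ch$CD138[90:110, 90:110] <- 5 # smoothed island stays well under 5000 px^2
  img <- as_norm(ch)
  fg <- detect_foreground(img, p)
  tis <- segment_tissue(img, fg, p)
  expect_false(any(tis$tumor))
  expect_true(all((tis$tumor | tis$stroma) == fg))
})

test_that("nucleus segmentation finds isolated and paired nuclei", {
  p <- pipeline_params()
  # one synthetic Gaussian nucleus
  d <- matrix(0, 128, 128)
  d <- vistamm:::add_gaussian(d, 64.3, 60.7, sigma = 4, amp = 3)
  lab <- segment_nuclei(d, p)
  expect_equal(max(lab), 1L)
  cent <- which(lab == 1, arr.ind = TRUE)
  expect_lt(sqrt((mean(cent[, 1]) - 64.3)^2 + (mean(cent[, 2]) - 60.7)^2), 2)
  # two nuclei 30 px apart, radius 8
  d2 <- matrix(0, 128, 128)
  d2 <- vistamm:::add_gaussian(d2, 50, 64, sigma = 4, amp = 3)
  d2 <- vistamm:::add_gaussian(d2, 80, 64, sigma = 4, amp = 3)
  expect_equal(max(segment_nuclei(d2, p)), 2L)
  # blank image
  expect_warning(lab0 <- segment_nuclei(matrix(0, 64, 64), p), "blank")
  expect_equal(max(lab0), 0L)
})

test_that("the watershed splits touching nuclei", {
  p <- pipeline_params(min_nucleus_area_px2 = 20)
  d <- matrix(0, 128, 128)
  d <- vistamm:::add_gaussian(d, 60, 64, sigma = 4, amp = 3)
  d <- vistamm:::add_gaussian(d, 74, 64, sigma = 4, amp = 3)
  lab <- segment_nuclei(d, p)
  expect_equal(max(lab), 2L)
})

test_that("Voronoi assignment covers single-seed and bisector cases", {
  # one nucleus, full foreground
  nuc <- matrix(0L, 40, 40); nuc[20, 20] <- 1L
  fg <- matrix(TRUE, 40, 40)
  cells <- segment_cells(nuc, fg)
  expect_true(all(cells == 1L))
  # two point seeds: perpendicular bisector between columns 10 and 20
  nuc2 <- matrix(0L, 21, 31); nuc2[11, 10] <- 1L; nuc2[11, 20] <- 2L
  cells2 <- segment_cells(nuc2, matrix(TRUE, 21, 31))
  expect_true(all(cells2[, 1:14] == 1L))
  expect_true(all(cells2[, 16:31] == 2L))
  # equidistant column 15 goes to the lower label
  expect_true(all(cells2[, 15] == 1L))
})

test_that("Voronoi assignment equals the brute-force nearest-seed oracle", {
  set.seed(42)
  for (rep in 1:3) {
    nuc <- matrix(0L, 64, 64)
    n_seed <- sample(3:8, 1)
    pos <- cbind(sample(5:60, n_seed), sample(5:60, n_seed))
    for (s in seq_len(n_seed)) {
      rr <- pos[s, 1] + (-2:2); cc <- pos[s, 2] + (-2:2)
      nuc[rr, cc][outer(-2:2, -2:2, function(a, b) a^2 + b^2) <= 4] <- s
    }
    fg <- matrix(runif(64 * 64) < 0.7, 64, 64)
    expect_identical(segment_cells(nuc, fg), oracle_nearest_seed(nuc, fg))
  }
})

test_that("no nuclei with nonempty foreground yields an empty mask and warning", {
  fg <- matrix(TRUE, 20, 20)
  expect_warning(cells <- segment_cells(matrix(0L, 20, 20), fg), "no nuclei")
  expect_true(all(cells == 0L))
})

test_that("the full pipeline is deterministic and label-bijective", {
  g <- generate_image(small_image_spec(), seed = 13)
  r1 <- suppressMessages(process_region(g$image))
  r2 <- suppressMessages(process_region(g$image))
  expect_identical(r1$seg$cell_labels, r2$seg$cell_labels)
  expect_identical(r1$cells, r2$cells)
  # partition invariant on a processed image
  expect_false(any(r1$seg$tumor & r1$seg$stroma))
  expect_true(all((r1$seg$tumor | r1$seg$stroma) == r1$seg$foreground))
  # cell labels bijective with nucleus labels
  expect_setequal(unique(as.integer(r1$seg$cell_labels)),
                  unique(as.integer(r1$seg$nucleus_labels)))
})
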