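# minimal hand-built cell tables and segmentations
cells_df <- function(...) {
  df <- data.frame(...)
  for (m in c("CD138", "CD8", "CD11b", "VISTA")) {
    col <- paste0("pos_", m)
    if (!col %in% names(df)) df[[col]] <- FALSE
  }
  df
}

mask_mm2 <- function(n_px, pixel_edge_um = 0.2421) {
  n_px * (pixel_edge_um / 1000)^2
}

test_that("densities follow their definition and handle empty compartments", {
  # 1 mm^2 tumor at 1 um pixels = 1000x1000 px
  seg <- list(tumor = matrix(TRUE, 1000, 1000),
              stroma = matrix(FALSE, 1000, 1000))
  cells <- cells_df(compartment = rep("tumor", 10), pos_CD8 = TRUE)
  expect_message(d <- compute_densities(cells, seg, pixel_edge_um = 1),
                 "zero-area")
  expect_equal(d$density[d$phenotype == "CD8" & d$compartment == "tumor"], 10)
  expect_true(is.na(d$density[d$phenotype == "CD8" &
                                d$compartment == "stroma"]))
  # zero cells in a nonempty compartment is density 0
  expect_equal(d$density[d$phenotype == "CD138" & d$compartment == "tumor"], 0)
})

test_that("density times area sums back to assigned cell counts", {
  g <- generate_image(small_image_spec(), seed = 23)
  r <- suppressMessages(process_region(g$image))
  d <- suppressMessages(compute_densities(r$cells, r$seg,
                                          g$image$pixel_edge_um))
  for (ph in unique(d$phenotype)) {
    sub <- d[d$phenotype == ph & !is.na(d$density), ]
    n_assigned <- sum(cells_with_phenotype(r$cells, ph) &
                        !is.na(r$cells$compartment) &
                        r$cells$compartment %in% sub$compartment)
    expect_equal(sum(sub$density * sub$area_mm2), n_assigned,
                 tolerance = 1e-8)
  }
})

test_that("nearest-neighbor distances match hand values and the oracle", {
  # 3-4-5 triangle: distance 5 px = 1.2105 um at the default pixel edge
  cells <- cells_df(compartment = c("tumor", "tumor"),
                    centroid_row = c(0, 3), centroid_col = c(0, 4),
                    pos_CD8 = c(TRUE, FALSE), pos_CD11b = c(FALSE, TRUE))
  expect_equal(mean_nn_distance(cells, "CD8", "CD11b", "tumor"),
               5 * 0.2421, tolerance = 1e-12)
  # single cell, same phenotype: self excluded, undefined
  solo <- cells_df(compartment = "tumor", centroid_row = 1, centroid_col = 1,
                   pos_CD8 = TRUE)
  expect_message(v <- mean_nn_distance(solo, "CD8", "CD8", "tumor"),
                 "no valid neighbor")
  expect_true(is.na(v))
  # 30 random cells vs the all-pairs oracle
  set.seed(7)
  n <- 30
  cl <- cells_df(compartment = rep("stroma", n),
                 centroid_row = runif(n, 0, 500),
                 centroid_col = runif(n, 0, 500),
                 pos_CD8 = rep(c(TRUE, FALSE), length.out = n),
                 pos_VISTA = rep(c(FALSE, TRUE), length.out = n),
                 pos_CD11b = rep(c(FALSE, TRUE), length.out = n))
  got <- mean_nn_distance(cl, "CD8", "VISTA+CD11b", "stroma",
                          pixel_edge_um = 1)
  src <- which(cl$pos_CD8)
  tgt <- which(cl$pos_VISTA & cl$pos_CD11b)
  want <- oracle_mean_nn(as.matrix(cl[src, c("centroid_row", "centroid_col")]),
                         as.matrix(cl[tgt, c("centroid_row", "centroid_col")]))
  expect_equal(got, want, tolerance = 1e-12)
})

dens_table <- function(vc_t, vc_s, cd8_t, cd8_s) {
  data.frame(phenotype = rep(c("VISTA+CD11b", "CD8"), each = 2),
             compartment = rep(c("tumor", "stroma"), 2),
             density = c(vc_t, vc_s, cd8_t, cd8_s))
}

test_that("preferential localization and the exclusion score follow the formula", {
  d <- dens_table(10, 5, 2, 8)
  expect_equal(preferential_localization(d, "VISTA+CD11b", eps = 0), 2)
  expect_equal(preferential_localization(d, "CD8", eps = 0), 0.25)
  # (10/5) x (8/2) = 8
  expect_equal(exclusion_score(d, eps = 0), 8)
  # all equal densities: neutral score 1
  expect_equal(exclusion_score(dens_table(3, 3, 3, 3), eps = 0), 1)
  # documented pseudocount behavior
  d0 <- dens_table(0, 8, 1, 1)
  expect_equal(preferential_localization(d0, "VISTA+CD11b", eps = 0.1),
               0.1 / 8.1)
})

test_that("the exclusion score is scale invariant and antisymmetric", {
  d <- dens_table(12, 3, 1.5, 9)
  s <- exclusion_score(d, eps = 0)
  d3 <- d; d3$density <- d3$density * 3
  expect_equal(exclusion_score(d3, eps = 0), s, tolerance = 1e-12)
  # with a pseudocount the invariance is approximate
  expect_equal(exclusion_score(d3, eps = 0.1), exclusion_score(d, eps = 0.1),
               tolerance = 0.15)
  # swapping compartments inverts the score
  dsw <- dens_table(3, 12, 9, 1.5)
  expect_equal(exclusion_score(dsw, eps = 0), 1 / s, tolerance = 1e-12)
})

test_that("missing constituents make the score missing", {
  d <- dens_table(NA, 3, 1, 1)
  expect_true(is.na(exclusion_score(d)))
})

test_that("patient profiles average regions before forming ratios", {
  g1 <- generate_image(small_image_spec(), seed = 41, region_id = "r1")
  g2 <- generate_image(small_image_spec(), seed = 43, region_id = "r2")
  rr <- suppressMessages(lapply(list(g1$image, g2$image), process_region))
  prof <- suppressMessages(patient_spatial_profile(rr, "pt01"))
  expect_s3_class(prof, "patient_spatial_profile")
  d1 <- suppressMessages(compute_densities(rr[[1]]$cells, rr[[1]]$seg))
  d2 <- suppressMessages(compute_densities(rr[[2]]$cells, rr[[2]]$seg))
  avg <- rowMeans(cbind(d1$density, d2$density), na.rm = TRUE)
  expect_equal(prof$density$density, ifelse(is.nan(avg), NA_real_, avg))
  # score computed from the averaged densities
  expect_equal(prof$exclusion_score, exclusion_score(prof$density))
})
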