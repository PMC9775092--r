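test_that("extract_regions reports labels, centroids and border flags", {
  m <- matrix(0L, 30, 40)
  m[5:10, 5:10] <- 1L
  m[15:20, 20:30] <- 2L
  m[1:4, 35:39] <- 3L  # touches row 1
  r <- extract_regions(m)
  expect_equal(r$region_id, 1:3)
  expect_equal(r$border, c(FALSE, FALSE, TRUE))
  expect_equal(r$n_pixels[1], 36L)
  expect_equal(r$centroid_x[2], 25)
  expect_equal(r$centroid_y[2], 17.5)
  # border region excluded from measurement by default
  expect_equal(measure_mask(m)$cell_id, 1:2)
  # empty mask: empty tibble, not an error
  expect_equal(nrow(extract_regions(matrix(0L, 5, 5))), 0)
  expect_error(extract_regions(matrix(0.5, 3, 3)), "integer")
})

test_that("circle fixed point: descriptors and CII match closed forms", {
  m <- rasterize_ellipse(40)
  got <- measure_mask(m)
  expect_lt(abs(got$area - pi * 1600) / (pi * 1600), 0.01)
  expect_lt(abs(got$aspect - 1), 0.03)
  expect_lt(abs(got$area_box - pi / 4) / (pi / 4), 0.03)
  expect_lt(abs(got$roundness - 1), 0.03)
  expect_lt(abs(got$radius_ratio - 1), 0.03)
  expect_lt(abs(got$cii - (3 - pi / 4)) / (3 - pi / 4), 0.03)
})

test_that("2:1 ellipse: aspect and area/box match the moments oracle", {
  got <- measure_mask(rasterize_ellipse(60, 30))
  expect_lt(abs(got$aspect - 2) / 2, 0.05)
  expect_lt(abs(got$area_box - pi / 4) / (pi / 4), 0.05)
  expect_lt(abs(got$radius_ratio - 2) / 2, 0.05)
})

test_that("compute_cii is the printed formula with its sign structure", {
  expect_equal(compute_cii(1, pi / 4, 1, 1), 3 - pi / 4)
  expect_equal(compute_cii(2, 0.5, 3, 4), 8.5)
  base <- compute_cii(1.2, 0.7, 1.1, 1.3)
  expect_gt(compute_cii(1.3, 0.7, 1.1, 1.3), base)
  expect_gt(compute_cii(1.2, 0.7, 1.2, 1.3), base)
  expect_gt(compute_cii(1.2, 0.7, 1.1, 1.4), base)
  expect_lt(compute_cii(1.2, 0.8, 1.1, 1.3), base)
  expect_error(compute_cii(Inf, 0.7, 1, 1), "finite")
})

test_that("cii column is recomputable from the descriptor columns", {
  fld <- render_field(sample_cell_truth(
    cell_population_spec(c(N = 0.5, I = 0.5), 60, seed = 11)))
  cells <- measure_mask(fld)
  expect_equal(cells$cii,
               compute_cii(cells$aspect, cells$area_box, cells$roundness,
                           cells$radius_ratio),
               tolerance = 1e-12)
  expect_true(all(cells$aspect >= 1))
  expect_true(all(cells$area_box > 0 & cells$area_box <= 1))
  expect_true(all(cells$radius_ratio >= 1))
})

test_that("degenerate and undersized regions are handled", {
  line <- matrix(0L, 30, 30)
  line[10, 3:28] <- 1L
  expect_error(suppressMessages(measure_cells(line, min_pixels = 10)),
               "degenerate")
  small <- matrix(0L, 20, 20)
  small[5:6, 5:6] <- 1L
  expect_message(out <- measure_cells(small), "below")
  expect_equal(nrow(out), 0)
})

test_that("thresholds come from control quantiles", {
  # degenerate control population pins all gates to the shared value
  ctrl <- tibble::tibble(area = rep(100, 30), cii = rep(2.2, 30))
  thr <- suppressWarnings(derive_thresholds(ctrl))
  expect_equal(thr$area_low, 100)
  expect_equal(thr$area_high, 100)
  expect_equal(thr$cii_high, 2.2)

  set.seed(42)
  ctrl <- tibble::tibble(area = rnorm(1000, 300, 40),
                         cii = rnorm(1000, 2.3, 0.15))
  thr <- derive_thresholds(ctrl)
  # Gaussian quantile oracle: 300 - 1.645 * 40 = 234.2
  expect_lt(abs(thr$area_low - 234.2) / 234.2, 0.03)
  expect_lt(abs(thr$area_high - 365.8) / 365.8, 0.03)
  # widening the quantile config widens the band monotonically
  thr2 <- derive_thresholds(ctrl, area_quantiles = c(0.025, 0.975),
                            cii_quantile = 0.975)
  expect_lt(thr2$area_low, thr$area_low)
  expect_gt(thr2$area_high, thr$area_high)
  expect_gt(thr2$cii_high, thr$cii_high)
  expect_error(derive_thresholds(ctrl[1:10, ]), ">= 20")
})

test_that("classification is exhaustive with non-extreme tie handling", {
  thr <- structure(list(area_low = 100, area_high = 300, cii_high = 2.5,
                        source = list()), class = "morph_thresholds")
  cells <- tidyr::expand_grid(area = c(50, 100, 200, 300, 400),
                              cii = c(2, 2.5, 3))
  got <- classify_cells(cells, thr)
  expect_false(any(is.na(got$class)))
  # boundary values classify as the non-extreme side
  expect_equal(as.character(got$class[got$area == 100 & got$cii == 2.5]), "N")
  expect_equal(as.character(got$class[got$area == 300 & got$cii == 2.5]), "N")
  expect_equal(as.character(got$class[got$area == 400 & got$cii == 3]), "HI")
  expect_equal(as.character(got$class[got$area == 50 & got$cii == 2]), "AR")
  expect_equal(as.character(got$class[got$area == 200 & got$cii == 3]), "I")
  # exhaustive over random planes
  set.seed(7)
  rnd <- tibble::tibble(area = runif(500, 0, 600), cii = runif(500, 1, 4))
  expect_false(any(is.na(classify_cells(rnd, thr)$class)))
})

test_that("population profile closes to 100% and tracks variability", {
  thr <- structure(list(area_low = 100, area_high = 300, cii_high = 2.5,
                        source = list()), class = "morph_thresholds")
  cells <- classify_cells(
    tibble::tibble(area = rep(200, 50), cii = rep(2, 50)), thr)
  prof <- population_profile(cells)
  expect_equal(prof$percent_N, 100)
  expect_equal(prof$area_variability, 0)
  expect_equal(sum(as.numeric(prof[paste0("percent_",
                                          morph_class_levels())])), 100)

  set.seed(3)
  mixed <- classify_cells(tibble::tibble(area = runif(200, 0, 500),
                                         cii = runif(200, 1.5, 3.5)), thr)
  prof2 <- population_profile(mixed)
  expect_equal(sum(as.numeric(prof2[paste0("percent_",
                                           morph_class_levels())])), 100,
               tolerance = 1e-9)
  expect_warning(population_profile(mixed[1:10, ]), "protocol")
  expect_error(population_profile(mixed[0, ]), "zero")
})

test_that("descriptors are scale- and rotation-robust", {
  m <- rasterize_ellipse(45, 30, theta = 0.4)
  v1 <- measure_mask(m)
  v2 <- measure_mask(upscale2(m))
  for (d in c("aspect", "area_box", "roundness", "radius_ratio")) {
    expect_lt(abs(v2[[d]] - v1[[d]]) / v1[[d]], 0.02)
  }
  expect_lt(abs(v2$area / v1$area - 4) / 4, 0.02)

  sweep <- purrr::map(seq(0, pi / 2, length.out = 7), function(th) {
    measure_mask(rasterize_ellipse(60, 30, theta = th))
  }) |> dplyr::bind_rows()
  for (d in c("aspect", "area_box", "roundness", "radius_ratio")) {
    expect_lt(diff(range(sweep[[d]])) / mean(sweep[[d]]), 0.05)
  }
})

test_that("control population classified against its own gates retains the design rates", {
  fld <- render_field(sample_cell_truth(
    cell_population_spec(c(N = 1), 800, seed = 19)))
  ctrl <- measure_mask(fld, pixel_size = 0.4)
  thr <- derive_thresholds(ctrl)
  cc <- classify_cells(ctrl, thr)
  size_normal <- mean(cc$class %in% c("N", "I")) * 100
  shape_regular <- mean(cc$class %in% c("N", "HR", "AR")) * 100
  # 5/95 area gates keep ~90% size-normal; 95 CII gate ~95% regular
  expect_lt(abs(size_normal - 90), 3)
  expect_lt(abs(shape_regular - 95), 3)
})
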