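test_that("population spec validates mixtures, areas and seeds", {
  expect_error(cell_population_spec(c(N = 0.6, HR = 0.3), 10, seed = 1),
               "sum to 1")
  expect_error(cell_population_spec(c(0.5, 0.5), 10, seed = 1), "named")
  bad <- morph_class_params()
  bad$area_mean[1] <- -5
  expect_error(cell_population_spec(c(N = 1), 10, seed = 1,
                                    class_params = bad), "positive")
  expect_error(cell_population_spec(c(N = 1), 0, seed = 1))
  expect_error(cell_population_spec(c(N = 1), 10, seed = NULL), "seed")
  expect_error(sample_cell_truth(cell_population_spec(c(Z = 1), 10, seed = 1)),
               "without parameters")
})

test_that("degenerate mixture yields a single class; counts are multinomial", {
  tr <- sample_cell_truth(cell_population_spec(c(N = 1), 50, seed = 1))
  expect_equal(nrow(tr), 50)
  expect_true(all(tr$class == "N"))

  spec <- cell_population_spec(c(N = 0.7, HR = 0.2, AR = 0.1), 10000, seed = 7)
  tr <- sample_cell_truth(spec)
  freq <- as.numeric(table(factor(tr$class, c("N", "HR", "AR")))) / 100
  # binomial 99% half-widths at n = 1e4: ~1.2 points; spec allows 1.5
  expect_true(all(abs(freq - c(70, 20, 10)) < 1.5))
})

test_that("generation is seed-deterministic and seed-sensitive", {
  spec7 <- cell_population_spec(c(N = 0.8, HR = 0.2), 80, seed = 7)
  tr_a <- sample_cell_truth(spec7)
  tr_b <- sample_cell_truth(spec7)
  expect_identical(tr_a, tr_b)
  f_a <- render_field(tr_a)
  f_b <- render_field(tr_b)
  expect_identical(f_a$image, f_b$image)
  expect_identical(f_a$mask, f_b$mask)

  tr_c <- sample_cell_truth(cell_population_spec(c(N = 0.8, HR = 0.2), 80,
                                                 seed = 8))
  expect_false(identical(tr_a$center_x, tr_c$center_x))
})

test_that("rendered masks honour the per-cell truth", {
  spec <- cell_population_spec(c(N = 1), 40, seed = 3, pixel_size = 0.4)
  tr <- sample_cell_truth(spec)
  fld <- render_field(tr)
  areas_px <- as.numeric(table(factor(fld$mask[fld$mask > 0], tr$cell_id)))
  expect_true(all(abs(areas_px - tr$nominal_area / 0.4^2) /
                    (tr$nominal_area / 0.4^2) < 0.05))
  # label k exactly covers cell k: every truth id present, nothing else
  expect_setequal(unique(as.vector(fld$mask)), c(0L, tr$cell_id))
})

test_that("rendered elongation matches truth within 10%", {
  params <- morph_class_params()
  params$elong_mean[params$class == "N"] <- 2
  params$elong_sd[params$class == "N"] <- 0
  params$boundary_noise[params$class == "N"] <- 0
  params$area_sd[params$class == "N"] <- 0
  spec <- cell_population_spec(c(N = 1), 15, seed = 5, class_params = params,
                               pixel_size = 0.4)
  fld <- render_field(sample_cell_truth(spec))
  cells <- measure_mask(fld, pixel_size = 0.4)
  expect_true(all(abs(cells$aspect - 2) / 2 < 0.1))
})

test_that("a single circular truth renders with the right area", {
  tr <- tibble::tibble(cell_id = 1L, class = "N", center_x = 40, center_y = 40,
                       nominal_area = pi * 30^2, elongation = 1,
                       boundary_noise = 0, orientation = 0)
  attr(tr, "field_dim") <- c(80L, 80L)
  attr(tr, "pixel_size") <- 1
  fld <- render_field(tr)
  expect_lt(abs(sum(fld$mask == 1L) - pi * 900) / (pi * 900), 0.03)
})

test_that("empty truth set renders a blank field", {
  tr <- sample_cell_truth(cell_population_spec(c(N = 1), 5, seed = 1))[0, ]
  attr(tr, "field_dim") <- c(50L, 50L)
  attr(tr, "pixel_size") <- 1
  fld <- render_field(tr)
  expect_true(all(fld$mask == 0L))
  expect_equal(dim(fld$image), c(50, 50, 3))
})

test_that("impossible density errors with a placement message", {
  spec <- cell_population_spec(c(N = 1), 400, seed = 2)
  expect_error(sample_cell_truth(spec, field_dim = c(150, 150)),
               "density too high|cannot hold")
})
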