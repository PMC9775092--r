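#' Default per-class morphometric population parameters
#'
#' One row per morphometric class giving the area distribution (mean/SD of
#' cross-sectional area in square microns) and shape parameters used by the
#' synthetic generator: `elong_mean`/`elong_sd` parameterise the base-ellipse
#' elongation (major/minor axis ratio, truncated at 1) and `boundary_noise`
#' the total relative amplitude of the radial perturbation of the cell
#' outline. Classes: `N` normal, `I` normal-size irregular, `HR`/`HI`
#' hypertrophic regular/irregular, `AR`/`AI` atrophic regular/irregular.
#'
#' Defaults emulate adult-rat cardiomyocyte cross-sections: normal-size areas
#' around 300 um^2, hypertrophic around 600 um^2, atrophic around 120 um^2.
#'
#' @return A tibble with columns `class`, `area_mean`, `area_sd`,
#'   `elong_mean`, `elong_sd`, `boundary_noise`.
#' @export
#' @examples
#' morph_class_params()
morph_class_params <- function() {
  tibble(
    class          = c("N", "I", "HR", "HI", "AR", "AI"),
    area_mean      = c(300, 300, 600, 600, 120, 120),
    area_sd        = c(40, 40, 60, 60, 20, 20),
    elong_mean     = c(1.15, 1.55, 1.15, 1.55, 1.15, 1.55),
    elong_sd       = c(0.08, 0.15, 0.08, 0.15, 0.08, 0.15),
    boundary_noise = c(0.02, 0.14, 0.02, 0.14, 0.02, 0.14)
  )
}

#' Specify a synthetic cardiomyocyte population
#'
#' Bundles and validates everything [sample_cell_truth()] needs: the class
#' mixture, per-class area and shape parameters, the number of cells, the
#' pixel calibration and a mandatory seed.
#'
#' @param class_mixture Named numeric vector of class proportions (names from
#'   `morph_class_params()$class`); must sum to 1.
#' @param n_cells Number of cells to generate (>= 1).
#' @param seed Integer seed; generation refuses to run without one.
#' @param class_params Per-class parameter table as in [morph_class_params()];
#'   rows for classes absent from `class_mixture` are ignored.
#' @param pixel_size Microns per pixel (> 0). The default 0.4 um/px matches
#'   typical 200-400x micrograph calibrations and keeps normal cells at a
#'   radius of ~25 px, where shape descriptors are numerically stable.
#' @param packing Target fraction of the field area occupied by cell
#'   footprints when the field is auto-sized; lower is sparser.
#'
#' @return An object of class `cell_population_spec`.
#' @export
#' @examples
#' spec <- cell_population_spec(c(N = 0.7, HR = 0.2, AR = 0.1),
#'                              n_cells = 100, seed = 1)
cell_population_spec <- function(class_mixture, n_cells, seed,
                                 class_params = morph_class_params(),
                                 pixel_size = 0.4, packing = 0.25) {
  if (is.null(names(class_mixture)) || any(!nzchar(names(class_mixture)))) {
    abort("`class_mixture` must be a named vector of class proportions.")
  }
  if (any(class_mixture < 0) || abs(sum(class_mixture) - 1) > 1e-9) {
    abort("`class_mixture` proportions must be non-negative and sum to 1 (tol 1e-9).")
  }
  check_df_cols(class_params,
                c("class", "area_mean", "area_sd", "elong_mean", "elong_sd",
                  "boundary_noise"))
  unknown <- setdiff(names(class_mixture), class_params$class)
  if (length(unknown)) {
    abort(sprintf("`class_mixture` has classes without parameters: %s.",
                  paste(unknown, collapse = ", ")))
  }
  if (any(class_params$area_mean <= 0)) abort("Area means must be positive.")
  if (any(class_params$area_sd < 0) || any(class_params$boundary_noise < 0)) {
    abort("Area SDs and boundary-noise levels must be non-negative.")
  }
  check_number(n_cells, "n_cells", min = 1)
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(packing, "packing", min = 0.01, max = 0.5)
  structure(
    list(class_mixture = class_mixture, n_cells = as.integer(n_cells),
         class_params = as_tibble(class_params), pixel_size = pixel_size,
         packing = packing, seed = check_seed(seed)),
    class = "cell_population_spec")
}

# Bounding radius (px) of a cell: semi-major axis of the base ellipse times
# the maximum outline perturbation factor.
cell_bound_radius <- function(area_px, elongation, boundary_noise) {
  r0 <- sqrt(area_px / pi)
  r0 * sqrt(elongation) * (1 + boundary_noise) + 1
}

#' Sample ground-truth cells for a synthetic field
#'
#' Draws class labels multinomially from the mixture, per-cell nominal areas
#' and shape parameters from the per-class distributions, and places cell
#' centers by dart throwing so that bounding disks stay at least `margin`
#' pixels apart (cells must not merge: morphometry measures single cells).
#'
#' @param spec A [cell_population_spec()].
#' @param field_dim Optional `c(height, width)` of the field in pixels; by
#'   default the field is sized so cell footprints occupy `spec$packing` of it.
#' @param margin Minimum gap between cell bounding disks, in pixels.
#' @param max_tries Placement attempts per cell before giving up.
#'
#' @return A tibble (`cell_id`, `class`, `center_x`, `center_y` in px,
#'   `nominal_area` in um^2, `elongation`, `boundary_noise`, `orientation`)
#'   with the field dimensions, pixel size and seed attached as attributes.
#' @export
#' @examples
#' truths <- sample_cell_truth(
#'   cell_population_spec(c(N = 1), n_cells = 20, seed = 1))
sample_cell_truth <- function(spec, field_dim = NULL, margin = 2,
                              max_tries = 400L) {
  if (!inherits(spec, "cell_population_spec")) {
    abort("`spec` must be a `cell_population_spec`.")
  }
  params <- spec$class_params
  withr::with_seed(spec$seed, {
    cls <- sample(names(spec$class_mixture), spec$n_cells, replace = TRUE,
                  prob = spec$class_mixture)
    idx <- match(cls, params$class)
    nominal_area <- pmax(rnorm(spec$n_cells, params$area_mean[idx],
                               params$area_sd[idx]),
                         0.25 * params$area_mean[idx])
    elongation <- pmax(rnorm(spec$n_cells, params$elong_mean[idx],
                             params$elong_sd[idx]), 1)
    boundary_noise <- params$boundary_noise[idx]
    orientation <- runif(spec$n_cells, 0, pi)

    area_px <- nominal_area / spec$pixel_size^2
    rbound <- cell_bound_radius(area_px, elongation, boundary_noise)
    if (is.null(field_dim)) {
      side <- ceiling(sqrt(sum(pi * rbound^2) / spec$packing)) +
        2 * ceiling(max(rbound))
      field_dim <- c(side, side)
    }
    centers <- place_centers(rbound, field_dim, margin, max_tries)

    out <- tibble(
      cell_id = seq_len(spec$n_cells), class = cls,
      center_x = centers[, 1], center_y = centers[, 2],
      nominal_area = nominal_area, elongation = elongation,
      boundary_noise = boundary_noise, orientation = orientation)
  })
  attr(out, "field_dim") <- as.integer(field_dim)
  attr(out, "pixel_size") <- spec$pixel_size
  attr(out, "seed") <- spec$seed
  out
}

# Dart-throwing placement with a uniform occupancy grid. Bounding disks of
# radius r_i must be >= margin apart; errors naming how many cells fit.
place_centers <- function(rbound, field_dim, margin, max_tries) {
  n <- length(rbound)
  h <- field_dim[1]; w <- field_dim[2]
  gmax <- max(rbound)
  if (2 * gmax + margin > min(h, w)) {
    abort(sprintf("Field %d x %d px cannot hold a cell of bounding radius %.1f px.",
                  h, w, gmax))
  }
  gsz <- gmax + margin
  ngx <- max(1L, ceiling(w / gsz)); ngy <- max(1L, ceiling(h / gsz))
  buckets <- vector("list", ngx * ngy)
  cx <- numeric(n); cy <- numeric(n)
  # place large cells first: much higher success rate at a given density
  ord <- order(rbound, decreasing = TRUE)
  for (i in ord) {
    r <- rbound[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, r + 1, w - r)
      y <- runif(1, r + 1, h - r)
      bx <- pmin(pmax(floor(x / gsz) + 1, 1), ngx)
      by <- pmin(pmax(floor(y / gsz) + 1, 1), ngy)
      reach <- ceiling((r + gmax + margin) / gsz)
      nb <- unlist(buckets[outer(
        pmax(1, bx - reach):pmin(ngx, bx + reach),
        (pmax(1, by - reach):pmin(ngy, by + reach) - 1) * ngx, "+")],
        use.names = FALSE)
      ok <- TRUE
      if (length(nb)) {
        d2 <- (cx[nb] - x)^2 + (cy[nb] - y)^2
        ok <- all(d2 > (r + rbound[nb] + margin)^2)
      }
      if (ok) {
        cx[i] <- x; cy[i] <- y
        buckets[[(by - 1) * ngx + bx]] <- c(buckets[[(by - 1) * ngx + bx]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      n_done <- sum(cx != 0)
      abort(sprintf(
        "Could only place %d of %d cells in a %d x %d px field; density too high.",
        n_done, n, h, w))
    }
  }
  cbind(cx, cy)
}

# Radial outline of one cell: base ellipse (semi-axes a, b, orientation phi)
# perturbed by low-order cosine modes. Star-convex by construction for
# amplitude < 1, so point-in-cell reduces to rho <= r(theta).
cell_radius_at <- function(theta, a, b, phi, noise_amp, noise_phase) {
  base <- a * b / sqrt((b * cos(theta - phi))^2 + (a * sin(theta - phi))^2)
  pert <- rep(1, length(theta))
  for (k in seq_along(noise_amp)) {
    pert <- pert + noise_amp[k] * cos((k + 1) * theta + noise_phase[k])
  }
  base * pert
}

#' Render a synthetic histology field from ground-truth cells
#'
#' Rasterizes each cell as a noisy ellipse (radial cosine perturbation of its
#' base ellipse) at its placed center, producing an H&E-like RGB image and an
#' integer label mask in which value `k` exactly covers cell `k`.
#'
#' @param truths Tibble from [sample_cell_truth()].
#' @param cell_color,background Base RGB triplets in \[0, 1\].
#' @param color_jitter SD of the per-cell shade jitter.
#'
#' @return A list of class `cell_field`: `image` (h x w x 3 array in \[0,1\]),
#'   `mask` (h x w integer matrix), `truths`, `pixel_size`.
#' @export
#' @examples
#' truths <- sample_cell_truth(
#'   cell_population_spec(c(N = 1), n_cells = 5, seed = 1))
#' field <- render_field(truths)
#' dim(field$mask)
render_field <- function(truths, cell_color = c(0.78, 0.45, 0.55),
                         background = c(0.96, 0.93, 0.95),
                         color_jitter = 0.04) {
  field_dim <- attr(truths, "field_dim")
  pixel_size <- attr(truths, "pixel_size") %||% 1
  seed <- attr(truths, "seed")
  if (is.null(field_dim)) abort("`truths` must carry a `field_dim` attribute.")
  h <- field_dim[1]; w <- field_dim[2]
  mask <- matrix(0L, h, w)
  img <- array(rep(background, each = h * w), dim = c(h, w, 3))
  if (nrow(truths) == 0) {
    return(structure(list(image = img, mask = mask, truths = truths,
                          pixel_size = pixel_size), class = "cell_field"))
  }
  withr::with_seed((seed %||% 0L) + 1L, {
    # fixed mode weights ~ 1/k over modes 2..5, scaled to the total amplitude
    wts <- (1 / (1:4)) / sum(1 / (1:4))
    for (i in seq_len(nrow(truths))) {
      tr <- truths[i, ]
      area_px <- tr$nominal_area / pixel_size^2
      r0 <- sqrt(area_px / pi)
      a <- r0 * sqrt(tr$elongation); b <- r0 / sqrt(tr$elongation)
      amp <- tr$boundary_noise * wts
      phase <- runif(4, 0, 2 * pi)
      rb <- a * (1 + tr$boundary_noise) + 1
      xs <- max(1, floor(tr$center_x - rb)):min(w, ceiling(tr$center_x + rb))
      ys <- max(1, floor(tr$center_y - rb)):min(h, ceiling(tr$center_y + rb))
      dx <- rep(xs - tr$center_x, times = length(ys))
      dy <- rep(ys - tr$center_y, each = length(xs))
      rho <- sqrt(dx^2 + dy^2)
      theta <- atan2(dy, dx)
      inside <- rho <= cell_radius_at(theta, a, b, tr$orientation, amp, phase)
      px <- rep(xs, times = length(ys))[inside]
      py <- rep(ys, each = length(xs))[inside]
      lin <- (px - 1) * h + py          # mask is h x w, indexed [y, x]
      free <- mask[lin] == 0L
      mask[lin[free]] <- tr$cell_id
      shade <- pmin(pmax(cell_color + rnorm(3, 0, color_jitter), 0), 1)
      for (ch in 1:3) img[lin[free] + (ch - 1) * h * w] <- shade[ch]
    }
  })
  structure(list(image = img, mask = mask, truths = truths,
                 pixel_size = pixel_size), class = "cell_field")
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("<cell_field> %d x %d px, %d cells, pixel size %g um/px\n",
              nrow(x$mask), ncol(x$mask), nrow(x$truths), x$pixel_size))
  invisible(x)
}
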