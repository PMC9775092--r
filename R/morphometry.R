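#' Extract labeled regions from a mask
#'
#' Turns an integer label mask (the first-class input: curated masks replace
#' the manual cell-outline tracing step) into one record per region, carrying
#' the pixel set, centroid and ordered boundary chain needed downstream.
#' Regions touching the image border are flagged and excluded from
#' measurement by default, since a cut-off cross-section has no meaningful
#' shape.
#'
#' @param mask Integer matrix (or EBImage Image) in which value `k` labels
#'   region `k`; 0 is background. A `cell_field` from [render_field()] is
#'   also accepted.
#'
#' @return A tibble with `region_id`, `n_pixels`, `centroid_x`, `centroid_y`,
#'   `border` (logical) and list-columns `pixels` (n x 2 matrix of x, y pixel
#'   coordinates) and `contour` (ordered boundary coordinates).
#' @export
#' @examples
#' m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
#' extract_regions(m)
extract_regions <- function(mask) {
  if (inherits(mask, "cell_field")) mask <- mask$mask
  if (inherits(mask, "Image")) mask <- EBImage::imageData(mask)
  if (!is.matrix(mask)) abort("`mask` must be an integer matrix.")
  if (any(abs(mask - round(mask)) > 1e-9) || any(mask < 0)) {
    abort("`mask` must contain non-negative integer labels (0 = background).")
  }
  mask <- matrix(as.integer(round(mask)), nrow(mask), ncol(mask))
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask > 0L)
  if (!length(fg)) {
    return(tibble(region_id = integer(), n_pixels = integer(),
                  centroid_x = numeric(), centroid_y = numeric(),
                  border = logical(), pixels = list(), contour = list()))
  }
  labs <- mask[fg]
  ys <- ((fg - 1L) %% h) + 1L
  xs <- ((fg - 1L) %/% h) + 1L
  by_lab <- split(seq_along(fg), labs)
  ids <- as.integer(names(by_lab))

  rows <- purrr::map2(by_lab, ids, function(ii, id) {
    px <- cbind(x = xs[ii], y = ys[ii])
    sub_x <- range(px[, 1]); sub_y <- range(px[, 2])
    # contour traced on a cropped binary patch (1 px pad)
    patch <- matrix(0L, sub_y[2] - sub_y[1] + 3L, sub_x[2] - sub_x[1] + 3L)
    patch[cbind(px[, 2] - sub_y[1] + 2L, px[, 1] - sub_x[1] + 2L)] <- 1L
    oc <- EBImage::ocontour(t(patch))[[1]]  # ocontour expects [x, y] layout
    contour <- cbind(x = oc[, 1] + sub_x[1] - 1L, y = oc[, 2] + sub_y[1] - 1L)
    tibble(region_id = id, n_pixels = nrow(px),
           centroid_x = mean(px[, 1]), centroid_y = mean(px[, 2]),
           border = sub_x[1] == 1L || sub_y[1] == 1L ||
             sub_x[2] == w || sub_y[2] == h,
           pixels = list(px), contour = list(contour))
  })
  dplyr::bind_rows(rows)
}

# Circular moving average of an ordered contour; window must be odd.
smooth_contour <- function(contour, k) {
  n <- nrow(contour)
  if (n < 2L * k) return(contour)
  half <- (k - 1L) %/% 2L
  out <- contour * 0
  for (o in -half:half) {
    out <- out + contour[((seq_len(n) + o - 1L) %% n) + 1L, , drop = FALSE]
  }
  out / k
}

# Smoothing window adapted to contour length so the perimeter estimate is
# stable under rescaling (a fixed window under-smooths upscaled staircase
# boundaries); odd, clamped to [3, 9].
adaptive_window <- function(n_contour) {
  k <- max(3L, min(9L, as.integer(round(n_contour / 64))))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

closed_polyline_length <- function(p) {
  d <- rbind(diff(p), p[1, , drop = FALSE] - p[nrow(p), , drop = FALSE])
  sum(sqrt(rowSums(d^2)))
}

# Descriptor engine for a single region (pixel coordinates + boundary chain).
measure_one <- function(px, contour, pixel_size, id) {
  x <- px[, 1]; y <- px[, 2]
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  tr <- mu20 + mu02; dt <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - dt, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 < 1e-9) {
    abort(sprintf("Region %s is degenerate (collinear pixels); cannot measure shape.",
                  id))
  }
  aspect <- sqrt(l1 / l2)
  # bounding box aligned with the principal axes (rotation-invariant)
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  u <- (x - cx) * cos(ang) + (y - cy) * sin(ang)
  v <- -(x - cx) * sin(ang) + (y - cy) * cos(ang)
  box <- (diff(range(u)) + 1) * (diff(range(v)) + 1)
  sc <- smooth_contour(contour, adaptive_window(nrow(contour)))
  perim <- closed_polyline_length(sc)
  dd <- sqrt((sc[, 1] - cx)^2 + (sc[, 2] - cy)^2)
  tibble(
    area = n * pixel_size^2,
    aspect = aspect,
    area_box = n / box,
    roundness = perim^2 / (4 * pi * n),
    radius_ratio = max(dd) / min(dd))
}

#' Measure cardiomyocyte cross-sections
#'
#' Computes, per region, the five morphometric measurements — area (um^2),
#' aspect (major/minor axis of the moment-equivalent ellipse), area/box
#' (area over the principal-axis-aligned bounding box), roundness
#' (perimeter^2 / 4 pi area) and radius ratio (max/min centroid-to-boundary
#' distance) — and the cardiomyocyte irregularity index
#' `CII = aspect - area/box + roundness + radius ratio`.
#'
#' Border-touching regions and regions below `min_pixels` are dropped (with a
#' message) before measurement: both give unstable descriptors.
#'
#' @param regions Tibble from [extract_regions()], or anything it accepts
#'   (label mask, `cell_field`).
#' @param pixel_size Microns per pixel; the default 1 reports areas in px^2.
#' @param min_pixels Minimum region size in pixels.
#' @param drop_border Exclude border-touching regions (default TRUE).
#'
#' @return A tibble: `cell_id`, `area`, `aspect`, `area_box`, `roundness`,
#'   `radius_ratio`, `cii`.
#' @export
#' @examples
#' m <- matrix(0L, 60, 60)
#' m[20:40, 15:45] <- 1L
#' measure_cells(m)
measure_cells <- function(regions, pixel_size = 1, min_pixels = 20,
                          drop_border = TRUE) {
  if (!is.data.frame(regions)) {
    ps <- if (inherits(regions, "cell_field")) regions$pixel_size else NULL
    regions <- extract_regions(regions)
    if (!is.null(ps) && missing(pixel_size)) pixel_size <- ps
  }
  check_df_cols(regions, c("region_id", "n_pixels", "border", "pixels", "contour"))
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  keep <- rep(TRUE, nrow(regions))
  if (drop_border && any(regions$border)) {
    message(sprintf("Dropping %d border-touching region(s).", sum(regions$border)))
    keep <- keep & !regions$border
  }
  small <- regions$n_pixels < min_pixels
  if (any(small & keep)) {
    message(sprintf("Dropping %d region(s) below %d px.", sum(small & keep),
                    min_pixels))
    keep <- keep & !small
  }
  regions <- regions[keep, ]
  out <- purrr::pmap(
    list(regions$pixels, regions$contour, regions$region_id),
    function(px, ct, id) measure_one(px, ct, pixel_size, id))
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(cell_id = integer(), area = numeric(), aspect = numeric(),
                  area_box = numeric(), roundness = numeric(),
                  radius_ratio = numeric(), cii = numeric()))
  }
  dplyr::mutate(
    dplyr::bind_cols(tibble(cell_id = regions$region_id), out),
    cii = compute_cii(.data$aspect, .data$area_box, .data$roundness,
                      .data$radius_ratio))
}

#' Cardiomyocyte irregularity index
#'
#' `CII = aspect - area/box + roundness + radius ratio`. For a perfect circle
#' the descriptors are (1, pi/4, 1, 1), so the CII fixed point is
#' 3 - pi/4 ~ 2.215; every form of irregularity (elongation, boundary
#' roughness, asymmetry) raises it.
#'
#' @param aspect,area_box,roundness,radius_ratio Numeric vectors (recycled).
#' @return Numeric vector of CII values.
#' @export
#' @examples
#' compute_cii(1, pi / 4, 1, 1)  # 3 - pi/4
compute_cii <- function(aspect, area_box, roundness, radius_ratio) {
  stopifnot(is.numeric(aspect), is.numeric(area_box),
            is.numeric(roundness), is.numeric(radius_ratio))
  if (any(!is.finite(c(aspect, area_box, roundness, radius_ratio)))) {
    abort("All four descriptors must be finite.")
  }
  aspect - area_box + roundness + radius_ratio
}

#' Derive size/shape gates from a control population
#'
#' The area-versus-CII plane is partitioned by reference-population quantile
#' gates: the normal-size band is the central area quantile range of control
#' cells and the irregularity cutoff is an upper CII quantile. Defaults
#' (5th/95th area, 95th CII) follow reference-population gating practice in
#' nuclear morphometric analysis.
#'
#' @param control_cells Measured control cells ([measure_cells()] output).
#' @param area_quantiles Lower/upper area quantiles, e.g. `c(0.05, 0.95)`.
#' @param cii_quantile Upper CII quantile for the irregularity cutoff.
#' @param min_cells Minimum control cells required (default 20; >= 100
#'   recommended for stable tail quantiles).
#'
#' @return An object of class `morph_thresholds`: `area_low`, `area_high`,
#'   `cii_high` and a `source` record of the inputs.
#' @export
derive_thresholds <- function(control_cells, area_quantiles = c(0.05, 0.95),
                              cii_quantile = 0.95, min_cells = 20) {
  check_df_cols(control_cells, c("area", "cii"))
  if (nrow(control_cells) < min_cells) {
    abort(sprintf("Need >= %d control cells to derive thresholds; got %d.",
                  min_cells, nrow(control_cells)))
  }
  if (length(area_quantiles) != 2 || area_quantiles[1] >= area_quantiles[2]) {
    abort("`area_quantiles` must be increasing c(low, high).")
  }
  if (nrow(control_cells) < 100) {
    warn("Fewer than 100 control cells; tail quantiles will be noisy.")
  }
  aq <- quantile(control_cells$area, area_quantiles, names = FALSE)
  structure(
    list(area_low = aq[1], area_high = aq[2],
         cii_high = quantile(control_cells$cii, cii_quantile, names = FALSE),
         source = list(n_control = nrow(control_cells),
                       area_quantiles = area_quantiles,
                       cii_quantile = cii_quantile)),
    class = "morph_thresholds")
}

#' @export
print.morph_thresholds <- function(x, ...) {
  cat(sprintf(
    "<morph_thresholds> area band [%.1f, %.1f] um^2, CII cutoff %.3f (n = %d control cells)\n",
    x$area_low, x$area_high, x$cii_high, x$source$n_control))
  invisible(x)
}

#' Classify cells into morphometric classes
#'
#' Two independent axes: size (atrophic if `area < area_low`, hypertrophic if
#' `area > area_high`, otherwise normal-size) and shape (irregular if
#' `cii > cii_high`, otherwise regular). Values exactly on a threshold take
#' the non-extreme side. Classes: `N`, `I`, `HR`, `HI`, `AR`, `AI`.
#'
#' @param cells Measured cells with `area` and `cii` columns.
#' @param thresholds A [derive_thresholds()] object.
#' @return `cells` with a `class` factor column added.
#' @export
classify_cells <- function(cells, thresholds) {
  check_df_cols(cells, c("area", "cii"))
  if (!inherits(thresholds, "morph_thresholds")) {
    abort("`thresholds` must be a `morph_thresholds` object.")
  }
  size <- dplyr::case_when(
    cells$area < thresholds$area_low ~ "A",
    cells$area > thresholds$area_high ~ "H",
    TRUE ~ "N")
  irregular <- cells$cii > thresholds$cii_high
  cls <- dplyr::case_when(
    size == "N" & !irregular ~ "N",
    size == "N" & irregular ~ "I",
    size == "H" & !irregular ~ "HR",
    size == "H" & irregular ~ "HI",
    size == "A" & !irregular ~ "AR",
    TRUE ~ "AI")
  dplyr::mutate(cells, class = factor(cls, levels = morph_class_levels()))
}

#' Morphometric class levels
#' @return Character vector of the six class labels in canonical order.
#' @export
morph_class_levels <- function() c("N", "I", "HR", "HI", "AR", "AI")

#' Per-animal population profile
#'
#' Summarises one animal's classified cells: the percentage of cells in each
#' morphometric class (always summing to 100), the mean CII, and the
#' variability of cell area as its coefficient of variation (SD/mean —
#' unitless, so comparable across animals and calibrations).
#'
#' @param cells Classified cells from [classify_cells()] for one animal.
#' @param min_cells Protocol minimum; a warning (not an error) is emitted
#'   below it. Default 50 cells per animal.
#' @return One-row tibble: `n_cells`, `percent_<class>` for each class,
#'   `mean_cii`, `area_variability`.
#' @export
population_profile <- function(cells, min_cells = 50) {
  check_df_cols(cells, c("area", "cii", "class"))
  n <- nrow(cells)
  if (n == 0) abort("Cannot profile an animal with zero cells.")
  if (n < min_cells) {
    warn(sprintf("Only %d cells (< %d protocol minimum); profile will be noisy.",
                 n, min_cells))
  }
  cls <- factor(cells$class, levels = morph_class_levels())
  pct <- as.numeric(table(cls)) / n * 100
  out <- tibble(n_cells = n)
  out[paste0("percent_", morph_class_levels())] <- as.list(pct)
  out$mean_cii <- mean(cells$cii)
  out$area_variability <- if (n > 1) sd(cells$area) / mean(cells$area) else 0
  out
}
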