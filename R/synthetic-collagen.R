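#' Simulate a picrosirius-red-stained liver field
#'
#' Generates an RGB field in which a known fraction of pixels carries the
#' collagen stain. A smooth random texture (bilinearly upsampled coarse
#' Gaussian noise) is thresholded at the quantile matching `true_fraction`,
#' giving spatially coherent "fiber" patches; stain pixels are rendered in a
#' picrosirius-like red, background in pale tissue tones, with slight per-
#' pixel color jitter. The rendered stain share equals `true_fraction` to
#' within one pixel in `prod(dim)`.
#'
#' @param true_fraction Target stained area fraction in \[0, 1\].
#' @param seed Integer seed (required).
#' @param dim Field size `c(height, width)` in pixels.
#' @param grain Coarse-noise grid size controlling patch scale.
#'
#' @return A list of class `collagen_field`: `image` (h x w x 3 array),
#'   `stain_mask` (logical matrix), `true_fraction`.
#' @export
#' @examples
#' fld <- sim_collagen_field(0.25, seed = 3, dim = c(128, 128))
#' mean(fld$stain_mask)
sim_collagen_field <- function(true_fraction, seed, dim = c(384, 384),
                               grain = 24) {
  check_number(true_fraction, "true_fraction", min = 0, max = 1)
  seed <- check_seed(seed)
  h <- dim[1]; w <- dim[2]
  withr::with_seed(seed, {
    coarse <- matrix(rnorm(grain * grain), grain, grain)
    field <- EBImage::imageData(EBImage::resize(EBImage::Image(coarse),
                                                w = h, h = w))
    n_stain <- round(true_fraction * h * w)
    stain <- matrix(FALSE, h, w)
    if (n_stain > 0) {
      stain[order(field, decreasing = TRUE)[seq_len(n_stain)]] <- TRUE
    }
    stain_col <- c(0.72, 0.12, 0.18)
    bg_col <- c(0.95, 0.90, 0.80)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      base <- ifelse(stain, stain_col[ch], bg_col[ch])
      img[, , ch] <- pmin(pmax(base + rnorm(h * w, 0, 0.02), 0), 1)
    }
  })
  structure(list(image = img, stain_mask = stain,
                 true_fraction = true_fraction),
            class = "collagen_field")
}

#' @export
print.collagen_field <- function(x, ...) {
  cat(sprintf("<collagen_field> %d x %d px, true stained fraction %.3f\n",
              nrow(x$stain_mask), ncol(x$stain_mask), x$true_fraction))
  invisible(x)
}
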