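# Rasterize an ellipse (or circle) as a binary mask: semi-axes a >= b,
# rotated by `theta`, center on a half-integer grid point so a circle of
# radius r spans exactly 2r pixels.
rasterize_ellipse <- function(a, b = a, theta = 0, pad = 6) {
  n <- ceiling(2 * a) + 2 * pad
  cx <- n / 2 + 0.5
  xs <- matrix(rep(1:n, n), n, n)
  ys <- matrix(rep(1:n, each = n), n, n)
  u <- (xs - cx) * cos(theta) + (ys - cx) * sin(theta)
  v <- -(xs - cx) * sin(theta) + (ys - cx) * cos(theta)
  m <- matrix(0L, n, n)
  m[(u / a)^2 + (v / b)^2 <= 1] <- 1L
  m
}

# 2x nearest-neighbour upscale of a mask.
upscale2 <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                          rep(seq_len(ncol(m)), each = 2)]

measure_mask <- function(m, ...) {
  suppressMessages(measure_cells(m, ...))
}

# Sample skewness (moment estimator), the oracle for the skewed serum family.
sample_skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}

# Brute-force check that a compact letter display encodes a significance
# pattern: share a letter <=> adjusted p >= alpha.
letters_match_pattern <- function(lt, p_matrix, alpha) {
  gs <- names(lt)
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (i >= j) next
      share <- length(intersect(strsplit(lt[[i]], "")[[1]],
                                strsplit(lt[[j]], "")[[1]])) > 0
      nonsig <- is.na(p_matrix[gs[i], gs[j]]) || p_matrix[gs[i], gs[j]] >= alpha
      if (share != nonsig) return(FALSE)
    }
  }
  TRUE
}
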