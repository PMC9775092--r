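# Internal validation and RNG helpers.

check_seed <- function(seed, call = rlang::caller_env()) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("A single integer `seed` is required; refusing to randomize silently.",
          call = call)
  }
  as.integer(seed)
}

# Deterministic child seeds so that one user-facing seed can drive several
# independent generators without reusing streams.
child_seeds <- function(seed, n) {
  withr::with_seed(check_seed(seed), sample.int(.Machine$integer.max, n))
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict_min && x <= min) || (!strict_min && x < min) || x > max) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x))
  }
  invisible(x)
}

check_df_cols <- function(df, cols, name = deparse(substitute(df))) {
  if (!is.data.frame(df)) abort(sprintf("`%s` must be a data frame.", name))
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Coerce an RGB image (EBImage::Image or plain array) to an h x w x 3 array
# with values in [0, 1].
as_rgb_array <- function(img, name = "image") {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] < 3L) {
    abort(sprintf("`%s` must be an RGB image (h x w x 3 array or EBImage Image).",
                  name))
  }
  img[, , 1:3, drop = FALSE]
}
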