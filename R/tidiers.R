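#' Tidy a group-comparison result
#'
#' One row per variable and group pair with the adjusted p-value and the
#' significance call at the comparison's alpha.
#'
#' @param x A `chp_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble: `variable`, `route`, `group1`, `group2`, `p_adj`,
#'   `significant`.
#' @method tidy chp_comparison
#' @export
tidy.chp_comparison <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  x |>
    as_tibble() |>
    dplyr::select("variable", "route", "pairwise") |>
    tidyr::unnest("pairwise") |>
    dplyr::mutate(significant = .data$p_adj < alpha)
}

#' Glance at a group-comparison result
#'
#' One row per variable: route taken, omnibus p-value, number of groups and
#' number of significant pairwise differences.
#'
#' @param x A `chp_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble: `variable`, `route`, `omnibus_p`, `n_groups`,
#'   `n_significant_pairs`, `alpha`.
#' @method glance chp_comparison
#' @export
glance.chp_comparison <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  tibble(
    variable = x$variable,
    route = x$route,
    omnibus_p = x$omnibus_p,
    n_groups = vapply(x$summaries, nrow, integer(1)),
    n_significant_pairs = vapply(x$pairwise,
                                 function(p) sum(p$p_adj < alpha), integer(1)),
    alpha = alpha)
}
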