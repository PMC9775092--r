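# Dunn's rank-based pairwise test after Kruskal-Wallis, with tie-corrected
# pooled variance. Returns unadjusted two-sided z-test p per group pair.
dunn_pairwise <- function(value, group) {
  group <- factor(group)
  r <- rank(value)
  n <- length(value)
  rbar <- tapply(r, group, mean)
  ni <- tapply(r, group, length)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  gl <- levels(group)
  pairs <- utils::combn(gl, 2)
  p <- apply(pairs, 2, function(pr) {
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(s2 * (1 / ni[[pr[1]]] + 1 / ni[[pr[2]]]))
    2 * pnorm(-abs(z))
  })
  tibble(group1 = pairs[1, ], group2 = pairs[2, ], p_value = p)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Assigns letters to groups so that two groups share at least one letter if
#' and only if they are *not* significantly different (adjusted p >= alpha),
#' by the insertion-and-absorption algorithm: start with every group in one
#' letter class; for each significant pair split every class containing
#' both; absorb classes that are subsets of others. Groups are processed in
#' the matrix order, so output is deterministic.
#'
#' @param p_matrix Symmetric matrix of (adjusted) pairwise p-values with
#'   group names as dimnames; the diagonal is ignored.
#' @param alpha Significance level.
#' @return Named character vector, group -> letter string.
#' @export
#' @examples
#' p <- matrix(c(NA, 0.01, 0.01, NA), 2, 2,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' letter_display(p, 0.05)
letter_display <- function(p_matrix, alpha = 0.05) {
  if (!is.matrix(p_matrix) || nrow(p_matrix) != ncol(p_matrix)) {
    abort("`p_matrix` must be a square matrix.")
  }
  if (is.null(rownames(p_matrix))) abort("`p_matrix` needs group dimnames.")
  off <- row(p_matrix) != col(p_matrix)
  if (any(abs(p_matrix[off] - t(p_matrix)[off]) > 1e-12, na.rm = TRUE) ||
      any(is.na(p_matrix[off]) != is.na(t(p_matrix)[off]))) {
    abort("`p_matrix` must be symmetric.")
  }
  groups <- rownames(p_matrix)
  k <- length(groups)
  classes <- list(seq_len(k))  # letter classes as index sets
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!is.na(p_matrix[i, j]) && p_matrix[i, j] < alpha) {
        new_classes <- list()
        for (cl in classes) {
          if (i %in% cl && j %in% cl) {
            new_classes <- c(new_classes, list(setdiff(cl, i)),
                             list(setdiff(cl, j)))
          } else {
            new_classes <- c(new_classes, list(cl))
          }
        }
        # absorb: drop classes contained in another class
        keep <- rep(TRUE, length(new_classes))
        for (a in seq_along(new_classes)) {
          for (b in seq_along(new_classes)) {
            if (a != b && keep[b] &&
                all(new_classes[[a]] %in% new_classes[[b]]) &&
                (length(new_classes[[a]]) < length(new_classes[[b]]) ||
                 (a > b && length(new_classes[[a]]) ==
                  length(new_classes[[b]])))) {
              keep[a] <- FALSE
              break
            }
          }
        }
        classes <- new_classes[keep]
      }
    }
  }
  classes <- classes[order(vapply(classes, min, numeric(1)))]
  out <- setNames(rep("", k), groups)
  for (ci in seq_along(classes)) {
    lab <- letters[(ci - 1) %% 26 + 1]
    if (ci > 26) lab <- paste0(lab, (ci - 1) %/% 26)
    for (g in classes[[ci]]) out[g] <- paste0(out[g], lab)
  }
  out
}

#' Normality-gated group comparison
#'
#' Runs the study's statistical pipeline over each measurement variable:
#' Shapiro-Wilk on every group gates the route — if all groups pass at the
#' gate level, one-way ANOVA with Tukey HSD pairwise comparisons
#' (parametric); otherwise Kruskal-Wallis with Dunn's pairwise test and the
#' configured p adjustment (nonparametric). Group summaries follow the
#' route (mean +- SD, or median and 25th-75th percentiles), and a compact
#' letter display is derived from the adjusted pairwise matrix: groups
#' sharing a letter are not significantly different at `alpha`.
#'
#' Groups with constant values (where Shapiro-Wilk is undefined) are flagged
#' and force the nonparametric route.
#'
#' @param data Data frame with a group column and one or more numeric
#'   measurement columns (wide, one row per animal).
#' @param group Name of the group column (string).
#' @param vars Measurement columns to analyse; default all numeric columns.
#' @param alpha Significance level for both the gate and the letters.
#' @param p_adjust Adjustment for Dunn's pairwise p-values: `"holm"`
#'   (default), `"bonferroni"` or `"none"`. Tukey HSD p-values are already
#'   family-adjusted.
#'
#' @return A `chp_comparison` tibble, one row per variable: `variable`,
#'   `route`, `omnibus_p`, and list-columns `pairwise` (group1, group2,
#'   p_adj), `letters` (named vector) and `summaries` (per-group location
#'   and spread matching the route).
#' @export
#' @examples
#' d <- tibble::tibble(group = rep(c("a", "b"), each = 5),
#'                     y = c(rnorm(5), rnorm(5, 4)))
#' compare_groups(d, group = "group")
compare_groups <- function(data, group = "group", vars = NULL, alpha = 0.05,
                           p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  check_df_cols(data, group)
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("Need at least two groups.")
  if (is.null(vars)) {
    vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], group)
  }
  if (!length(vars)) abort("No numeric measurement columns found.")
  small <- names(which(table(g) < 3))
  if (length(small)) {
    abort(sprintf("Group(s) with fewer than 3 animals (normality gate needs >= 3): %s.",
                  paste(small, collapse = ", ")))
  }
  res <- purrr::map(vars, function(v) {
    compare_one(data[[v]], g, v, alpha, p_adjust)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("chp_comparison", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- p_adjust
  out
}

compare_one <- function(value, g, varname, alpha, p_adjust) {
  ok <- is.finite(value)
  value <- value[ok]; g <- droplevels(g[ok])
  degenerate <- vapply(split(value, g),
                       function(x) length(unique(x)) == 1L, logical(1))
  sw_p <- vapply(split(value, g), function(x) {
    if (length(unique(x)) == 1L) NA_real_ else shapiro.test(x)$p.value
  }, numeric(1))
  parametric <- !any(degenerate) && all(sw_p >= alpha)
  lv <- levels(g)
  if (parametric) {
    fit <- aov(value ~ g)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$g
    # Tukey rows follow combn(levels, 2) order, named "lvl_j-lvl_i";
    # reconstruct the pairs positionally (robust to '-' inside group names)
    prs <- utils::combn(lv, 2)
    stopifnot(identical(rownames(tk), paste(prs[2, ], prs[1, ], sep = "-")))
    pw <- tibble(group1 = prs[1, ], group2 = prs[2, ], p_adj = tk[, "p adj"])
    summ <- tibble(group = lv,
                   n = as.integer(table(g)),
                   location = as.numeric(tapply(value, g, mean)),
                   spread_low = location - as.numeric(tapply(value, g, sd)),
                   spread_high = location + as.numeric(tapply(value, g, sd)),
                   location_label = "mean", spread_label = "sd")
  } else {
    omnibus_p <- kruskal.test(value, g)$p.value
    dn <- dunn_pairwise(value, g)
    pw <- tibble(group1 = dn$group1, group2 = dn$group2,
                 p_adj = p.adjust(dn$p_value, method = p_adjust))
    summ <- tibble(group = lv,
                   n = as.integer(table(g)),
                   location = as.numeric(tapply(value, g, median)),
                   spread_low = as.numeric(tapply(value, g, quantile,
                                                  probs = 0.25)),
                   spread_high = as.numeric(tapply(value, g, quantile,
                                                   probs = 0.75)),
                   location_label = "median", spread_label = "iqr")
  }
  pm <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (r in seq_len(nrow(pw))) {
    pm[pw$group1[r], pw$group2[r]] <- pw$p_adj[r]
    pm[pw$group2[r], pw$group1[r]] <- pw$p_adj[r]
  }
  tibble(variable = varname,
         route = if (parametric) "parametric" else "nonparametric",
         omnibus_p = omnibus_p,
         degenerate_groups = list(names(which(degenerate))),
         pairwise = list(pw),
         p_matrix = list(pm),
         letters = list(letter_display(pm, alpha)),
         summaries = list(summ))
}

#' @export
print.chp_comparison <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat(sprintf("<chp_comparison> %d variable(s), alpha = %g\n", nrow(x), alpha))
  for (i in seq_len(nrow(x))) {
    lt <- x$letters[[i]]
    cat(sprintf("  %s [%s]: omnibus p = %.4g; letters: %s\n",
                x$variable[i], x$route[i], x$omnibus_p[i],
                paste(names(lt), lt, sep = "=", collapse = " ")))
  }
  invisible(x)
}

#' Table-1-style summary with significance letters
#'
#' Formats a [compare_groups()] result as one row per variable and one
#' column per group: `mean +- SD` (parametric) or `median (q25-q75)`
#' (nonparametric), each followed by its compact-letter superscript.
#'
#' @param comparison A `chp_comparison` object.
#' @param digits Significant digits for the numbers.
#' @return A tibble, variables x groups, of formatted strings.
#' @export
report_table <- function(comparison, digits = 3) {
  stopifnot(inherits(comparison, "chp_comparison"))
  rows <- purrr::pmap(
    list(comparison$variable, comparison$route, comparison$summaries,
         comparison$letters, comparison$omnibus_p),
    function(v, route, s, lt, op) {
      fmt <- if (route == "parametric") {
        sprintf("%s ± %s %s", signif(s$location, digits),
                signif(s$location - s$spread_low, digits), lt[s$group])
      } else {
        sprintf("%s (%s-%s) %s", signif(s$location, digits),
                signif(s$spread_low, digits), signif(s$spread_high, digits),
                lt[s$group])
      }
      out <- tibble(variable = v)
      out[s$group] <- as.list(trimws(fmt))
      out$p_value <- op
      out
    })
  dplyr::bind_rows(rows)
}
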