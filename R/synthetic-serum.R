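#' Simulate a group-structured serum panel
#'
#' Draws per-animal analyte values from group-level specifications. The
#' `symmetric` family is Gaussian (location = mean, scale = SD); the `skewed`
#' family is log-normal, moment-matched so that the draw mean equals
#' `location` and the draw SD equals `scale` — the minimal right-skewed
#' family consistent with analytes reported as median (IQR).
#'
#' @param specs Tibble with one row per group x analyte: columns `group`,
#'   `analyte`, `location`, `scale`, `family` (`"symmetric"` or `"skewed"`)
#'   and `n_animals` (>= 2, constant within group).
#' @param seed Integer seed (required).
#'
#' @return Long tibble: `group`, `animal_id`, `analyte`, `value`.
#' @export
#' @examples
#' specs <- tibble::tibble(group = "control", analyte = "ICAM1",
#'                         location = 0.14, scale = 0.03,
#'                         family = "symmetric", n_animals = 10)
#' sim_serum_panel(specs, seed = 1)
sim_serum_panel <- function(specs, seed) {
  check_df_cols(specs, c("group", "analyte", "location", "scale", "family",
                         "n_animals"))
  seed <- check_seed(seed)
  if (anyDuplicated(specs[c("group", "analyte")])) {
    abort("Duplicate group/analyte rows in `specs`.")
  }
  if (any(specs$scale < 0)) abort("`scale` must be >= 0.")
  if (any(specs$n_animals < 2)) abort("`n_animals` must be >= 2.")
  if (!all(specs$family %in% c("symmetric", "skewed"))) {
    abort('`family` must be "symmetric" or "skewed".')
  }
  if (any(specs$family == "skewed" & specs$location <= 0)) {
    abort("Skewed (log-normal) analytes need a positive `location`.")
  }
  npg <- unique(specs[c("group", "n_animals")])
  if (anyDuplicated(npg$group)) {
    abort("`n_animals` must be constant within a group.")
  }
  withr::with_seed(seed, {
    cols <- c("group", "analyte", "location", "scale", "family", "n_animals")
    out <- purrr::pmap(specs[cols], function(group, analyte, location, scale,
                                             family, n_animals) {
      value <- if (family == "symmetric") {
        rnorm(n_animals, location, scale)
      } else if (scale == 0) {
        rep(location, n_animals)
      } else {
        sdlog <- sqrt(log(1 + (scale / location)^2))
        rlnorm(n_animals, log(location) - sdlog^2 / 2, sdlog)
      }
      tibble(group = group,
             animal_id = paste0(group, "_", seq_len(n_animals)),
             analyte = analyte, value = value)
    })
  })
  dplyr::bind_rows(out)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Generates paired target / spike-in-normalizer Ct values per sample such
#' that the group-mean `2^-ddCt` relative expression (versus the reference
#' group) recovers the requested fold change up to sampling noise: the
#' target Ct of group g is shifted by `-log2(fold[g])` cycles relative to
#' the reference baseline. Independent Gaussian noise of SD `noise_sd`
#' cycles is added to both target and normalizer Ct.
#'
#' @param fold_changes Named positive numeric vector, group -> fold change;
#'   must contain `reference_group` with fold 1.
#' @param reference_group Name of the reference (calibrator) group.
#' @param seed Integer seed (required).
#' @param target Target miRNA name.
#' @param n_per_group Samples per group.
#' @param ct_base Mean target Ct in the reference group (cycles).
#' @param normalizer_base Mean spike-in normalizer Ct (cycles).
#' @param noise_sd SD of per-sample Ct noise, cycles.
#'
#' @return Tibble: `sample_id`, `group`, `target`, `ct_target`,
#'   `ct_normalizer`.
#' @export
#' @examples
#' sim_ct_table(c(control = 1, NAFLD = 4), "control", seed = 11)
sim_ct_table <- function(fold_changes, reference_group, seed,
                         target = "miR-122", n_per_group = 10,
                         ct_base = 28, normalizer_base = 21, noise_sd = 0.2) {
  if (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes)))) {
    abort("`fold_changes` must be a named vector (group -> fold).")
  }
  if (any(fold_changes <= 0)) abort("Fold changes must be positive.")
  if (!reference_group %in% names(fold_changes)) {
    abort(sprintf("Reference group '%s' missing from `fold_changes`.",
                  reference_group))
  }
  if (abs(fold_changes[[reference_group]] - 1) > 1e-9) {
    abort("The reference group must have fold change 1.")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  seed <- check_seed(seed)
  groups <- names(fold_changes)
  withr::with_seed(seed, {
    out <- purrr::map(groups, function(g) {
      shift <- -log2(fold_changes[[g]])
      tibble(
        sample_id = paste0(g, "_", seq_len(n_per_group)),
        group = g, target = target,
        ct_target = ct_base + shift + rnorm(n_per_group, 0, noise_sd),
        ct_normalizer = normalizer_base + rnorm(n_per_group, 0, noise_sd))
    })
  })
  dplyr::bind_rows(out)
}
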