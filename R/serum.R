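#' Atherogenic lipid ratios
#'
#' Computes the three lipid-ratio cardiovascular-risk markers from a serum
#' panel: Castelli's Risk Index I (`CRI_I = TC / HDLc`), Castelli's Risk
#' Index II (`CRI_II = LDLc / HDLc`) and the atherogenic coefficient
#' (`AC = (TC - HDLc) / HDLc`). The ratios are unit-free: any consistent
#' concentration unit (mg/dL assumed) gives the same values.
#'
#' @param panel Data frame with one row per animal and columns `TC`, `LDLc`,
#'   `HDLc` (all >= 0, `HDLc` > 0); an `animal_id` column is carried through
#'   and used in error messages.
#'
#' @return `panel` as a tibble with `CRI_I`, `CRI_II`, `AC` columns added.
#' @export
#' @examples
#' atherogenic_ratios(tibble::tibble(animal_id = "r1", TC = 200,
#'                                   LDLc = 120, HDLc = 50))
atherogenic_ratios <- function(panel) {
  check_df_cols(panel, c("TC", "LDLc", "HDLc"))
  bad <- which(!is.finite(panel$HDLc) | panel$HDLc <= 0)
  if (length(bad)) {
    who <- if ("animal_id" %in% names(panel)) {
      paste(panel$animal_id[bad], collapse = ", ")
    } else {
      paste("row", paste(bad, collapse = ", "))
    }
    abort(sprintf("HDLc must be > 0 to form ratios; offending animal(s): %s.",
                  who))
  }
  if (any(panel$TC < 0 | panel$LDLc < 0, na.rm = TRUE)) {
    abort("Concentrations must be non-negative.")
  }
  dplyr::mutate(as_tibble(panel),
                CRI_I = .data$TC / .data$HDLc,
                CRI_II = .data$LDLc / .data$HDLc,
                AC = (.data$TC - .data$HDLc) / .data$HDLc)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample and target: `dCt = Ct(target) - Ct(normalizer)` (the spike-in
#' reference), `ddCt = dCt - mean dCt of the reference group` for that
#' target, and `fold = 2^-ddCt`. Technical replicate rows (same sample and
#' target) are averaged at the Ct level first, the standard qPCR practice.
#' Because the reference mean is subtracted in cycle space, the geometric
#' mean of reference-group folds is exactly 1.
#'
#' @param records Data frame with columns `sample_id`, `group`, `target`,
#'   `ct_target`, `ct_normalizer`.
#' @param reference_group Calibrator group; must contain samples for every
#'   target present.
#'
#' @return Tibble: `sample_id`, `group`, `target`, `dct`, `ddct`, `fold`.
#' @export
#' @examples
#' ct <- sim_ct_table(c(control = 1, NAFLD = 0.5), "control",
#'                    seed = 2, noise_sd = 0)
#' fold_change_ddct(ct, "control")
fold_change_ddct <- function(records, reference_group) {
  check_df_cols(records,
                c("sample_id", "group", "target", "ct_target", "ct_normalizer"))
  if (!reference_group %in% records$group) {
    abort(sprintf("Reference group '%s' has no samples.", reference_group))
  }
  if (any(records$ct_target < 10 | records$ct_target > 40, na.rm = TRUE)) {
    warn("Some target Ct values fall outside the typical 10-40 cycle range.")
  }
  dct <- records |>
    dplyr::group_by(.data$sample_id, .data$group, .data$target) |>
    dplyr::summarise(dct = mean(.data$ct_target) - mean(.data$ct_normalizer),
                     .groups = "drop")
  ref <- dct |>
    dplyr::filter(.data$group == reference_group) |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(ref_dct = mean(.data$dct), .groups = "drop")
  missing <- setdiff(unique(dct$target), ref$target)
  if (length(missing)) {
    abort(sprintf("Target(s) absent from the reference group: %s.",
                  paste(missing, collapse = ", ")))
  }
  dct |>
    dplyr::left_join(ref, by = "target") |>
    dplyr::mutate(ddct = .data$dct - .data$ref_dct,
                  fold = 2^(-.data$ddct)) |>
    dplyr::select(!"ref_dct")
}
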