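#' Default study design for the synthetic pipeline
#'
#' Five diet/treatment groups with per-group generator settings: the
#' morphometric class mixture (percent-normal anchored to the study design:
#' lowest in the untreated disease group), per-animal liver collagen
#' fraction, serum lipid panel locations (mg/dL) and circulating-miRNA fold
#' changes versus the control group. These are realism anchors for
#' validation, not reproduction targets — the source study deposits no raw
#' data.
#'
#' @return A named list, one element per group.
#' @export
default_study_groups <- function() {
  list(
    "control" = list(
      mixture = c(N = .73, HR = .16, AR = .05, I = .03, HI = .02, AI = .01),
      collagen = 0.045,
      lipids = c(TC = 70, LDLc = 20, HDLc = 35, TG = 60),
      folds = c("miR-122" = 1, "miR-33a" = 1, "miR-186" = 1, "miR-126" = 1)),
    "NAFLD" = list(
      mixture = c(N = .67, HR = .26, AR = .02, I = .02, HI = .02, AI = .01),
      collagen = 0.099,
      lipids = c(TC = 120, LDLc = 55, HDLc = 28, TG = 110),
      folds = c("miR-122" = 4, "miR-33a" = 3, "miR-186" = 2.5,
                "miR-126" = 0.6)),
    "NAFLD+LOLA" = list(
      mixture = c(N = .76, HR = .16, AR = .03, I = .02, HI = .02, AI = .01),
      collagen = 0.037,
      lipids = c(TC = 100, LDLc = 40, HDLc = 30, TG = 90),
      folds = c("miR-122" = 1.8, "miR-33a" = 1.5, "miR-186" = 1.2,
                "miR-126" = 0.7)),
    "NAFLD+VitE" = list(
      mixture = c(N = .81, HR = .14, AR = .02, I = .01, HI = .01, AI = .01),
      collagen = 0.081,
      lipids = c(TC = 105, LDLc = 45, HDLc = 29, TG = 95),
      folds = c("miR-122" = 3.5, "miR-33a" = 2.8, "miR-186" = 2.2,
                "miR-126" = 0.6)),
    "NAFLD+LOLA+VitE" = list(
      mixture = c(N = .75, HR = .17, AR = .03, I = .02, HI = .02, AI = .01),
      collagen = 0.042,
      lipids = c(TC = 80, LDLc = 25, HDLc = 33, TG = 70),
      folds = c("miR-122" = 1.2, "miR-33a" = 1.1, "miR-186" = 1,
                "miR-126" = 1.3)))
}

#' Run the full synthetic study pipeline
#'
#' Drives every stage end to end on generated data: cell fields per animal
#' (render, extract, measure), control-referenced thresholds and
#' classification, per-animal population profiles, collagen fields and
#' scores, serum lipid panels and atherogenic ratios, Ct tables and
#' `2^-ddCt` fold changes, and the normality-gated group statistics with a
#' formatted report. All randomness derives from `seed`; with a fixed seed
#' two runs write byte-identical CSVs.
#'
#' @param seed Integer seed (required).
#' @param out_dir Directory for CSV/JSON outputs; `NULL` skips writing.
#' @param groups Study design as in [default_study_groups()].
#' @param n_animals Animals per group.
#' @param cells_per_animal Cardiomyocytes measured per animal.
#' @param fields_per_animal Collagen fields imaged per animal.
#' @param lipid_cv Coefficient of variation of the serum lipid draws.
#' @param ct_noise_sd Ct noise SD in cycles.
#' @param collagen_dim Collagen field size in px.
#'
#' @return (Invisibly) a named list of the result tibbles.
#' @export
run_study_pipeline <- function(seed, out_dir = NULL,
                               groups = default_study_groups(),
                               n_animals = 4, cells_per_animal = 60,
                               fields_per_animal = 4, lipid_cv = 0.08,
                               ct_noise_sd = 0.2,
                               collagen_dim = c(192, 192)) {
  seed <- check_seed(seed)
  gnames <- names(groups)
  seeds <- child_seeds(seed, 6)

  # --- morphometry: one field per animal -------------------------------
  animal_tbl <- tidyr::expand_grid(group = gnames,
                                   animal = seq_len(n_animals)) |>
    dplyr::mutate(animal_id = paste0(.data$group, "_", .data$animal))
  cell_seeds <- child_seeds(seeds[1], nrow(animal_tbl))
  cells <- purrr::pmap(
    list(animal_tbl$group, animal_tbl$animal_id, cell_seeds),
    function(grp, aid, s) {
      spec <- cell_population_spec(groups[[grp]]$mixture,
                                   n_cells = cells_per_animal, seed = s)
      field <- render_field(sample_cell_truth(spec))
      suppressMessages(measure_cells(field)) |>
        dplyr::mutate(group = grp, animal_id = aid, .before = 1)
    }) |>
    dplyr::bind_rows()

  thresholds <- derive_thresholds(dplyr::filter(cells, .data$group == gnames[1]))
  cells <- classify_cells(cells, thresholds)
  profiles <- cells |>
    dplyr::group_by(.data$group, .data$animal_id) |>
    dplyr::group_modify(~ suppressWarnings(population_profile(.x))) |>
    dplyr::ungroup()

  # --- collagen ---------------------------------------------------------
  col_tbl <- tidyr::expand_grid(animal_tbl, field = seq_len(fields_per_animal))
  col_seeds <- child_seeds(seeds[2], nrow(col_tbl) + 1)
  frac_jitter <- withr::with_seed(col_seeds[1],
                                  rnorm(nrow(col_tbl), 0, 0.008))
  collagen_fields <- purrr::pmap(
    list(col_tbl$group, col_tbl$animal_id, col_tbl$field,
         col_seeds[-1], frac_jitter),
    function(grp, aid, fid, s, jit) {
      tf <- min(max(groups[[grp]]$collagen + jit, 0.005), 0.95)
      quantify_collagen_field(sim_collagen_field(tf, seed = s,
                                                 dim = collagen_dim),
                              field_id = fid) |>
        dplyr::mutate(group = grp, animal_id = aid, .before = 1)
    }) |>
    dplyr::bind_rows()
  collagen_animals <- suppressWarnings(collagen_score(collagen_fields)) |>
    dplyr::left_join(dplyr::distinct(collagen_fields, .data$animal_id,
                                     .data$group),
                     by = "animal_id") |>
    dplyr::relocate("group")

  # --- serum lipids and atherogenic ratios ------------------------------
  lipid_specs <- purrr::imap(groups, function(g, nm) {
    tibble(group = nm, analyte = names(g$lipids),
           location = unname(g$lipids),
           scale = lipid_cv * unname(g$lipids),
           family = "symmetric", n_animals = n_animals)
  }) |>
    dplyr::bind_rows()
  serum <- sim_serum_panel(lipid_specs, seed = seeds[3])
  panel <- tidyr::pivot_wider(serum, names_from = "analyte",
                              values_from = "value")
  ratios <- atherogenic_ratios(panel)

  # --- circulating miRNAs ----------------------------------------------
  targets <- names(groups[[1]]$folds)
  ct_seeds <- child_seeds(seeds[4], length(targets))
  ct <- purrr::map2(targets, ct_seeds, function(tg, s) {
    folds <- vapply(groups, function(g) g$folds[[tg]], numeric(1))
    sim_ct_table(setNames(folds, gnames), reference_group = gnames[1],
                 seed = s, target = tg, n_per_group = n_animals,
                 noise_sd = ct_noise_sd)
  }) |>
    dplyr::bind_rows()
  folds <- fold_change_ddct(ct, reference_group = gnames[1])

  # --- group statistics -------------------------------------------------
  stat_input <- ratios |>
    dplyr::select("group", "animal_id", "CRI_I", "CRI_II", "AC") |>
    dplyr::left_join(dplyr::select(profiles, "animal_id", "percent_N",
                                   "mean_cii", "area_variability"),
                     by = "animal_id") |>
    dplyr::left_join(dplyr::select(collagen_animals, "animal_id",
                                   collagen = "score"),
                     by = "animal_id") |>
    dplyr::left_join(
      folds |>
        dplyr::mutate(target = paste0("fold_", gsub("-", "_", .data$target))) |>
        dplyr::select("sample_id", "target", "fold") |>
        tidyr::pivot_wider(names_from = "target", values_from = "fold"),
      by = c("animal_id" = "sample_id"))
  comparison <- compare_groups(stat_input, group = "group")
  report <- report_table(comparison)

  results <- list(cells = cells, thresholds = thresholds,
                  profiles = profiles, collagen_fields = collagen_fields,
                  collagen_animals = collagen_animals, serum = serum,
                  ratios = ratios, ct = ct, folds = folds,
                  stat_input = stat_input, comparison = comparison,
                  report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) readr::write_csv(df, file.path(out_dir, f))
    wr(cells, "cells.csv")
    wr(profiles, "profiles.csv")
    wr(collagen_fields, "collagen_fields.csv")
    wr(collagen_animals, "collagen_animals.csv")
    wr(serum, "serum.csv")
    wr(ratios, "ratios.csv")
    wr(ct, "ct.csv")
    wr(folds, "mirna_folds.csv")
    wr(tidy(comparison), "pairwise.csv")
    wr(glance(comparison), "omnibus.csv")
    wr(report, "report.csv")
    jsonlite::write_json(
      list(area_low = thresholds$area_low, area_high = thresholds$area_high,
           cii_high = thresholds$cii_high, source = thresholds$source),
      file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(results)
}
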