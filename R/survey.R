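# Survey data model: stratified plot records and importance values.

survey_columns <- c(
  "plot_id", "stage", "layer", "species",
  "count", "dominance", "subplot_hits", "n_subplots"
)

covariate_columns <- c("plot_id", "cover", "pH", "TOC", "TN", "TP")

#' Read a stratified vegetation survey table
#'
#' Reads a delimited text file of per-plot, per-layer species records and
#' validates it against the survey data model: one row per
#' (plot, layer, species), with an individual (or ramet) count, a
#' dominance measure (basal area for the tree layer, percent cover for
#' shrub and herb layers), and subplot occurrence counts used for
#' relative frequency.
#'
#' @param path Path to a CSV/TSV file with columns `plot_id`, `stage`,
#'   `layer`, `species`, `count`, `dominance`, `subplot_hits`,
#'   `n_subplots`.
#' @return A tibble of validated records; `stage` is a factor ordered
#'   BF < LM < HM < MB.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("survey file '%s' does not exist", path))
  }
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  validate_survey(as_tibble(df))
}

#' Validate a survey tibble
#'
#' Checks column presence, enum levels, duplicate (plot, layer, species)
#' rows, and numeric invariants (`count >= 1`, `dominance >= 0`,
#' `subplot_hits <= n_subplots`).
#'
#' @param survey A data frame of survey records.
#' @return The validated tibble with `stage` as an ordered factor.
#' @export
validate_survey <- function(survey) {
  survey <- as_tibble(survey)
  missing <- setdiff(survey_columns, names(survey))
  if (length(missing) > 0) {
    stop_format(sprintf(
      "survey is missing required column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  bad_stage <- setdiff(unique(as.character(survey$stage)), .stages)
  if (length(bad_stage) > 0) {
    stop_validation(sprintf(
      "unknown stage value(s): %s (expected %s)",
      paste(bad_stage, collapse = ", "), paste(.stages, collapse = ", ")
    ))
  }
  bad_layer <- setdiff(unique(as.character(survey$layer)), .layers)
  if (length(bad_layer) > 0) {
    stop_validation(sprintf(
      "unknown layer value(s): %s (expected %s)",
      paste(bad_layer, collapse = ", "), paste(.layers, collapse = ", ")
    ))
  }
  dup <- survey |>
    count(.data$plot_id, .data$layer, .data$species) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_validation(sprintf(
      "duplicate (plot, layer, species) row(s), e.g. %s / %s / %s",
      dup$plot_id[1], dup$layer[1], dup$species[1]
    ))
  }
  if (any(!is.finite(survey$count)) || any(survey$count < 1)) {
    stop_validation("`count` must be >= 1 for every record")
  }
  if (any(!is.finite(survey$dominance)) || any(survey$dominance < 0)) {
    stop_validation("`dominance` must be a finite non-negative number")
  }
  if (any(!is.finite(survey$subplot_hits)) || any(survey$subplot_hits < 0) ||
      any(!is.finite(survey$n_subplots)) || any(survey$n_subplots < 1)) {
    stop_validation("subplot counts must be finite, hits >= 0, totals >= 1")
  }
  if (any(survey$subplot_hits > survey$n_subplots)) {
    stop_validation("`subplot_hits` cannot exceed `n_subplots`")
  }
  survey |>
    mutate(
      stage = factor(as.character(.data$stage), levels = .stages),
      layer = as.character(.data$layer)
    )
}

#' Read plot-level covariates
#'
#' Reads invader cover (fraction in `[0, 1]`) and soil chemistry (pH,
#' total organic carbon, total nitrogen, total phosphorus, g/kg) keyed by
#' plot.
#'
#' @param path Path to a CSV with columns `plot_id`, `cover`, `pH`,
#'   `TOC`, `TN`, `TP` (and optionally `stage`).
#' @return A tibble with one row per plot.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("covariate file '%s' does not exist", path))
  }
  df <- as_tibble(readr::read_delim(path, show_col_types = FALSE, progress = FALSE))
  validate_covariates(df)
}

#' @rdname read_covariates
#' @param covariates A data frame of plot covariates to validate.
#' @export
validate_covariates <- function(covariates) {
  covariates <- as_tibble(covariates)
  missing <- setdiff(covariate_columns, names(covariates))
  if (length(missing) > 0) {
    stop_format(sprintf(
      "covariates are missing required column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(covariates$plot_id)) {
    stop_validation("duplicate plot_id in covariates")
  }
  num <- covariates[setdiff(covariate_columns, "plot_id")]
  if (!all(vapply(num, is.numeric, logical(1))) ||
      !all(complete.cases(num)) || !all(is.finite(as.matrix(num)))) {
    stop_validation("all covariates must be finite numbers")
  }
  if (any(covariates$cover < 0 | covariates$cover > 1)) {
    stop_validation("`cover` must lie in [0, 1]")
  }
  if ("stage" %in% names(covariates)) {
    covariates$stage <- factor(as.character(covariates$stage), levels = .stages)
  }
  covariates
}

#' Species importance values within plot and layer
#'
#' For every (plot, layer) the importance value of a species is the mean
#' of its relative density (share of individuals), relative dominance
#' (share of basal area or cover) and relative frequency (share of the
#' summed per-species subplot frequencies), each expressed in percent.
#' The tree layer is surveyed at whole-plot grain, so every tree species
#' has frequency 1 and relative frequency 100/S.
#'
#' @param survey A validated survey tibble (see [read_survey()]).
#' @param layers Layers to compute; defaults to all three.
#' @return A tibble with one row per (plot, layer, species) holding
#'   `rel_density`, `rel_dominance`, `rel_frequency` and `iv`, all in
#'   percent. Within each (plot, layer) each component and `iv` sum
#'   to 100.
#' @export
importance_values <- function(survey, layers = survey_layers()) {
  survey <- validate_survey(survey)
  for (l in layers) check_layer(l)
  recs <- survey |> filter(.data$layer %in% layers)
  if (nrow(recs) == 0) {
    return(tibble(
      plot_id = character(), stage = factor(character(), levels = .stages),
      layer = character(), species = character(),
      rel_density = double(), rel_dominance = double(),
      rel_frequency = double(), iv = double()
    ))
  }
  recs |>
    mutate(
      frequency = ifelse(.data$layer == "tree", 1,
                         .data$subplot_hits / .data$n_subplots)
    ) |>
    group_by(.data$plot_id, .data$stage, .data$layer) |>
    group_modify(function(g, key) {
      tot_n <- sum(g$count)
      tot_dom <- sum(g$dominance)
      tot_freq <- sum(g$frequency)
      if (tot_dom <= 0 && tot_n > 0) {
        stop_validation(sprintf(
          "degenerate survey: zero total dominance with nonzero counts in plot '%s' layer '%s'",
          key$plot_id, key$layer
        ))
      }
      if (tot_freq <= 0) {
        stop_validation(sprintf(
          "degenerate survey: zero total frequency in plot '%s' layer '%s'",
          key$plot_id, key$layer
        ))
      }
      tibble(
        species = g$species,
        rel_density = 100 * g$count / tot_n,
        rel_dominance = 100 * g$dominance / tot_dom,
        rel_frequency = 100 * g$frequency / tot_freq
      )
    }) |>
    ungroup() |>
    mutate(iv = (.data$rel_density + .data$rel_dominance + .data$rel_frequency) / 3) |>
    arrange(.data$plot_id, .data$layer, dplyr::desc(.data$iv), .data$species)
}

#' Stage-mean importance values
#'
#' Averages per-plot importance values over the replicate plots of each
#' expansion stage, counting a species as IV = 0 in plots where it is
#' absent. This is the species-by-stage matrix behind IV heatmaps and
#' the stage-occurrence filter of the Resistance Index.
#'
#' @param iv An importance-value tibble from [importance_values()].
#' @param layer A single layer to summarise.
#' @param plots Optional tibble of `plot_id`, `stage` giving the full
#'   plot design (needed when some plots have no records in `layer`);
#'   defaults to the plots present in `iv` across all layers.
#' @return A wide tibble `species` x stage (columns BF, LM, HM, MB) of
#'   mean IV, rows ordered by descending overall mean then species name.
#' @export
stage_mean_iv <- function(iv, layer, plots = NULL) {
  check_layer(layer)
  if (is.null(plots)) {
    plots <- iv |> distinct(.data$plot_id, .data$stage)
  }
  plots <- plots |>
    mutate(stage = factor(as.character(.data$stage), levels = .stages))
  lay <- iv |> filter(.data$layer == !!layer)
  species <- sort(unique(lay$species))
  if (length(species) == 0) {
    return(tibble(species = character(), BF = double(), LM = double(),
                  HM = double(), MB = double()))
  }
  grid <- tidyr::expand_grid(plots |> select("plot_id", "stage"),
                             species = species)
  means <- grid |>
    left_join(lay |> select("plot_id", "species", "iv"),
              by = c("plot_id", "species")) |>
    mutate(iv = tidyr::replace_na(.data$iv, 0)) |>
    group_by(.data$species, .data$stage) |>
    summarise(mean_iv = mean(.data$iv), .groups = "drop")
  wide <- means |>
    tidyr::pivot_wider(names_from = "stage", values_from = "mean_iv",
                       values_fill = 0)
  for (s in setdiff(.stages, names(wide))) wide[[s]] <- 0
  wide |>
    mutate(overall = (.data$BF + .data$LM + .data$HM + .data$MB) / 4) |>
    arrange(dplyr::desc(.data$overall), .data$species) |>
    select("species", dplyr::all_of(.stages))
}
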