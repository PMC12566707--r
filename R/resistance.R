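# Phylogenetically weighted species Resistance Index: the Theil-Sen
# slope of a species' importance value against invader cover, divided by
# its patristic distance to the invader, z-standardized within layer.

#' Stage-occurrence filter for Resistance Index candidates
#'
#' A species enters the Resistance Index only if it occurs (stage-mean
#' IV > 0) in at least `min_stages` of the four expansion stages, so
#' that its IV-vs-cover series spans enough of the gradient.
#'
#' @param stage_means Numeric vector of the species' mean IV per stage
#'   (length 4, BF/LM/HM/MB).
#' @param min_stages Minimum number of occupied stages (default 3).
#' @return `TRUE` if the species passes the filter.
#' @export
stage_filter <- function(stage_means, min_stages = 3) {
  sum(stage_means > 0) >= min_stages
}

#' Theil-Sen slope of a species' IV along the cover gradient
#'
#' Plots where the species is absent contribute IV = 0 (required so that
#' monotone disappearance yields a negative slope).
#'
#' @param iv_by_plot Numeric vector of the species' IV per plot,
#'   including zeros for absent plots.
#' @param cover Invader cover per plot, scaled `[0, 1]`, same order.
#' @return The Theil-Sen slope (IV percent per unit cover).
#' @export
species_beta <- function(iv_by_plot, cover) {
  theil_sen(cover, iv_by_plot)$slope
}

#' Raw Resistance Index
#'
#' `RI = beta / D`, where `beta` is the species' IV-vs-cover Theil-Sen
#' slope and `D` its patristic distance to the invader. Dividing by
#' distance weights the trend by evolutionary proximity: a decline in a
#' close relative of the invader yields a more negative RI than the same
#' decline in a distant one.
#'
#' @param beta Theil-Sen IV slope (percent per unit cover).
#' @param dist Patristic distance to the invader, strictly positive.
#' @return `beta / dist`.
#' @export
resistance_index <- function(beta, dist) {
  if (any(!is.finite(dist)) || any(dist <= 0)) {
    stop_validation("`dist` must be strictly positive (the invader itself is excluded)")
  }
  beta / dist
}

#' Standardize raw RI within layer and classify
#'
#' z-standardizes `ri_raw` within each layer using the sample standard
#' deviation (ddof = 1) and classifies species as `Resistant`
#' (`ri_z >= +1`), `Susceptible` (`ri_z <= -1`) or `Neutral`. A layer
#' with zero RI spread is degenerate: all species are Neutral with
#' `ri_z = NA` and `degenerate = TRUE`.
#'
#' @param records A tibble with at least `layer` and `ri_raw` columns.
#' @return The tibble with `ri_z`, `klass` and `degenerate` columns
#'   added.
#' @export
standardize_and_classify <- function(records) {
  records |>
    group_by(.data$layer) |>
    group_modify(function(g, key) {
      if (sum(is.finite(g$ri_raw)) < 2) {
        stop_validation(sprintf(
          "layer '%s' needs >= 2 species with finite raw RI", key$layer
        ))
      }
      s <- sd(g$ri_raw)
      if (s == 0) {
        g$ri_z <- NA_real_
        g$klass <- "Neutral"
        g$degenerate <- TRUE
      } else {
        g$ri_z <- (g$ri_raw - mean(g$ri_raw)) / s
        g$klass <- dplyr::case_when(
          g$ri_z >= 1 ~ "Resistant",
          g$ri_z <= -1 ~ "Susceptible",
          TRUE ~ "Neutral"
        )
        g$degenerate <- FALSE
      }
      g
    }) |>
    ungroup()
}

#' Species Resistance Index along an invader expansion gradient
#'
#' The full species-level analysis: for every species of each layer that
#' occurs in at least `min_stages` expansion stages, compute the
#' Theil-Sen slope of its IV against invader cover over all plots
#' (IV = 0 where absent), divide by its patristic distance to the
#' invader, then z-standardize within layer and classify with the
#' +/-1 thresholds. The invader itself is excluded.
#'
#' @param iv Importance values from [importance_values()].
#' @param covariates Plot covariates with `plot_id` and `cover` (see
#'   [read_covariates()]).
#' @param tree Phylogeny containing the surveyed species and the
#'   invader.
#' @param invader Tip label of the focal invader.
#' @param layers Layers to analyse.
#' @param min_stages Stage-occurrence filter threshold (default 3).
#' @param stage_means_beta If `TRUE`, compute the slope over the 4
#'   stage-mean IVs instead of all plots (sensitivity analysis; default
#'   `FALSE`).
#' @return A tibble with one row per retained species: `species`,
#'   `layer`, `beta`, `dist_to_invader`, `ri_raw`, `ri_z`, `klass`,
#'   `n_stages_present`, plus a `metadata` attribute recording the
#'   filter, ddof and cover scaling. Species failing the filter are
#'   listed in the `skipped` attribute.
#' @export
resistance_scores <- function(iv, covariates, tree, invader,
                              layers = survey_layers(), min_stages = 3,
                              stage_means_beta = FALSE) {
  covariates <- validate_covariates(covariates)
  validate_tree(tree)
  if (!invader %in% tree$tip.label) {
    stop_lookup(sprintf("invader '%s' not found in tree", invader))
  }
  plots <- covariates |> select("plot_id", "cover")
  design <- iv |> distinct(.data$plot_id, .data$stage)

  out <- list()
  skipped <- list()
  for (lay in layers) {
    lay_iv <- iv |>
      filter(.data$layer == lay, .data$species != invader)
    if (nrow(lay_iv) == 0) next
    sp <- sort(unique(lay_iv$species))
    check_tips(tree, sp)
    dists <- patristic_distances(tree, c(sp, invader))[sp, invader]
    sm <- stage_mean_iv(lay_iv |> mutate(layer = lay), lay, plots = design)
    rows <- purrr::map(sp, function(s) {
      stage_means <- as.numeric(sm[sm$species == s, .stages])
      n_pres <- sum(stage_means > 0)
      if (!stage_filter(stage_means, min_stages)) {
        return(tibble(species = s, layer = lay, n_stages_present = n_pres,
                      reason = sprintf("present in %d < %d stages", n_pres, min_stages)))
      }
      if (stage_means_beta) {
        stage_cover <- design |>
          left_join(plots, by = "plot_id") |>
          group_by(.data$stage) |>
          summarise(cover = mean(.data$cover), .groups = "drop")
        beta <- species_beta(stage_means[match(stage_cover$stage, .stages)],
                             stage_cover$cover)
      } else {
        series <- plots |>
          left_join(lay_iv |> filter(.data$species == s) |>
                      select("plot_id", "iv"),
                    by = "plot_id") |>
          mutate(iv = tidyr::replace_na(.data$iv, 0))
        beta <- species_beta(series$iv, series$cover)
      }
      tibble(species = s, layer = lay, beta = beta,
             dist_to_invader = unname(dists[s]),
             ri_raw = resistance_index(beta, unname(dists[s])),
             n_stages_present = n_pres)
    })
    keep <- purrr::keep(rows, ~ !"reason" %in% names(.x))
    skipped[[lay]] <- bind_rows(purrr::keep(rows, ~ "reason" %in% names(.x)))
    if (length(keep) > 0) out[[lay]] <- bind_rows(keep)
  }
  res <- bind_rows(out)
  if (nrow(res) > 0) {
    res <- standardize_and_classify(res) |>
      select("species", "layer", "beta", "dist_to_invader", "ri_raw",
             "ri_z", "klass", "n_stages_present", "degenerate") |>
      arrange(.data$layer, .data$ri_z)
  }
  attr(res, "skipped") <- bind_rows(skipped)
  attr(res, "metadata") <- list(
    invader = invader, min_stages = min_stages, ddof = 1,
    cover_scale = "[0,1]", absent_iv = 0,
    beta_basis = if (stage_means_beta) "stage means" else "all plots"
  )
  res
}
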