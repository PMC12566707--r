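# End-to-end orchestration: generate (or load) -> IV -> diversity ->
# phylogenetic structure -> trends -> resistance -> ordination, writing
# an append-only run directory with a machine-readable manifest.

#' Run the full gradient analysis pipeline
#'
#' Runs every stage of the analysis on either a synthetic gradient
#' (default) or user-supplied files, and writes tidy CSV/JSON outputs
#' plus a manifest recording the configuration, seeds and output
#' checksums. Reruns with the same inputs and seed are identical.
#'
#' @param out_dir Output directory (created; existing stage outputs are
#'   never overwritten by later stages).
#' @param config A [gradient_config()] used when no survey files are
#'   given.
#' @param survey,covariates,tree Optional paths (or in-memory objects)
#'   for the survey records, plot covariates and phylogeny; all three
#'   must be given together.
#' @param invader Invader tip label (defaults to the config's).
#' @param n_rand Null-model randomizations for NRI/NTI (default 999).
#' @param n_perm RDA permutations (default 999).
#' @param seed Top-level seed for the stochastic stages (default: the
#'   config seed).
#' @param include_root,include_invader,min_stages,prune_missing Stage
#'   options; see [faith_pd()], [importance_values()],
#'   [resistance_scores()], [phylo_structure()].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         config = gradient_config(),
                         survey = NULL, covariates = NULL, tree = NULL,
                         invader = NULL,
                         n_rand = 999, n_perm = 999, seed = NULL,
                         include_root = TRUE, include_invader = TRUE,
                         min_stages = 3, prune_missing = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- seed %||% config$seed
  invader <- invader %||% config$invader_name

  supplied <- !vapply(list(survey, covariates, tree), is.null, logical(1))
  if (any(supplied) && !all(supplied)) {
    stop_validation("supply `survey`, `covariates` and `tree` together, or none")
  }
  if (all(supplied)) {
    if (is.character(survey)) survey <- read_survey(survey)
    if (is.character(covariates)) covariates <- read_covariates(covariates)
    if (is.character(tree)) tree <- read_tree(tree)
    survey <- validate_survey(survey)
    covariates <- validate_covariates(covariates)
    truth <- NULL
  } else {
    dat <- generate_gradient(config)
    survey <- dat$survey; covariates <- dat$covariates; tree <- dat$tree
    truth <- dat$truth
    write_gradient(dat, out_dir)
  }
  surveyed <- unique(survey$species)
  absent <- setdiff(surveyed, tree$tip.label)
  if (length(absent) > 0 && !prune_missing) {
    stop_lookup(sprintf(
      "species absent from tree (use prune_missing = TRUE to drop them from phylogenetic metrics): %s",
      paste(absent, collapse = ", ")
    ))
  }

  log_line <- function(stage, file) {
    message(sprintf("[%s] wrote %s (md5 %s)", stage, file,
                    unname(tools::md5sum(file))))
  }
  outputs <- character(0)
  emit_csv <- function(x, name, stage) {
    f <- file.path(out_dir, name)
    readr::write_csv(x, f)
    outputs[[name]] <<- unname(tools::md5sum(f))
    log_line(stage, f)
  }

  # importance values (optionally dropping the invader's own rows)
  iv <- importance_values(survey)
  if (!include_invader) {
    iv_no_inv <- survey |> filter(.data$species != invader)
    iv <- importance_values(iv_no_inv)
  }
  emit_csv(iv, "importance_values.csv", "iv")
  design <- survey |> distinct(.data$plot_id, .data$stage)
  for (lay in intersect(survey_layers(), unique(iv$layer))) {
    emit_csv(stage_mean_iv(iv, lay, plots = design),
             sprintf("stage_mean_iv_%s.csv", lay), "iv")
  }

  diversity <- alpha_diversity(survey)
  emit_csv(diversity, "alpha_diversity.csv", "diversity")

  phylo <- phylo_structure(survey, tree, n_rand = n_rand, seed = seed,
                           include_root = include_root,
                           prune_missing = prune_missing)
  emit_csv(phylo, "phylo_structure.csv", "phylo")

  # gradient trends per (layer, index), BH-adjusted within layer
  metrics <- diversity |>
    left_join(phylo |> select("plot_id", "layer", "pd", "nri", "nti"),
              by = c("plot_id", "layer")) |>
    left_join(covariates |> select("plot_id", "cover"), by = "plot_id") |>
    tidyr::pivot_longer(cols = c("richness", "margalef", "simpson", "shannon",
                                 "pielou", "pd", "nri", "nti"),
                        names_to = "index", values_to = "value") |>
    filter(is.finite(.data$value))
  trends <- metrics |>
    group_by(.data$layer, .data$index) |>
    group_modify(~ trend_test(.x$cover, .x$value)) |>
    ungroup() |>
    group_by(.data$layer) |>
    mutate(p_adjusted = bh_fdr(.data$p_value)) |>
    ungroup()
  emit_csv(trends, "trends.csv", "trends")

  stage_tests <- metrics |>
    group_by(.data$layer, .data$index) |>
    group_modify(function(g, key) {
      kd <- kruskal_dunn(g$value, g$stage)
      dplyr::bind_cols(glance(kd) |> select(-"alpha"),
                       tidy(kd) |> tidyr::nest(pairwise = dplyr::everything()))
    }) |>
    ungroup() |>
    tidyr::unnest("pairwise")
  emit_csv(stage_tests, "stage_tests.csv", "trends")

  resistance <- resistance_scores(iv |> filter(!.data$species %in% absent),
                                  covariates, tree, invader,
                                  min_stages = min_stages)
  emit_csv(resistance, "resistance.csv", "resistance")

  # ordination per layer: Shannon, PD, NTI on cover + soil
  ord <- list(); vpa <- list()
  for (lay in intersect(survey_layers(), unique(diversity$layer))) {
    Y <- metrics |>
      filter(.data$layer == lay, .data$index %in% c("shannon", "pd", "nti")) |>
      tidyr::pivot_wider(id_cols = "plot_id", names_from = "index",
                         values_from = "value") |>
      arrange(match(.data$plot_id, covariates$plot_id))
    X <- covariates |>
      filter(.data$plot_id %in% Y$plot_id) |>
      arrange(match(.data$plot_id, Y$plot_id))
    Ym <- Y |> select(-"plot_id")
    if (nrow(Ym) < 8 || any(vapply(Ym, sd, numeric(1)) == 0)) next
    fit <- rda_gradient(Ym, X |> select("cover", "pH", "TOC", "TN", "TP"),
                        n_perm = n_perm, seed = child_seed(seed, paste("rda", lay)))
    ord[[lay]] <- fit
    f <- file.path(out_dir, sprintf("ordination_%s.json", lay))
    jsonlite::write_json(
      list(layer = lay, r2 = fit$r2, r2_adjusted = fit$r2_adjusted,
           global_p = fit$global_p, term_p = as.list(fit$term_p),
           vif = as.list(fit$vif),
           axis_percent = as.list(fit$explained_fraction_per_axis)),
      f, auto_unbox = TRUE, digits = NA
    )
    outputs[[basename(f)]] <- unname(tools::md5sum(f))
    log_line("ordination", f)
    vpa[[lay]] <- variance_partition(Ym, X$cover,
                                     X |> select("pH", "TOC", "TN", "TP")) |>
      mutate(layer = lay, .before = 1)
  }
  if (length(vpa) > 0) emit_csv(bind_rows(vpa), "vpa.csv", "ordination")

  manifest <- list(
    package = "phyloRI",
    version = as.character(utils::packageVersion("phyloRI")),
    r_version = as.character(getRversion()),
    seed = seed, n_rand = n_rand, n_perm = n_perm,
    include_root = include_root, include_invader = include_invader,
    min_stages = min_stages, prune_missing = prune_missing,
    invader = invader,
    synthetic = !all(supplied),
    config = if (all(supplied)) NULL else unclass(config)[
      c("seed", "reps_per_stage", "cover_means", "cover_jitter_sd",
        "species_per_layer", "iv_noise_sd", "presence_min")],
    outputs = as.list(outputs)
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, null = "null")
  log_line("manifest", mf)

  invisible(list(
    survey = survey, covariates = covariates, tree = tree, truth = truth,
    iv = iv, diversity = diversity, phylo = phylo, trends = trends,
    stage_tests = stage_tests, resistance = resistance,
    ordination = ord, vpa = if (length(vpa) > 0) bind_rows(vpa) else NULL,
    manifest = manifest, out_dir = out_dir
  ))
}
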