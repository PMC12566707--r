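# Synthetic invader-expansion gradient generator: 4 stages x 4 replicate
# plots, three species response archetypes, soil covariates trending
# with cover, and a random ultrametric phylogeny with the invader placed
# so that distances to it spread widely. Every dataset carries its
# ground truth for parameter-recovery tests.

#' Configuration for the synthetic gradient generator
#'
#' Defaults emulate a four-stage bamboo-expansion chronosequence:
#' 16 plots (4 stages x 4 replicates) with stage-mean invader cover
#' 0 / 0.30 / 0.70 / 1.0 (jitter sd 0.03, clipped to `[0, 1]`), soil
#' chemistry trending linearly with cover (pH rising ~0.85 units,
#' TOC falling ~13.7 g/kg, TN falling ~0.65 g/kg, TP flat), and species
#' pools of 20 tree / 30 shrub / 30 herb species. Tree-layer natives
#' all decline as the invader takes the canopy; shrub and herb layers
#' mix declining, neutral and increasing archetypes, with a few
#' "strong" species per side at the full slope magnitude
#' (-20 / +15 IV-percent per unit cover) and the rest mild. Archetypes
#' are assigned stratified over distance-to-invader quartiles so slope
#' and distance are not confounded.
#'
#' @param seed Integer master seed (default 20251021).
#' @param reps_per_stage Replicate plots per stage (default 4).
#' @param cover_means Stage-mean invader cover, strictly increasing.
#' @param cover_jitter_sd Plot-level cover jitter sd (default 0.03).
#' @param species_per_layer Named integer vector (tree, shrub, herb).
#' @param archetype_mix Named list per understory layer of
#'   (decliner, neutral, increaser) proportions summing to 1.
#' @param beta_decline,beta_increase Full-magnitude archetype slopes in
#'   IV percent per unit cover (defaults 20 and 15).
#' @param n_strong Number of full-magnitude species per archetype side
#'   and layer (default 3).
#' @param mild_range Slope magnitude of non-strong archetype species as
#'   a fraction of the full magnitude (default `c(0.05, 0.3)`).
#' @param iv_noise_sd Plot-level IV noise sd in IV points (default 1).
#' @param presence_min IV percent below which a species is absent from a
#'   plot (default 0.5).
#' @param soil_model Data frame with columns `variable`, `intercept`
#'   (value at cover 0), `slope` (change from cover 0 to 1) and `sd`
#'   (plot noise).
#' @param tree_scale Branch-length multiplier applied to the coalescent
#'   tree (default 200, giving distances on the order of a dated
#'   phylogeny in Myr).
#' @param invader_name Tip label of the focal invader.
#' @param n_subplots Subplots per layer for the frequency component
#'   (tree surveyed at whole-plot grain).
#' @param total_count,total_dominance Per-layer totals used to back-solve
#'   counts and dominance from target IV shares.
#' @param min_dist_ratio Required max/min ratio of within-layer
#'   distances to the invader (default 4); tree generation retries until
#'   met.
#' @return A list of class `gradient_config`.
#' @export
gradient_config <- function(
    seed = 20251021,
    reps_per_stage = 4,
    cover_means = c(BF = 0, LM = 0.30, HM = 0.70, MB = 1.0),
    cover_jitter_sd = 0.03,
    species_per_layer = c(tree = 20, shrub = 30, herb = 30),
    archetype_mix = list(
      shrub = c(decliner = 0.3, neutral = 0.4, increaser = 0.3),
      herb = c(decliner = 0.2, neutral = 0.2, increaser = 0.6)
    ),
    beta_decline = 20,
    beta_increase = 15,
    n_strong = 3,
    mild_range = c(0.05, 0.3),
    iv_noise_sd = 1,
    presence_min = 0.5,
    soil_model = data.frame(
      variable = c("pH", "TOC", "TN", "TP"),
      intercept = c(4.39, 30.74, 2.13, 0.22),
      slope = c(0.85, -13.67, -0.65, 0.01),
      sd = c(0.13, 1.97, 0.18, 0.045)
    ),
    tree_scale = 200,
    invader_name = "invader",
    n_subplots = c(tree = 1, shrub = 5, herb = 25),
    total_count = c(tree = 80, shrub = 300, herb = 500),
    total_dominance = c(tree = 2500, shrub = 120, herb = 90),
    min_dist_ratio = 4) {
  if (any(diff(cover_means) <= 0)) {
    stop_validation("`cover_means` must be strictly increasing")
  }
  for (mx in archetype_mix) {
    if (abs(sum(mx) - 1) > 1e-9 || any(mx < 0)) {
      stop_validation("each archetype mix must be non-negative and sum to 1")
    }
  }
  if (iv_noise_sd < 0 || cover_jitter_sd < 0 || any(soil_model$sd < 0)) {
    stop_validation("all noise sds must be >= 0")
  }
  structure(
    list(
      seed = as.integer(seed), reps_per_stage = reps_per_stage,
      cover_means = cover_means, cover_jitter_sd = cover_jitter_sd,
      species_per_layer = species_per_layer, archetype_mix = archetype_mix,
      beta_decline = beta_decline, beta_increase = beta_increase,
      n_strong = n_strong, mild_range = mild_range,
      iv_noise_sd = iv_noise_sd, presence_min = presence_min,
      soil_model = soil_model, tree_scale = tree_scale,
      invader_name = invader_name, n_subplots = n_subplots,
      total_count = total_count, total_dominance = total_dominance,
      min_dist_ratio = min_dist_ratio
    ),
    class = "gradient_config"
  )
}

#' Generate the community phylogeny for a synthetic gradient
#'
#' Simulates a random ultrametric (coalescent) tree over all species of
#' all layers plus the invader, scales branch lengths, and assigns
#' species names to tips stratified over distance-to-invader quartiles,
#' so that every layer spans near and far relatives (within-layer
#' max/min distance ratio at least `min_dist_ratio`; topology is
#' redrawn until satisfied).
#'
#' @param config A [gradient_config()].
#' @return An [ape::phylo] tree whose tip labels are
#'   `<layer>_sp<k>` plus the invader.
#' @export
generate_tree <- function(config) {
  stopifnot(inherits(config, "gradient_config"))
  spl <- config$species_per_layer
  n_sp <- sum(spl)
  if (n_sp < 2) stop_validation("need at least 2 species")
  withr::with_seed(child_seed(config$seed, "tree"), {
    for (try in 1:50) {
      tr <- ape::rcoal(n_sp + 1)
      tr$edge.length <- tr$edge.length * config$tree_scale
      d <- ape::cophenetic.phylo(tr)
      inv_tip <- tr$tip.label[1]
      dist_inv <- d[inv_tip, setdiff(tr$tip.label, inv_tip)]
      ord <- names(sort(dist_inv))
      q <- split(ord, cut(seq_along(ord), 4, labels = FALSE))
      # per-quartile layer allocation, proportional with remainder spread
      alloc <- sapply(q, function(tips) length(tips))
      labels <- character(0)
      tips_in_order <- character(0)
      remaining <- spl
      for (i in seq_along(q)) {
        quota <- round(spl * (length(q[[i]]) / n_sp) + 1e-9)
        # fix rounding so the quartile is exactly filled and pools not overdrawn
        quota <- pmin(quota, remaining)
        while (sum(quota) < length(q[[i]])) {
          j <- which.max(remaining - quota)
          quota[j] <- quota[j] + 1
        }
        while (sum(quota) > length(q[[i]])) {
          j <- which.max(quota)
          quota[j] <- quota[j] - 1
        }
        remaining <- remaining - quota
        lay_labels <- rep(names(spl), times = quota)
        labels <- c(labels, sample(lay_labels))
        tips_in_order <- c(tips_in_order, q[[i]])
      }
      # name species within layer in increasing-distance order
      new_names <- character(length(tips_in_order))
      idx <- setNames(rep(0L, length(spl)), names(spl))
      for (i in seq_along(tips_in_order)) {
        lay <- labels[i]
        idx[lay] <- idx[lay] + 1L
        new_names[i] <- sprintf("%s_sp%02d", lay, idx[lay])
      }
      relabel <- setNames(new_names, tips_in_order)
      tr$tip.label[match(tips_in_order, tr$tip.label)] <- relabel[tips_in_order]
      tr$tip.label[tr$tip.label == inv_tip] <- config$invader_name
      # check within-layer spread of distance to the invader
      d2 <- ape::cophenetic.phylo(tr)
      ok <- all(vapply(names(spl), function(lay) {
        dl <- d2[config$invader_name, grep(paste0("^", lay, "_sp"), tr$tip.label, value = TRUE)]
        max(dl) / min(dl) >= config$min_dist_ratio
      }, logical(1)))
      if (ok) return(validate_tree(tr))
    }
    stop_validation("could not generate a tree with the required distance spread")
  })
}

# Round-robin dealing order over distance quartiles: returns positions
# (1..n, assumed sorted by distance) visited quartile by quartile, so a
# contiguous block of labels dealt in this order spreads evenly over
# near and far relatives. Position order within a quartile is random.
deal_positions <- function(n) {
  qsize <- rep(n %/% 4, 4)
  if (n %% 4 > 0) qsize[seq_len(n %% 4)] <- qsize[seq_len(n %% 4)] + 1
  qid <- rep(seq_len(4), times = qsize)
  pos_by_q <- lapply(seq_len(4), function(q) {
    p <- which(qid == q)
    if (length(p) > 1) sample(p) else p
  })
  seq_pos <- integer(0)
  while (any(lengths(pos_by_q) > 0)) {
    for (q in seq_len(4)) {
      if (length(pos_by_q[[q]]) > 0) {
        seq_pos <- c(seq_pos, pos_by_q[[q]][1])
        pos_by_q[[q]] <- pos_by_q[[q]][-1]
      }
    }
  }
  seq_pos
}

# Archetype/slope assignment for one layer, stratified over
# distance-to-invader quartiles. Species names arrive sorted by
# increasing distance (generate_tree names them that way).
assign_archetypes <- function(species, mix, config) {
  n <- length(species)
  counts <- round(mix * n)
  counts[1] <- n - sum(counts[-1])   # absorb rounding in the first class
  labs <- rep(names(mix), times = counts)
  n_strong <- config$n_strong
  strong <- unlist(lapply(names(mix), function(a) {
    k <- counts[[a]]
    if (a == "neutral" || k == 0) return(rep(FALSE, k))
    c(rep(TRUE, min(n_strong, k)), rep(FALSE, max(0, k - n_strong)))
  }))
  # shuffle within archetype, then deal blocks round-robin over quartiles
  shuf <- unlist(lapply(names(mix), function(a) {
    ix <- which(labs == a)
    if (length(ix) > 1) sample(ix) else ix
  }))
  labs <- labs[shuf]; strong <- strong[shuf]
  pos <- deal_positions(n)
  old_labs <- labs; old_strong <- strong
  labs[pos] <- old_labs; strong[pos] <- old_strong
  mag <- ifelse(labs == "decliner", -config$beta_decline,
                ifelse(labs == "increaser", config$beta_increase, 0))
  w <- ifelse(strong, runif(n, 0.9, 1.1),
              runif(n, config$mild_range[1], config$mild_range[2]))
  slope <- mag * ifelse(labs == "neutral", 0, w)
  base <- numeric(n)
  base[labs == "decliner"] <- -slope[labs == "decliner"] + runif(sum(labs == "decliner"), 0, 3)
  base[labs == "neutral"] <- runif(sum(labs == "neutral"), 1, 5)
  base[labs == "increaser"] <- runif(sum(labs == "increaser"), 0, 1.5)
  tibble(species = species, archetype = labs, strong = strong,
         base = base, slope = slope)
}

#' Generate plot surveys, covariates and ground truth
#'
#' Builds the 16-plot survey: per plot, each species' target IV follows
#' its archetype curve `base + slope * cover` (the invader's tree-layer
#' target is `100 * cover`), targets are normalized to sum to 100 over
#' the species present (target below `presence_min` means absent), IV
#' noise is added, and counts / dominance / subplot hits are back-solved
#' so the realized importance values reproduce the (noisy) targets —
#' counts and hits are integers, and the real-valued dominance component
#' absorbs their rounding wherever non-negativity allows. Soil
#' covariates are linear in cover plus noise. Monoculture (MB) plots'
#' tree layer contains only the invader.
#'
#' @param config A [gradient_config()].
#' @param tree The phylogeny from [generate_tree()].
#' @return A list with `survey` (record tibble), `covariates` (per-plot
#'   cover and soil), and `truth` (list: `species` — archetype, base,
#'   slope, distance to invader, true Theil-Sen beta of the latent IV
#'   series, true RI; `latent` — per plot/species latent target IV
#'   before noise).
#' @export
generate_surveys <- function(config, tree) {
  stopifnot(inherits(config, "gradient_config"))
  validate_tree(tree)
  inv <- config$invader_name
  spl <- config$species_per_layer
  d <- ape::cophenetic.phylo(tree)

  withr::with_seed(child_seed(config$seed, "survey"), {
    stages <- names(config$cover_means)
    plots <- tidyr::expand_grid(stage = stages, rep = seq_len(config$reps_per_stage)) |>
      mutate(plot_id = sprintf("%s_%d", .data$stage, .data$rep),
             cover = pmin(1, pmax(0, config$cover_means[.data$stage] +
                                    rnorm(dplyr::n(), 0, config$cover_jitter_sd))))
    soil <- purrr::pmap_dfr(config$soil_model, function(variable, intercept, slope, sd) {
      tibble(plot_id = plots$plot_id, variable = variable,
             value = intercept + slope * plots$cover + rnorm(nrow(plots), 0, sd))
    }) |>
      tidyr::pivot_wider(names_from = "variable", values_from = "value")
    covariates <- plots |>
      select("plot_id", "stage", "cover") |>
      left_join(soil, by = "plot_id") |>
      mutate(stage = factor(.data$stage, levels = .stages))

    # species parameters per layer
    params <- purrr::map_dfr(names(spl), function(lay) {
      sp <- sprintf("%s_sp%02d", lay, seq_len(spl[[lay]]))
      if (lay == "tree") {
        # natives all decline as the invader takes the canopy; a few
        # dominants at full magnitude, the rest minor
        n <- length(sp)
        base <- numeric(n)
        strong <- c(rep(TRUE, config$n_strong), rep(FALSE, n - config$n_strong))
        base[strong] <- config$beta_decline * runif(config$n_strong, 0.9, 1.1)
        rest <- 100 - sum(base[strong])
        shares <- rlnorm(n - config$n_strong, 0, 0.8)
        base[!strong] <- rest * shares / sum(shares)
        # deal strong/mild across distance quartiles
        pos <- deal_positions(n)
        old_base <- base; old_strong <- strong
        base[pos] <- old_base; strong[pos] <- old_strong
        tibble(species = sp, layer = lay, archetype = "decliner",
               strong = strong, base = base, slope = -base)
      } else {
        assign_archetypes(sp, config$archetype_mix[[lay]], config) |>
          mutate(layer = lay, .after = "species")
      }
    })
    params <- bind_rows(
      params,
      tibble(species = inv, layer = "tree", archetype = "invader",
             strong = TRUE, base = 0, slope = 100)
    )

    # Back-solve survey records from target IV shares: integer counts and
    # subplot hits approximately proportional to the target, with the
    # real-valued dominance share absorbing their rounding wherever the
    # non-negativity constraint allows. Returns the realized IVs too:
    # they differ from the target only where a component floor binds
    # (notably the tree layer's presence-based frequency, 100/S).
    backsolve <- function(t_i, lay) {
      n_sub <- config$n_subplots[[lay]]
      cnt <- pmax(1, round(config$total_count[[lay]] * t_i / 100))
      hits <- if (lay == "tree") rep(1, length(t_i)) else {
        pmin(n_sub, pmax(1, round(n_sub * t_i / max(t_i))))
      }
      relden <- 100 * cnt / sum(cnt)
      relfreq <- 100 * (hits / n_sub) / sum(hits / n_sub)
      dom_share <- pmax(0, 3 * t_i - relden - relfreq)
      dom_share <- 100 * dom_share / sum(dom_share)
      list(count = cnt, hits = hits, n_subplots = n_sub,
           dominance = dom_share / 100 * config$total_dominance[[lay]],
           iv = (relden + relfreq + dom_share) / 3)
    }

    # latent targets and noisy realized IV per plot x layer
    latent <- list(); records <- list()
    for (i in seq_len(nrow(plots))) {
      pid <- plots$plot_id[i]; cov <- plots$cover[i]
      for (lay in names(spl)) {
        pars <- params |> filter(.data$layer == lay)
        raw <- pmax(0, pars$base + pars$slope * cov)
        raw[raw < config$presence_min] <- 0
        if (lay == "tree" && plots$stage[i] == "MB") {
          # monoculture by definition: a virtually pure invader stand
          raw[pars$species != inv] <- 0
        }
        if (sum(raw) <= 0) {
          stop_validation(sprintf("no species present in plot %s layer %s", pid, lay))
        }
        target <- 100 * raw / sum(raw)
        # latent truth = the IV the survey design would measure with no
        # noise (component floors included), alongside the raw archetype
        # target share
        latent_iv <- numeric(length(target))
        latent_iv[target > 0] <- backsolve(target[target > 0], lay)$iv
        latent[[length(latent) + 1]] <- tibble(
          plot_id = pid, layer = lay, species = pars$species,
          cover = cov, target_iv = target, latent_iv = latent_iv
        )
        noisy <- target + ifelse(target > 0, rnorm(length(target), 0, config$iv_noise_sd), 0)
        noisy[noisy < config$presence_min] <- 0
        if (sum(noisy) <= 0) noisy <- target    # degenerate redraw guard
        noisy <- 100 * noisy / sum(noisy)
        pres <- noisy > 0
        bs <- backsolve(noisy[pres], lay)
        records[[length(records) + 1]] <- tibble(
          plot_id = pid, stage = plots$stage[i], layer = lay,
          species = pars$species[pres], count = bs$count,
          dominance = bs$dominance,
          subplot_hits = bs$hits, n_subplots = bs$n_subplots
        )
      }
    }
    latent <- bind_rows(latent)
    survey <- validate_survey(bind_rows(records))

    # ground truth: Theil-Sen slope of the latent IV series (zeros kept)
    beta_of <- function(sp) {
      li <- latent[latent$species == sp, ]
      theil_sen(li$cover, li$latent_iv)$slope
    }
    truth_sp <- params |>
      mutate(
        dist_to_invader = ifelse(.data$species == inv, 0,
                                 d[cbind(.data$species, inv)]),
        true_beta = vapply(.data$species, beta_of, numeric(1)),
        true_ri = ifelse(.data$species == inv, NA_real_,
                         .data$true_beta / .data$dist_to_invader)
      )

    list(survey = survey, covariates = covariates,
         truth = list(species = truth_sp, latent = latent))
  })
}

#' Generate a full synthetic gradient dataset
#'
#' Convenience wrapper: tree plus surveys, covariates and truth, all
#' reproducible bit-identically from the config seed.
#'
#' @param config A [gradient_config()].
#' @return A list of class `gradient_data` with elements `tree`,
#'   `survey`, `covariates`, `truth`, `config`.
#' @export
generate_gradient <- function(config = gradient_config()) {
  tree <- generate_tree(config)
  out <- generate_surveys(config, tree)
  structure(c(list(tree = tree), out, list(config = config)),
            class = "gradient_data")
}

#' Write a synthetic gradient dataset to disk
#'
#' Writes `survey.csv`, `covariates.csv`, `tree.nwk` and `truth.json`
#' into `dir`.
#'
#' @param data A `gradient_data` list from [generate_gradient()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_gradient <- function(data, dir) {
  stopifnot(inherits(data, "gradient_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(data$survey, file.path(dir, "survey.csv"))
  readr::write_csv(data$covariates, file.path(dir, "covariates.csv"))
  ape::write.tree(data$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(species = data$truth$species, latent = data$truth$latent,
         seed = data$config$seed),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA
  )
  invisible(dir)
}
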