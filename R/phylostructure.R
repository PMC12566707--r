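# MPD, MNTD, and standardized effect sizes (NRI/NTI) under the
# taxa-labels null model.

#' Mean pairwise and nearest-taxon phylogenetic distance
#'
#' `mpd()` is the mean patristic distance over all unordered pairs of
#' community members; `mntd()` is the mean, over members, of the
#' distance to the nearest other member. Both are presence-based
#' (unweighted).
#'
#' @param d A patristic distance matrix with species as dimnames (see
#'   [patristic_distances()]).
#' @param community Character vector of at least two species, all
#'   present in `d`.
#' @return A single number in branch-length units.
#' @export
mpd <- function(d, community) {
  community <- check_community(d, community)
  sub <- d[community, community]
  mean(sub[upper.tri(sub)])
}

#' @rdname mpd
#' @export
mntd <- function(d, community) {
  community <- check_community(d, community)
  sub <- d[community, community]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

check_community <- function(d, community) {
  community <- unique(as.character(community))
  missing <- setdiff(community, rownames(d))
  if (length(missing) > 0) {
    stop_lookup(sprintf("species not in distance matrix: %s",
                        paste(missing, collapse = ", ")))
  }
  if (length(community) < 2) {
    stop_undefined("MPD/MNTD are undefined for communities of fewer than 2 species")
  }
  community
}

#' Phylogenetic structure (NRI/NTI) under the taxa-labels null model
#'
#' Standardized effect sizes of MPD and MNTD against a null distribution
#' obtained by shuffling species identities (the labels of the distance
#' matrix) while holding community size fixed — equivalent to drawing
#' random communities of the same size from the species pool. The
#' indices follow the z-score sign convention
#' `NRI = -1 * (MPD_obs - mean(MPD_null)) / sd(MPD_null)` (and NTI
#' likewise with MNTD), so positive values indicate phylogenetic
#' clustering and negative values overdispersion.
#'
#' Degenerate communities are reported rather than erroring: a
#' single-species community, a community equal to the whole pool, or a
#' null distribution with zero spread all return NRI = NTI = 0 with
#' `degenerate = TRUE`.
#'
#' @inheritParams mpd
#' @param n_rand Number of null randomizations (default 999; the
#'   Monte-Carlo method only).
#' @param seed Integer seed making the randomization reproducible.
#' @param method `"sample"` for Monte-Carlo label shuffles, or
#'   `"exhaustive"` to enumerate every same-size community in the pool
#'   (feasible for small pools; gives the exact null mean and sd).
#' @return A one-row tibble with `mpd_obs`, `mntd_obs`, the null means
#'   and standard deviations, `nri`, `nti`, `n_randomizations`, `seed`
#'   and `degenerate`.
#' @export
ses_structure <- function(d, community, n_rand = 999, seed = NULL,
                          method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  pool <- rownames(d)
  community <- unique(as.character(community))
  missing <- setdiff(community, pool)
  if (length(missing) > 0) {
    stop_lookup(sprintf("species not in distance matrix: %s",
                        paste(missing, collapse = ", ")))
  }
  k <- length(community)
  if (method == "sample" && (!is.numeric(n_rand) || n_rand < 1)) {
    stop_validation("`n_rand` must be >= 1")
  }

  res <- tibble(
    mpd_obs = NA_real_, mntd_obs = NA_real_,
    mpd_null_mean = NA_real_, mpd_null_sd = NA_real_,
    mntd_null_mean = NA_real_, mntd_null_sd = NA_real_,
    nri = 0, nti = 0,
    n_randomizations = if (method == "sample") as.integer(n_rand) else NA_integer_,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    degenerate = FALSE
  )
  if (k < 2) {
    # Monoculture convention: structure metrics undefined, SES reported 0.
    res$degenerate <- TRUE
    return(res)
  }
  res$mpd_obs <- mpd(d, community)
  res$mntd_obs <- mntd(d, community)
  if (k == length(pool)) {
    # Every label permutation yields the same community: point-mass null.
    res$mpd_null_mean <- res$mpd_obs
    res$mntd_null_mean <- res$mntd_obs
    res$mpd_null_sd <- 0
    res$mntd_null_sd <- 0
    res$degenerate <- TRUE
    return(res)
  }

  if (method == "exhaustive") {
    sets <- combn(pool, k, simplify = FALSE)
    null_mpd <- vapply(sets, function(s) mpd(d, s), numeric(1))
    null_mntd <- vapply(sets, function(s) mntd(d, s), numeric(1))
  } else {
    draw <- function() {
      null_mpd <- numeric(n_rand)
      null_mntd <- numeric(n_rand)
      for (i in seq_len(n_rand)) {
        s <- sample(pool, k)
        sub <- d[s, s]
        null_mpd[i] <- mean(sub[upper.tri(sub)])
        diag(sub) <- Inf
        null_mntd[i] <- mean(apply(sub, 1, min))
      }
      list(mpd = null_mpd, mntd = null_mntd)
    }
    nulls <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
    null_mpd <- nulls$mpd
    null_mntd <- nulls$mntd
  }

  res$mpd_null_mean <- mean(null_mpd)
  res$mpd_null_sd <- sd(null_mpd)
  res$mntd_null_mean <- mean(null_mntd)
  res$mntd_null_sd <- sd(null_mntd)
  if (res$mpd_null_sd > 0) {
    res$nri <- -1 * (res$mpd_obs - res$mpd_null_mean) / res$mpd_null_sd
  } else {
    res$degenerate <- TRUE
  }
  if (res$mntd_null_sd > 0) {
    res$nti <- -1 * (res$mntd_obs - res$mntd_null_mean) / res$mntd_null_sd
  } else {
    res$degenerate <- TRUE
  }
  res
}

#' Per-plot, per-layer phylogenetic structure
#'
#' Computes PD, MPD, MNTD and their taxa-labels SES (NRI/NTI) for every
#' plot and layer. The null species pool for a layer is the set of all
#' species observed in that layer across every plot. Each community
#' gets a deterministic child seed derived from the top-level seed and
#' its (plot, layer) key, so results do not depend on plot order.
#'
#' @inheritParams phylo_diversity
#' @param n_rand Null randomizations per community (default 999).
#' @param seed Top-level integer seed.
#' @return A tibble with one row per (plot, layer): `pd`, `mpd_obs`,
#'   `mntd_obs`, `nri`, `nti`, `n_randomizations`, `degenerate`.
#' @export
phylo_structure <- function(survey, tree, layers = survey_layers(),
                            n_rand = 999, seed = 1,
                            include_root = TRUE, prune_missing = FALSE) {
  survey <- validate_survey(survey)
  validate_tree(tree)
  recs <- survey |> filter(.data$layer %in% layers)
  missing <- setdiff(unique(recs$species), tree$tip.label)
  if (length(missing) > 0) {
    if (!prune_missing) {
      stop_lookup(sprintf("species not found in tree: %s",
                          paste(missing, collapse = ", ")))
    }
    warn(sprintf("pruning %d species absent from tree: %s",
                 length(missing), paste(missing, collapse = ", ")))
    recs <- recs |> filter(!.data$species %in% missing)
  }
  out <- list()
  for (lay in intersect(layers, unique(recs$layer))) {
    lay_recs <- recs |> filter(.data$layer == lay)
    pool <- sort(unique(lay_recs$species))
    d <- patristic_distances(tree, pool)
    plots <- lay_recs |> distinct(.data$plot_id, .data$stage)
    rows <- purrr::pmap(plots, function(plot_id, stage) {
      comm <- lay_recs$species[lay_recs$plot_id == plot_id]
      ses <- ses_structure(d, comm, n_rand = n_rand,
                           seed = child_seed(seed, paste(plot_id, lay)))
      dplyr::bind_cols(
        tibble(plot_id = plot_id, stage = stage, layer = lay,
               pd = faith_pd(tree, comm, include_root = include_root)),
        ses
      )
    })
    out[[lay]] <- bind_rows(rows)
  }
  bind_rows(out) |> arrange(.data$plot_id, .data$layer)
}
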