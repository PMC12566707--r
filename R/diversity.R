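# Taxonomic alpha-diversity indices.

#' Alpha-diversity profile of one abundance vector
#'
#' Computes species richness S, the Margalef richness index
#' `(S - 1)/ln N`, the Shannon-Wiener index `H' = -sum(p_i ln p_i)`,
#' Simpson diversity in the complement (Gini-Simpson) form
#' `1 - sum(n_i (n_i - 1)) / (N (N - 1))`, and Pielou evenness
#' `H'/ln S`. Monoculture (S = 1) communities take the conventional
#' value 0 for Margalef, Shannon, Simpson and Pielou; N = 1 likewise
#' gives Margalef 0.
#'
#' @param n Numeric vector of per-species abundances (individuals or
#'   ramets), all `>= 1`; zero-abundance species must be dropped before
#'   calling.
#' @return A one-row tibble with `richness`, `margalef`, `simpson`
#'   (complement form), `shannon`, `pielou`, and the raw
#'   `simpson_concentration`.
#' @export
diversity_profile <- function(n) {
  if (length(n) == 0) {
    stop_validation("abundance vector is empty")
  }
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    stop_validation("all abundances must be finite and >= 1 (drop zero-abundance species upstream)")
  }
  S <- length(n)
  N <- sum(n)
  p <- n / N
  shannon <- -sum(p * log(p)) + 0   # + 0 normalizes IEEE negative zero
  margalef <- if (N <= 1) 0 else (S - 1) / log(N)
  conc <- if (N <= 1) 1 else sum(n * (n - 1)) / (N * (N - 1))
  simpson <- 1 - conc
  pielou <- if (S == 1) 0 else shannon / log(S)
  tibble(
    richness = S, margalef = margalef, simpson = simpson,
    shannon = shannon, pielou = pielou, simpson_concentration = conc
  )
}

#' Per-plot, per-layer alpha diversity
#'
#' Applies [diversity_profile()] to the abundance (count) column of each
#' (plot, layer) group of a survey.
#'
#' @inheritParams importance_values
#' @return A tibble with one row per (plot, layer) and the five index
#'   columns of [diversity_profile()].
#' @export
alpha_diversity <- function(survey, layers = survey_layers()) {
  survey <- validate_survey(survey)
  for (l in layers) check_layer(l)
  survey |>
    filter(.data$layer %in% layers) |>
    group_by(.data$plot_id, .data$stage, .data$layer) |>
    group_modify(~ diversity_profile(.x$count)) |>
    ungroup()
}
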