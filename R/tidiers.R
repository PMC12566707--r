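# broom-style tidiers for fitted objects.

#' Tidy a Kruskal-Wallis + Dunn result
#'
#' @param x A `kruskal_dunn` object.
#' @param ... Unused.
#' @return The pairwise Dunn comparison tibble (`group_a`, `group_b`,
#'   `z`, `p_value`, `p_adjusted`).
#' @export
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @rdname tidy.kruskal_dunn
#' @return For `glance()`: a one-row tibble with the Kruskal-Wallis H
#'   statistic, degrees of freedom, p-value, n and alpha.
#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble(kw_statistic = x$kw_statistic, kw_df = x$kw_df, kw_p = x$kw_p,
         n = x$n, alpha = x$alpha)
}

#' Tidy a gradient RDA fit
#'
#' @param x An `rda_gradient` object.
#' @param ... Unused.
#' @return One row per predictor with its marginal permutation p-value
#'   and VIF.
#' @export
tidy.rda_gradient <- function(x, ...) {
  tibble(term = names(x$term_p),
         p_value = unname(x$term_p),
         vif = unname(x$vif[names(x$term_p)]))
}

#' @rdname tidy.rda_gradient
#' @return For `glance()`: a one-row model summary (`r2`,
#'   `r2_adjusted`, `global_p`, `axis1_percent`, `n`, `n_perm`).
#' @export
glance.rda_gradient <- function(x, ...) {
  tibble(r2 = x$r2, r2_adjusted = x$r2_adjusted, global_p = x$global_p,
         axis1_percent = unname(x$explained_fraction_per_axis[1]),
         n = x$n, n_perm = x$n_perm)
}
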