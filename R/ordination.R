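# Redundancy analysis of diversity on the invader-soil gradient,
# permutation tests, VIF screening, and variance partitioning.

as_numeric_matrix <- function(x, what) {
  x <- as.data.frame(x)
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop_validation(sprintf("all %s columns must be numeric", what))
  }
  m <- as.matrix(x)
  if (any(!is.finite(m))) {
    stop_validation(sprintf("all %s values must be finite", what))
  }
  m
}

# Ezekiel's adjusted R^2 with m predictors on n observations.
adjusted_r2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

# R^2 of the multivariate least-squares of (column-standardized) Y on X:
# trace of fitted crossproduct over trace of response crossproduct.
multivar_r2 <- function(Y, X) {
  Ys <- scale(Y)
  fit <- lm(Ys ~ ., data = as.data.frame(X))
  sum(fitted(fit)^2) / sum(Ys^2)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the others.
#' Perfectly collinear predictors return `Inf`.
#'
#' @param X A data frame or matrix of `>= 2` numeric predictors with
#'   more rows than columns.
#' @return A named numeric vector, one value per predictor.
#' @export
vif <- function(X) {
  X <- as_numeric_matrix(X, "predictor")
  if (ncol(X) < 2) stop_validation("VIF needs at least 2 predictors")
  if (nrow(X) <= ncol(X)) stop_validation("VIF needs more observations than predictors")
  vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    res <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), y)$residuals
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' Redundancy analysis of diversity responses on gradient predictors
#'
#' Correlation-scale RDA (both response and predictor columns are
#' centred and scaled, since responses mix units): the constrained
#' ordination is fitted with [vegan::rda()], explanatory power is the
#' constrained share of total variance with Ezekiel's adjusted R^2, the
#' global and per-term (marginal) p-values come from unrestricted row
#' permutations of the predictors, and VIFs screen collinearity.
#'
#' @param Y Plots x responses data frame (e.g. Shannon, PD, NTI per
#'   layer).
#' @param X Plots x predictors data frame (invader cover and soil
#'   variables).
#' @param n_perm Number of permutations for the significance tests
#'   (default 999; fewer than 99 triggers a warning).
#' @param seed Integer seed for the permutation tests.
#' @param standardize Scale Y and X columns to unit variance (default
#'   `TRUE`).
#' @param test Run the permutation significance tests (default `TRUE`;
#'   set `FALSE` for exactly collinear designs, where the residual is
#'   zero and a permutation F is meaningless — p-values are then `NA`).
#' @return An object of class `rda_gradient`: a list with `r2`,
#'   `r2_adjusted`, `global_p`, `term_p`, `vif`,
#'   `explained_fraction_per_axis` (percent of constrained variance),
#'   site/response/predictor scores, `n`, `n_perm`, and the underlying
#'   vegan fit as `fit`. See [tidy.rda_gradient()] and
#'   [glance.rda_gradient()].
#' @export
rda_gradient <- function(Y, X, n_perm = 999, seed = NULL, standardize = TRUE,
                         test = TRUE) {
  Ym <- as_numeric_matrix(Y, "response")
  Xm <- as_numeric_matrix(X, "predictor")
  if (nrow(Ym) != nrow(Xm)) stop_validation("Y and X must have equal row counts")
  n <- nrow(Ym)
  m <- ncol(Xm)
  if (n <= m + 1) stop_validation("need more plots than predictors + 1")
  if (n_perm < 99) warn("fewer than 99 permutations gives coarse p-values")
  qrX <- qr(cbind(1, scale(Xm, scale = FALSE)))
  if (qrX$rank < m + 1) {
    bad <- colnames(Xm)[qrX$pivot[seq(qrX$rank + 1, m + 1)] - 1]
    stop_validation(sprintf("rank-deficient predictors (collinear): %s",
                            paste(bad, collapse = ", ")))
  }
  if (standardize) {
    zv <- c(colnames(Ym)[apply(Ym, 2, sd) == 0], colnames(Xm)[apply(Xm, 2, sd) == 0])
    if (length(zv) > 0) {
      stop_validation(sprintf("zero-variance column(s) cannot be standardized: %s",
                              paste(zv, collapse = ", ")))
    }
    Ym <- scale(Ym)
    Xm <- scale(Xm)
  }
  dat <- as.data.frame(Xm)
  fit <- vegan::rda(Ym ~ ., data = dat)
  r2 <- fit$CCA$tot.chi / fit$tot.chi
  r2_adj <- adjusted_r2(r2, n, m)
  eig <- fit$CCA$eig
  run_perm <- function() {
    global <- stats::anova(fit, permutations = n_perm)
    terms <- stats::anova(fit, by = "margin", permutations = n_perm)
    list(global = global, terms = terms)
  }
  if (test) {
    an <- if (is.null(seed)) run_perm() else withr::with_seed(as.integer(seed), run_perm())
    term_tab <- an$terms
    term_p <- setNames(term_tab[["Pr(>F)"]][seq_len(m)],
                       rownames(term_tab)[seq_len(m)])
    global_p <- an$global[["Pr(>F)"]][1]
  } else {
    term_p <- setNames(rep(NA_real_, m), colnames(Xm))
    global_p <- NA_real_
  }
  structure(
    list(
      r2 = r2, r2_adjusted = r2_adj,
      global_p = global_p,
      term_p = term_p,
      vif = if (m >= 2) vif(Xm) else setNames(1, colnames(Xm)),
      explained_fraction_per_axis = 100 * eig / sum(eig),
      site_scores = vegan::scores(fit, display = "sites", choices = seq_along(eig)),
      response_scores = vegan::scores(fit, display = "species", choices = seq_along(eig)),
      predictor_scores = vegan::scores(fit, display = "bp", choices = seq_along(eig)),
      n = n, n_perm = n_perm, seed = seed, fit = fit
    ),
    class = "rda_gradient"
  )
}

#' @export
print.rda_gradient <- function(x, ...) {
  cat(sprintf("RDA: R2 = %.3f, adjusted R2 = %.3f, global p = %.4g (n = %d, %d permutations)\n",
              x$r2, x$r2_adjusted, x$global_p, x$n, x$n_perm))
  cat("Axis % of constrained variance:",
      paste(sprintf("%.1f", x$explained_fraction_per_axis), collapse = ", "), "\n")
  cat("Marginal term p-values:\n")
  print(round(x$term_p, 4))
  invisible(x)
}

#' Variance partitioning of diversity onto cover and soil
#'
#' Partitions the (adjusted) explained variance of the response block
#' into the fraction unique to invader cover, unique to the soil
#' variables, shared between them, and unexplained, using adjusted R^2
#' differences: `a = adjR2(cover+soil) - adjR2(soil)`,
#' `b = adjR2(cover+soil) - adjR2(cover)`,
#' `shared = adjR2(full) - a - b`, `unexplained = 1 - adjR2(full)`.
#' Negative adjusted fractions (a known feature of VPA) are kept in the
#' `fraction_total` column and clamped to zero only in
#' `fraction_display`.
#'
#' @param Y Plots x responses data frame.
#' @param cover A numeric vector (or one-column data frame) of invader
#'   cover per plot.
#' @param soil Plots x soil-variables data frame.
#' @param standardize Scale response columns before fitting (default
#'   `TRUE`).
#' @return A tibble of class `vpa_fractions` with one row per component
#'   (`unique_cover`, `unique_soil`, `shared`, `unexplained`) and
#'   columns `fraction_total` (share of total response variance,
#'   unclamped), `fraction_display` (clamped to `[0, 1]`) and
#'   `fraction_explained` (share of the explained variance; `NA` for
#'   the unexplained row).
#' @export
variance_partition <- function(Y, cover, soil, standardize = TRUE) {
  Ym <- as_numeric_matrix(Y, "response")
  if (standardize) Ym <- scale(Ym)
  cover <- as_numeric_matrix(if (is.null(dim(cover))) data.frame(cover = cover) else cover,
                             "cover")
  soil <- as_numeric_matrix(soil, "soil")
  n <- nrow(Ym)
  if (nrow(cover) != n || nrow(soil) != n) {
    stop_validation("Y, cover and soil must have equal row counts")
  }
  m_full <- ncol(cover) + ncol(soil)
  if (n <= m_full + 1) stop_validation("need more plots than predictors + 1")

  r2a <- function(X) adjusted_r2(multivar_r2(Ym, X), n, ncol(X))
  full <- r2a(cbind(cover, soil))
  only_cover <- r2a(cover)
  only_soil <- r2a(soil)
  a <- full - only_soil
  b <- full - only_cover
  shared <- full - a - b
  unexplained <- 1 - full
  frac <- c(unique_cover = a, unique_soil = b, shared = shared,
            unexplained = unexplained)
  explained <- c(a, b, shared) / full
  out <- tibble(
    component = names(frac),
    fraction_total = unname(frac),
    fraction_display = pmin(pmax(unname(frac), 0), 1),
    fraction_explained = c(explained, NA)
  )
  class(out) <- c("vpa_fractions", class(out))
  attr(out, "adj_r2") <- c(full = full, cover = only_cover, soil = only_soil)
  out
}
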