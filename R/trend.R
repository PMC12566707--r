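# Nonparametric gradient and group statistics: Theil-Sen, Mann-Kendall,
# Kruskal-Wallis + Dunn post hoc, BH-FDR.

#' Theil-Sen robust slope
#'
#' The slope is the median of all pairwise slopes
#' `(y_j - y_i) / (x_j - x_i)` over pairs with distinct x; the intercept
#' is `median(y - slope * x)`.
#'
#' @param x Gradient values (e.g. invader cover in `[0, 1]`).
#' @param y Response values, same length.
#' @return A one-row tibble with `slope`, `intercept`, `n`.
#' @export
theil_sen <- function(x, y) {
  if (length(x) != length(y)) stop_validation("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop_validation("Theil-Sen needs at least 2 points")
  dx <- outer(x, x, "-")
  if (all(dx == 0)) {
    stop_undefined("Theil-Sen slope is undefined when all x are identical")
  }
  dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  slope <- median(dy[keep] / dx[keep])
  tibble(slope = slope, intercept = median(y - slope * x), n = n)
}

# Mahonian counts: number of permutations of 1..n with k inversions,
# k = 0..n(n-1)/2. Basis of the exact null distribution of Kendall's S.
inversion_counts <- function(n) {
  w <- 1
  for (m in 2:n) {
    D <- length(w) + m - 1
    new <- numeric(D)
    cum <- cumsum(w)
    for (k in seq_len(D)) {
      lo <- max(1, k - m + 1)
      new[k] <- cum[min(k, length(w))] - if (lo > 1) cum[lo - 1] else 0
    }
    w <- new
  }
  w
}

#' Mann-Kendall trend test (Kendall's tau-b)
#'
#' Rank-based test of monotonic association between a response and a
#' gradient. Reports the Kendall score
#' `S = sum_{i<j} sign(x_j - x_i) sign(y_j - y_i)`, the tie-corrected
#' correlation tau-b, and a two-sided p-value: exact by enumeration of
#' the permutation null when `n <= exact_max` and neither variable has
#' ties, otherwise from the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @inheritParams theil_sen
#' @param exact_max Largest n for which the exact no-ties p-value is
#'   used (default 10).
#' @return A one-row tibble with `s_statistic`, `tau`, `p_value`, `n`,
#'   `method`.
#' @export
mann_kendall <- function(x, y, exact_max = 10) {
  if (length(x) != length(y)) stop_validation("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_validation("Mann-Kendall needs at least 3 points")

  sgn <- outer(x, x, function(a, b) sign(b - a)) *
    outer(y, y, function(a, b) sign(b - a))
  S <- sum(sgn[upper.tri(sgn)])

  D <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  Tx <- sum(tx * (tx - 1) / 2)
  Ty <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((D - Tx) * (D - Ty))
  tau <- if (denom > 0) S / denom else 0

  has_ties <- Tx > 0 || Ty > 0
  if (!has_ties && n <= exact_max) {
    counts <- inversion_counts(n)             # inversions k -> S = D - 2k
    s_vals <- D - 2 * (seq_along(counts) - 1)
    total <- sum(counts)
    p <- min(1, 2 * min(sum(counts[s_vals <= S]) / total,
                        sum(counts[s_vals >= S]) / total))
    method <- "exact"
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    var_s <- (v0 - vt - vu) / 18 +
      sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
        (9 * n * (n - 1) * (n - 2)) +
      sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    if (var_s <= 0 || S == 0) {
      p <- 1
    } else {
      z <- (S - sign(S)) / sqrt(var_s)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal"
  }
  tibble(s_statistic = S, tau = tau, p_value = p, n = n, method = method)
}

#' Combined gradient trend test
#'
#' Theil-Sen slope plus Mann-Kendall test of the same (x, y) pairs — the
#' standard robust description of a monotonic trend along the expansion
#' gradient.
#'
#' @inheritParams mann_kendall
#' @return A one-row tibble: `slope`, `intercept`, `tau`, `s_statistic`,
#'   `p_value`, `n`.
#' @export
trend_test <- function(x, y, exact_max = 10) {
  ts <- theil_sen(x, y)
  mk <- mann_kendall(x, y, exact_max = exact_max)
  tibble(
    slope = ts$slope, intercept = ts$intercept,
    tau = mk$tau, s_statistic = mk$s_statistic,
    p_value = mk$p_value, n = mk$n
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (a validating wrapper around
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length, each `>=` its input.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_validation("all p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-squared p-value, followed
#' by Dunn's z tests for every pair of groups using the pooled-rank
#' variance with tie correction, BH-FDR adjustment across the pairs,
#' and a compact letter display at `alpha`. All-identical values give
#' H = 0, p = 1 (not an error).
#'
#' @param values Numeric response values.
#' @param groups Group labels (factor or character), same length; factor
#'   level order (or BF-to-MB stage order) drives the letter display.
#' @param alpha Significance level for the letter display (default
#'   0.05, applied to BH-adjusted pairwise p-values).
#' @return An object of class `kruskal_dunn`: a list with
#'   `kw_statistic`, `kw_df`, `kw_p`, a `pairwise` tibble
#'   (`group_a`, `group_b`, `z`, `p_value`, `p_adjusted`) and a
#'   `letters` tibble. Use [tidy()] / [glance()] to extract tibbles.
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05) {
  if (length(values) != length(groups)) {
    stop_validation("`values` and `groups` must have equal length")
  }
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- if (is.factor(groups)) droplevels(groups[ok]) else factor(groups[ok])
  lev <- levels(groups)
  if (all(lev %in% .stages)) {
    lev <- intersect(.stages, lev)
    groups <- factor(groups, levels = lev)
  }
  k <- nlevels(groups)
  if (k < 2) stop_validation("need at least 2 groups")
  if (max(table(groups)) < 2) stop_validation("need at least one group with >= 2 values")

  N <- length(values)
  all_tied <- length(unique(values)) == 1
  if (all_tied) {
    kw_stat <- 0; kw_p <- 1
  } else {
    kw <- kruskal.test(values, groups)
    kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
  }

  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(lev, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    sigma2 <- (N * (N + 1) / 12 - tie_term) * (1 / ng[[a]] + 1 / ng[[b]])
    z <- if (sigma2 > 0) (rbar[[a]] - rbar[[b]]) / sqrt(sigma2) else 0
    tibble(group_a = a, group_b = b, z = z,
           p_value = if (sigma2 > 0) 2 * pnorm(-abs(z)) else 1)
  })
  pw$p_adjusted <- bh_fdr(pw$p_value)

  letters <- compact_letters(lev, pw$group_a, pw$group_b,
                             pw$p_adjusted < alpha)
  structure(
    list(
      kw_statistic = kw_stat, kw_df = k - 1, kw_p = kw_p,
      n = N, alpha = alpha, pairwise = pw,
      letters = tibble(group = lev, letters = letters[lev])
    ),
    class = "kruskal_dunn"
  )
}

# Insert-and-absorb compact letter display: groups sharing a letter are
# not significantly different.
compact_letters <- function(groups, a, b, significant) {
  sets <- list(groups)
  for (i in which(significant)) {
    for (j in seq_along(sets)) {
      s <- sets[[j]]
      if (all(c(a[i], b[i]) %in% s)) {
        sets[[j]] <- setdiff(s, a[i])
        sets[[length(sets) + 1]] <- setdiff(s, b[i])
      }
    }
    # absorb sets wholly contained in another
    keep <- rep(TRUE, length(sets))
    for (j in seq_along(sets)) {
      for (m in seq_along(sets)) {
        if (j != m && keep[m] &&
            all(sets[[j]] %in% sets[[m]]) &&
            (length(sets[[j]]) < length(sets[[m]]) || j > m)) {
          keep[j] <- FALSE
          break
        }
      }
    }
    sets <- sets[keep]
  }
  # order sets by the first group they contain, assign a, b, c, ...
  first <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first)]
  out <- setNames(rep("", length(groups)), groups)
  for (j in seq_along(sets)) {
    for (g in sets[[j]]) out[g] <- paste0(out[g], letters[j])
  }
  out
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g\n",
              x$kw_statistic, x$kw_df, x$kw_p))
  cat("Dunn pairwise comparisons (BH-adjusted):\n")
  print(x$pairwise)
  cat("Letters (alpha = ", x$alpha, "): ",
      paste(x$letters$group, x$letters$letters, sep = "=", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}
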