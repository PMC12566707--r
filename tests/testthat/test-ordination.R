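test_that("VIF matches closed forms", {
  # exactly orthogonal pair -> both VIF 1
  x1 <- rep(c(1, -1), 8)
  e <- rep(c(1, 1, -1, -1), 4)
  expect_equal(unname(vif(data.frame(x1 = x1, x2 = e))), c(1, 1))
  # duplicated column -> infinite
  expect_equal(unname(vif(data.frame(a = x1, b = x1))), c(Inf, Inf))
  # exact r = 0.9 construction -> VIF = 1/(1 - 0.81)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * e
  expect_equal(cor(x1, x2), 0.9)
  expect_equal(unname(vif(data.frame(x1, x2))), rep(1 / (1 - 0.81), 2))
  expect_error(vif(data.frame(a = x1)), class = "phyloRI_validation_error")
})

test_that("RDA reduces to known closed forms", {
  withr::with_seed(41, {
    x <- rnorm(16)
    # single response, single predictor: R^2 equals squared Pearson r
    y <- 0.6 * x + rnorm(16, sd = 0.8)
    fit <- rda_gradient(data.frame(y = y), data.frame(x = x),
                        n_perm = 199, seed = 2)
    expect_equal(fit$r2, cor(x, y)^2, tolerance = 1e-10)
    expect_equal(fit$r2_adjusted, 1 - (1 - fit$r2) * 15 / 14, tolerance = 1e-12)

    # noiseless multivariate response: R^2 = 1, one axis carries all
    Y0 <- data.frame(a = 2 * x + 1, b = -3 * x + 2)
    fit0 <- rda_gradient(Y0, data.frame(x = x), test = FALSE)
    expect_equal(fit0$r2, 1, tolerance = 1e-10)
    expect_equal(unname(fit0$explained_fraction_per_axis[1]), 100)

    # adjusted R^2 equals vegan's RsquareAdj on a generic fit
    Y <- data.frame(p = rnorm(16), q = rnorm(16), r = rnorm(16))
    X <- data.frame(c1 = rnorm(16), c2 = rnorm(16), c3 = rnorm(16))
    fitg <- rda_gradient(Y, X, n_perm = 99, seed = 3)
    veg <- vegan::rda(scale(as.matrix(Y)) ~ ., data = as.data.frame(scale(as.matrix(X))))
    expect_equal(fitg$r2, unname(vegan::RsquareAdj(veg)$r.squared), tolerance = 1e-10)
    expect_equal(fitg$r2_adjusted, unname(vegan::RsquareAdj(veg)$adj.r.squared),
                 tolerance = 1e-10)

    # row-shuffle invariance
    perm <- sample(16)
    fitp <- rda_gradient(Y[perm, ], X[perm, ], n_perm = 99, seed = 3)
    expect_equal(fitp$r2, fitg$r2, tolerance = 1e-12)
    expect_equal(fitp$r2_adjusted, fitg$r2_adjusted, tolerance = 1e-12)

    # rank-deficient predictors are named
    expect_error(rda_gradient(Y, data.frame(a = x, b = 2 * x)),
                 class = "phyloRI_validation_error")
  })
})

test_that("variance partitioning satisfies the additive identity and matches vegan::varpart", {
  withr::with_seed(52, {
    for (i in 1:5) {
      Y <- matrix(rnorm(16 * 3), 16, 3, dimnames = list(NULL, c("sh", "pd", "nti")))
      cover <- runif(16)
      soil <- data.frame(pH = rnorm(16), TOC = rnorm(16), TN = rnorm(16), TP = rnorm(16))
      vp <- variance_partition(Y, cover, soil)
      expect_equal(sum(vp$fraction_total), 1, tolerance = 1e-9)
      adj <- attr(vp, "adj_r2")
      expect_equal(vp$fraction_total[vp$component == "unique_cover"],
                   adj[["full"]] - adj[["soil"]])
      # vegan cross-check (same Ezekiel adjustment underneath)
      vw <- vegan::varpart(scale(Y), data.frame(cover = cover), soil)
      ind <- vw$part$indfract$Adj.R.squared
      expect_equal(vp$fraction_total[vp$component == "unique_cover"], ind[1],
                   tolerance = 1e-8)
      expect_equal(vp$fraction_total[vp$component == "unique_soil"], ind[2],
                   tolerance = 1e-8)
      expect_equal(vp$fraction_total[vp$component == "shared"], ind[3],
                   tolerance = 1e-8)
      expect_equal(vp$fraction_total[vp$component == "unexplained"], ind[4],
                   tolerance = 1e-8)
    }
  })
})

test_that("VPA separates shared-dominant and unique-dominant designs", {
  withr::with_seed(63, {
    n <- 16
    cover <- rep(c(0, 0.3, 0.7, 1), each = 4) + rnorm(n, 0, 0.03)
    # soil is a deterministic function of cover plus small noise, and the
    # response is driven through soil: the shared fraction must dominate
    soil <- data.frame(pH = 4.4 + 0.85 * cover + rnorm(n, 0, 0.05),
                       TOC = 30.7 - 13.7 * cover + rnorm(n, 0, 0.5))
    Y <- data.frame(shannon = 2.5 - 1.5 * scale(soil$pH)[, 1] + rnorm(n, 0, 0.3),
                    pd = 1800 - 500 * scale(soil$pH)[, 1] + rnorm(n, 0, 150))
    vp <- variance_partition(Y, cover, soil)
    f <- setNames(vp$fraction_total, vp$component)
    expect_gt(f[["shared"]], f[["unique_cover"]])
    expect_gt(f[["shared"]], f[["unique_soil"]])

    # orthogonal design with a cover-only signal: unique_cover dominates
    cov2 <- rep(c(-1.5, -0.5, 0.5, 1.5), 4)
    soil2 <- data.frame(pH = rep(c(-1.5, -0.5, 0.5, 1.5), each = 4),
                        TOC = rep(c(1, -1), 8))
    Y2 <- data.frame(shannon = 1.2 * cov2 + rnorm(n, 0, 0.3),
                     pd = -0.8 * cov2 + rnorm(n, 0, 0.3))
    vp2 <- variance_partition(Y2, cov2, soil2)
    f2 <- setNames(vp2$fraction_total, vp2$component)
    expect_gt(f2[["unique_cover"]], abs(f2[["shared"]]))
    expect_gt(f2[["unique_cover"]], f2[["unique_soil"]])

    # pure noise: essentially nothing explained
    Y3 <- data.frame(a = rnorm(n), b = rnorm(n))
    vp3 <- variance_partition(Y3, cover, soil)
    f3 <- setNames(vp3$fraction_total, vp3$component)
    expect_gt(f3[["unexplained"]], 0.7)
    expect_lt(abs(f3[["unique_cover"]]), 0.25)
    expect_lt(abs(f3[["unique_soil"]]), 0.25)
  })
})
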