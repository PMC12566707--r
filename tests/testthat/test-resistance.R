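test_that("species beta recovers exact IV-vs-cover lines", {
  cover <- c(0, 0.1, 0.3, 0.5, 0.8, 1)
  expect_equal(species_beta(20 * (1 - cover), cover), -20)
  expect_equal(species_beta(rep(7, 6), cover), 0)
  expect_equal(species_beta(5 + 15 * cover, cover), 15)
})

test_that("raw RI is the slope-over-distance quotient with the proximity contract", {
  expect_equal(resistance_index(0, 350), 0)
  expect_equal(resistance_index(-12, 400), -0.03)
  expect_equal(resistance_index(9, 150), 0.06)
  # same decline, closer relative -> more negative RI
  expect_lt(resistance_index(-10, 200), resistance_index(-10, 800))
  expect_error(resistance_index(-5, 0), class = "phyloRI_validation_error")
  expect_error(resistance_index(-5, -3), class = "phyloRI_validation_error")
  withr::with_seed(9, {
    b <- rnorm(20); d <- runif(20, 50, 900)
    expect_equal(resistance_index(b, d), b / d)
  })
})

test_that("within-layer standardization yields mean 0, sd 1 and the +/-1 classes", {
  # opposite equal raw values: z = +/- 1/sqrt(2), both Neutral
  two <- tibble::tibble(layer = "shrub", species = c("a", "b"),
                        ri_raw = c(0.04, -0.04))
  z2 <- standardize_and_classify(two)
  expect_equal(sort(z2$ri_z), c(-1, 1) / sqrt(2))
  expect_true(all(z2$klass == "Neutral"))

  # identical raw values: degenerate layer, all Neutral
  same <- tibble::tibble(layer = "herb", species = letters[1:4], ri_raw = 0.02)
  zs <- standardize_and_classify(same)
  expect_true(all(zs$degenerate))
  expect_true(all(zs$klass == "Neutral"))
  expect_true(all(is.na(zs$ri_z)))

  withr::with_seed(23, {
    df <- tibble::tibble(layer = rep(c("tree", "shrub"), c(12, 20)),
                         species = paste0("s", 1:32),
                         ri_raw = rnorm(32, sd = 0.05))
    z <- standardize_and_classify(df)
    for (lay in c("tree", "shrub")) {
      zi <- z$ri_z[z$layer == lay]
      expect_equal(mean(zi), 0, tolerance = 1e-9)
      expect_equal(sd(zi), 1, tolerance = 1e-9)
    }
    expect_true(all(z$klass[z$ri_z >= 1] == "Resistant"))
    expect_true(all(z$klass[z$ri_z <= -1] == "Susceptible"))
    expect_true(all(z$klass[abs(z$ri_z) < 1] == "Neutral"))
    # classification is invariant to affine rescaling of raw RI
    z_aff <- standardize_and_classify(df |> dplyr::mutate(ri_raw = 3.7 * ri_raw + 0.2))
    expect_equal(z_aff$klass, z$klass)
    expect_equal(z_aff$ri_z, z$ri_z)
  })
})

test_that("the stage-occurrence filter requires presence in 3 of 4 stages", {
  expect_false(stage_filter(c(5, 0, 0, 0)))
  expect_false(stage_filter(c(5, 2, 0, 0)))
  expect_true(stage_filter(c(5, 2, 1, 0)))
  expect_true(stage_filter(c(5, 2, 1, 3)))
  expect_true(stage_filter(c(0, 2, 1, 3)))
})

test_that("resistance_scores computes beta, distance and classes on a constructed gradient", {
  # four plots, exact IV lines, tiny 4-species tree + invader
  tr <- ape::read.tree(text = "(((decl_near:50,invader:50):200,incr_near:250):250,((decl_far:100,flat_far:100):200,rare:300):200);")
  cover <- c(0, 0.3, 0.7, 1)
  design <- tibble::tibble(
    plot_id = paste0("p", 1:4),
    stage = factor(c("BF", "LM", "HM", "MB"), levels = expansion_stages()),
    cover = cover
  )
  mk_iv <- function(sp, ivs) {
    tibble::tibble(plot_id = design$plot_id, stage = design$stage,
                   layer = "shrub", species = sp, iv = ivs,
                   rel_density = ivs, rel_dominance = ivs, rel_frequency = ivs)
  }
  iv <- dplyr::bind_rows(
    mk_iv("decl_near", 40 * (1 - cover)),
    mk_iv("decl_far", 40 * (1 - cover)),
    mk_iv("incr_near", 10 + 20 * cover),
    mk_iv("flat_far", rep(10, 4)),
    mk_iv("rare", c(5, 0, 0, 0))          # fails the stage filter
  )
  cov <- design |> dplyr::mutate(pH = 5, TOC = 20, TN = 2, TP = 0.2)
  rs <- resistance_scores(iv, cov, tr, "invader")
  expect_setequal(rs$species, c("decl_near", "decl_far", "incr_near", "flat_far"))
  skipped <- attr(rs, "skipped")
  expect_equal(skipped$species, "rare")

  expect_equal(rs$beta[rs$species == "decl_near"], -40)
  expect_equal(rs$beta[rs$species == "flat_far"], 0)
  expect_equal(rs$dist_to_invader[rs$species == "decl_near"], 100)
  expect_equal(rs$dist_to_invader[rs$species == "decl_far"], 1000)
  # same slope, nearer relative -> more negative raw RI
  expect_lt(rs$ri_raw[rs$species == "decl_near"], rs$ri_raw[rs$species == "decl_far"])
  expect_equal(rs$ri_raw, rs$beta / rs$dist_to_invader)
  # the invader never appears among the records
  expect_false("invader" %in% rs$species)

  # negating the IV deviations negates beta (antisymmetry in the slope)
  iv_neg <- iv |> dplyr::mutate(iv = ifelse(species == "incr_near", 20 - 20 * cover[match(plot_id, design$plot_id)] + 10, iv))
  rs_neg <- resistance_scores(iv_neg, cov, tr, "invader")
  expect_equal(rs_neg$beta[rs_neg$species == "incr_near"],
               -rs$beta[rs$species == "incr_near"])
})

test_that("archetype recovery: strong decliners and increasers separate on the default gradient", {
  dat <- generate_gradient(gradient_config())
  iv <- importance_values(dat$survey)
  rs <- resistance_scores(iv, dat$covariates, dat$tree, "invader")
  truth <- dat$truth$species
  m <- dplyr::inner_join(rs, truth, by = c("species", "layer"))
  expect_gt(nrow(m), 30)
  # rank agreement between true beta/D and the estimate
  expect_gt(cor(m$true_ri, m$ri_raw, method = "spearman"), 0.8)
  # strong decliners never classify as Resistant, strong increasers never as Susceptible
  sd_cls <- m$klass[m$strong & m$archetype == "decliner"]
  si_cls <- m$klass[m$strong & m$archetype == "increaser"]
  expect_false(any(sd_cls == "Resistant"))
  expect_false(any(si_cls == "Susceptible"))
})
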