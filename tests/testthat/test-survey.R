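test_that("read_survey round-trips records and rejects malformed files", {
  s <- toy_survey()
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(s, f)
  got <- read_survey(f)
  expect_equal(nrow(got), nrow(s))
  expect_s3_class(got$stage, "factor")
  expect_equal(
    got |> dplyr::arrange(plot_id, layer, species) |>
      dplyr::mutate(stage = as.character(stage)),
    s |> dplyr::arrange(plot_id, layer, species),
    ignore_attr = TRUE
  )

  # missing column named in the error
  readr::write_csv(s[setdiff(names(s), "dominance")], f)
  expect_error(read_survey(f), "dominance", class = "phyloRI_format_error")

  # enum violations
  bad <- s; bad$stage[1] <- "XX"
  expect_error(validate_survey(bad), "XX", class = "phyloRI_validation_error")
  bad <- s; bad$layer[1] <- "canopy"
  expect_error(validate_survey(bad), "canopy", class = "phyloRI_validation_error")

  # duplicate (plot, layer, species) and negative values
  expect_error(validate_survey(rbind(s, s[1, ])),
               "duplicate", class = "phyloRI_validation_error")
  bad <- s; bad$count[1] <- 0
  expect_error(validate_survey(bad), "count", class = "phyloRI_validation_error")
  bad <- s; bad$dominance[1] <- -2
  expect_error(validate_survey(bad), "dominance", class = "phyloRI_validation_error")
  bad <- s; bad$subplot_hits[3] <- 9
  expect_error(validate_survey(bad), class = "phyloRI_validation_error")
})

test_that("importance values match hand evaluation of the three ratios", {
  # monoculture: every ratio is 100
  mono <- tibble::tibble(plot_id = "p", stage = "MB", layer = "tree",
                         species = "bamboo", count = 50, dominance = 900,
                         subplot_hits = 1, n_subplots = 1)
  expect_equal(importance_values(mono)$iv, 100)

  # symmetry: identical records share IV 50/50
  twin <- tibble::tibble(plot_id = "p", stage = "BF", layer = "shrub",
                         species = c("a", "b"), count = 4, dominance = 12,
                         subplot_hits = 3, n_subplots = 5)
  expect_equal(importance_values(twin)$iv, c(50, 50))

  # hand-evaluated two-species case: counts 3/1, dominance 10/10,
  # hits 2-of-2 and 1-of-2 -> rel density 75/25, rel dominance 50/50,
  # rel frequency (1, 0.5)/1.5 = 200/3, 100/3
  pair <- tibble::tibble(plot_id = "p", stage = "LM", layer = "herb",
                         species = c("a", "b"), count = c(3, 1),
                         dominance = c(10, 10), subplot_hits = c(2, 1),
                         n_subplots = 2)
  iv <- importance_values(pair)
  expect_equal(iv$rel_density, c(75, 25))
  expect_equal(iv$rel_dominance, c(50, 50))
  expect_equal(iv$rel_frequency, c(200 / 3, 100 / 3))
  expect_equal(iv$iv, c((75 + 50 + 200 / 3) / 3, (25 + 50 + 100 / 3) / 3))

  # tree layer frequency is presence at plot grain: rel_frequency 100/S
  tr <- toy_survey() |> dplyr::filter(layer == "tree", plot_id == "p1")
  expect_equal(importance_values(tr)$rel_frequency, c(50, 50))

  # degenerate layer: zero total dominance with nonzero counts
  degen <- mono; degen$dominance <- 0
  expect_error(importance_values(degen), "dominance",
               class = "phyloRI_validation_error")
})

test_that("IV conservation, order and dominance-scale invariance hold on generated surveys", {
  dat <- generate_gradient(small_config(seed = 421))
  iv <- importance_values(dat$survey)
  sums <- iv |>
    dplyr::group_by(plot_id, layer) |>
    dplyr::summarise(dplyr::across(c(rel_density, rel_dominance, rel_frequency, iv), sum),
                     .groups = "drop")
  expect_true(all(abs(sums$rel_density - 100) < 1e-9))
  expect_true(all(abs(sums$rel_dominance - 100) < 1e-9))
  expect_true(all(abs(sums$rel_frequency - 100) < 1e-9))
  expect_true(all(abs(sums$iv - 100) < 1e-9))

  # permuting record order changes nothing
  shuffled <- withr::with_seed(1, dat$survey[sample(nrow(dat$survey)), ])
  iv2 <- importance_values(shuffled) |> dplyr::arrange(plot_id, layer, species)
  expect_equal(iv2, iv |> dplyr::arrange(plot_id, layer, species))

  # scaling all dominance in a layer leaves rel_dominance unchanged
  scaled <- dat$survey |>
    dplyr::mutate(dominance = ifelse(layer == "shrub", dominance * 7.3, dominance))
  iv3 <- importance_values(scaled) |> dplyr::arrange(plot_id, layer, species)
  expect_equal(iv3$rel_dominance,
               (iv |> dplyr::arrange(plot_id, layer, species))$rel_dominance)
})

test_that("stage-mean IV averages over stage plots with zeros for absences", {
  s <- tibble::tribble(
    ~plot_id, ~stage, ~layer, ~species, ~count, ~dominance, ~subplot_hits, ~n_subplots,
    "b1", "BF", "shrub", "x", 3, 6, 2, 5,
    "b1", "BF", "shrub", "y", 1, 2, 1, 5,
    "b2", "BF", "shrub", "x", 2, 4, 2, 5,
    "m1", "MB", "shrub", "y", 5, 5, 5, 5
  )
  iv <- importance_values(s)
  sm <- stage_mean_iv(iv, "shrub")
  # brute force: average per stage including zero for absent plots
  iv_of <- function(p, sp) {
    v <- iv$iv[iv$plot_id == p & iv$species == sp]
    if (length(v) == 0) 0 else v
  }
  expect_equal(sm$BF[sm$species == "x"], (iv_of("b1", "x") + iv_of("b2", "x")) / 2)
  expect_equal(sm$BF[sm$species == "y"], (iv_of("b1", "y") + 0) / 2)
  expect_equal(sm$MB[sm$species == "x"], 0)       # absent from the stage
  expect_equal(sm$MB[sm$species == "y"], 100)
  expect_equal(sm$LM, c(0, 0))                    # stage with no plots in design? see below
  expect_error(stage_mean_iv(iv, "understorey"), class = "phyloRI_validation_error")

  # single species present in all 4 plots of one stage at IV 10 -> mean 10
  s4 <- tibble::tibble(plot_id = paste0("h", 1:4), stage = "HM", layer = "herb",
                       species = "z", count = 5, dominance = 5,
                       subplot_hits = 3, n_subplots = 5)
  expect_equal(stage_mean_iv(importance_values(s4), "herb")$HM, 100)
})

test_that("generator output re-reads field-by-field as 16 plots, 4 per stage", {
  dat <- generate_gradient(small_config(seed = 99))
  dir <- withr::local_tempdir()
  write_gradient(dat, dir)
  survey <- read_survey(file.path(dir, "survey.csv"))
  cov <- read_covariates(file.path(dir, "covariates.csv"))
  expect_equal(survey, dat$survey)
  expect_equal(nrow(cov), 16)
  expect_equal(unname(table(cov$stage)[expansion_stages()]), rep(4L, 4),
               ignore_attr = TRUE)
  expect_equal(cov |> dplyr::mutate(stage = as.character(stage)),
               dat$covariates |> dplyr::mutate(stage = as.character(stage)),
               ignore_attr = TRUE)
})
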