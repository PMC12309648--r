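# simulated model frame with configurable truth; Y = f(features) + noise
sim_frame <- function(n_mpas = 14, years = 2016:2021, beta_age = 0,
                      beta_habdiv = 0, beta0 = 0.2, sigma_b = 0,
                      v = 0.05, seed = 1) {
  cfg <- sim_config(n_mpas = n_mpas, years = years, beta0 = beta0,
                    beta_age = beta_age, beta_habdiv = beta_habdiv,
                    sigma_between = sigma_b, prop_no_take = 1, seed = seed)
  net <- generate_network(cfg)
  fr <- tidyr::crossing(net, ecosystem = cfg$ecosystems, year = cfg$years)
  fr$age <- fr$year - fr$implementation_year
  truth <- beta0 + beta_age * fr$age + beta_habdiv * fr$habitat_diversity +
    fr$b_mpa
  fr$Y <- truth + stats::rnorm(nrow(fr), 0, sqrt(v))
  fr$truth <- truth
  fr$v <- v
  fr$weight <- 1 / v
  fr
}

test_that("model frame restricts to no-take targeted effects and reports drops", {
  eff <- tibble::tibble(
    mpa_id = rep(c("m1", "m2", "m3"), each = 2),
    ecosystem = "kelp_forest", year = rep(c(2020, 2021), 3),
    status = rep(c("targeted", "targeted", "targeted", "nontargeted",
                   "targeted", "targeted"))[1:6],
    protection = c("no_take", "no_take", "no_take", "no_take",
                   "partial_take", "partial_take"),
    Y = 0.5, v = 0.1, region = "north")
  feats <- tibble::tibble(
    mpa_id = c("m1", "m2", "m3"), implementation_year = 2010,
    size_km2 = c(5, 10, 15), habitat_diversity = c(0.5, NA, 1),
    habitat_richness = 3, prop_rock = 0.4, pre_landings = 20,
    settlement_ecosystem = 1, settlement_total = 4)

  frame <- build_model_frame(eff, feats)
  # m3 is partial-take, m2 has a missing feature, m1's nontargeted row absent
  expect_true(all(frame$mpa_id == "m1"))
  expect_equal(nrow(frame), 2)
  expect_equal(frame$age, c(10, 11))
  dropped <- attr(frame, "dropped")
  expect_true(all(dropped$mpa_id == "m2"))
  expect_true(all(c("weight", mpa_features()) %in% names(frame)))

  only_partial <- dplyr::filter(eff, protection == "partial_take")
  expect_error(build_model_frame(only_partial, feats),
               class = "mpameta_invalid_argument")
})

test_that("annual frame rows are counted by filter enumeration", {
  cfg <- sim_config(n_mpas = 15, seed = 44)
  sim <- simulate_mpa_dataset(cfg)
  st <- classify_target_status(sim$species[c("species_id", "annual_catch")], 10)
  eff <- effect_sizes(summarize_pairs(
    aggregate_replicate_biomass(sim$surveys, sim$species, st)), sim$network)
  frame <- build_model_frame(eff, sim$network)
  expected <- sum(eff$status == "targeted" & eff$protection == "no_take")
  expect_equal(nrow(frame), expected)
})

test_that("a pure-noise response shrinks smooths toward linearity and r2 toward 0", {
  stats <- purrr::map_dfr(1:5, function(i) {
    set.seed(500 + i)
    fr <- sim_frame(seed = 500 + i)
    fit <- fit_weighted_gam(fr, c("habitat_diversity", "size_km2"),
                            partials = FALSE)
    sm <- tidy(fit)
    feats <- sm[sm$term %in% c("habitat_diversity", "size_km2"), ]
    tibble::tibble(edf = mean(feats$edf), r2 = glance(fit)$r2_adj)
  })
  expect_lt(mean(stats$edf), 2)   # shrinks toward 1 on average
  expect_lt(mean(stats$r2), 0.05)
})

test_that("a linear truth is recovered by the fitted partial effect", {
  set.seed(6)
  fr <- sim_frame(beta_habdiv = 2, seed = 102)
  fit <- fit_weighted_gam(fr, "habitat_diversity")
  part <- fit$partials[fit$partials$term == "habitat_diversity", ]
  slope <- stats::coef(stats::lm(estimate ~ x, data = part))[["x"]]
  expect_equal(slope, 2, tolerance = 0.15)
  # truth correlates strongly with the fitted values
  expect_gt(stats::cor(fit$fitted, fr$truth), 0.9)
})

test_that("the fit is invariant to rescaling all weights", {
  set.seed(7)
  fr <- sim_frame(beta_habdiv = 1, seed = 103)
  f1 <- fit_weighted_gam(fr, "habitat_diversity")
  fr2 <- dplyr::mutate(fr, weight = weight * 37)
  f2 <- fit_weighted_gam(fr2, "habitat_diversity")
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
  expect_equal(f1$edf, f2$edf, tolerance = 1e-6)
})

test_that("duplicating rows with halved weights leaves the fit unchanged", {
  # the weighted-least-squares identity holds at fixed smoothing parameters
  set.seed(8)
  fr <- sim_frame(beta_habdiv = 1, seed = 104)
  f1 <- fit_weighted_gam(fr, "habitat_diversity")
  fr_dup <- dplyr::bind_rows(dplyr::mutate(fr, weight = weight / 2),
                             dplyr::mutate(fr, weight = weight / 2))
  f2 <- fit_weighted_gam(fr_dup, "habitat_diversity", sp = f1$model$sp)
  expect_equal(f2$fitted[seq_len(nrow(fr))], f1$fitted, tolerance = 1e-6)
})

test_that("an ill-posed frame signals an error", {
  fr <- sim_frame(seed = 105)[1:4, ]
  expect_error(fit_weighted_gam(fr, mpa_features()),
               class = "mpameta_ill_posed")
})

test_that("forward selection finds a single true driver with a decreasing trace", {
  set.seed(9)
  fr <- sim_frame(beta_habdiv = 1.5, seed = 106)
  sel <- forward_select_gcv(fr, candidates = "habitat_diversity")
  expect_equal(sel$included, "habitat_diversity")
  acc <- sel$trace[sel$trace$accepted, ]
  expect_true(all(diff(acc$gcv) < 0))
  expect_s3_class(sel$fit, "mpa_gam")
  # partial curves are available on the selected fit
  expect_true("habitat_diversity" %in% sel$fit$partials$term)
})
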