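test_that("target-status classification applies the two-stage rule", {
  expect_equal(
    classify_target_status(
      tibble::tibble(species_id = c("A", "B"), annual_catch = c(1000, 0)))$status,
    c("targeted", "nontargeted"))

  # low-volume bycatch reclassified nontargeted
  expect_equal(
    classify_target_status(
      tibble::tibble(species_id = c("A", "B"), annual_catch = c(5, 500)),
      bycatch_threshold = 10)$status,
    c("nontargeted", "targeted"))

  # cryptic-species override wins
  expect_equal(
    classify_target_status(
      tibble::tibble(species_id = "A", annual_catch = 0),
      overrides = c(A = "targeted"))$status,
    "targeted")

  expect_error(
    classify_target_status(
      tibble::tibble(species_id = "A", annual_catch = -1)),
    class = "mpameta_invalid_argument")
})

test_that("protection classification honours de facto no-take status", {
  regs <- tibble::tibble(
    mpa_id = c("smr", "smca_salmon", "smca_finfish"),
    ecosystem = "kelp_forest",
    allows_take = c(FALSE, TRUE, TRUE),
    take_affects_ecosystem = c(NA, FALSE, TRUE))
  out <- classify_protection(regs)
  expect_equal(out$protection, c("no_take", "no_take", "partial_take"))

  expect_equal(protection_for("smca_salmon", "kelp_forest", regs), "no_take")
  expect_error(protection_for("nope", "kelp_forest", regs),
               class = "mpameta_missing_data")
})

test_that("length-to-weight conversion is the allometric power law", {
  expect_equal(length_to_weight(2, 1, 3), 8)
  expect_equal(length_to_weight(10, 0.01, 3), 10)
  expect_error(length_to_weight(2, 1, 0), class = "mpameta_invalid_argument")
  expect_error(length_to_weight(-1, 1, 3), class = "mpameta_invalid_argument")
})

test_that("replicate biomass aggregation sums individual weights by status", {
  obs <- dplyr::bind_rows(
    obs_row(sp = "sp_a", count = 1, lengths = list(2)),
    obs_row(sp = "sp_b", count = 2, lengths = list(c(2, 3)), rep = "r1"))
  out <- aggregate_replicate_biomass(obs, toy_species(), toy_status())
  expect_equal(nrow(out), 2)  # both statuses, one replicate
  expect_equal(out$biomass[out$status == "targeted"], 8)        # 1*2^3
  expect_equal(out$biomass[out$status == "nontargeted"],
               0.01 * (8 + 27))                                  # a=0.01, b=3

  # splitting a fish list across rows leaves the total unchanged (additivity)
  split_obs <- dplyr::bind_rows(
    obs_row(sp = "sp_a", count = 1, lengths = list(2)),
    obs_row(sp = "sp_b", count = 1, lengths = list(2)),
    obs_row(sp = "sp_b", count = 1, lengths = list(3)))
  out2 <- aggregate_replicate_biomass(split_obs, toy_species(), toy_status())
  expect_equal(out2$biomass, out$biomass)
})

test_that("empty replicates yield explicit zero rows for both statuses", {
  obs <- obs_row(sp = NA_character_, count = 0, lengths = list(numeric(0)))
  out <- aggregate_replicate_biomass(obs, toy_species(), toy_status())
  expect_equal(nrow(out), 2)
  expect_setequal(out$status, c("targeted", "nontargeted"))
  expect_equal(out$biomass, c(0, 0))
})

test_that("counts without lengths fall back to the species mean length", {
  obs <- obs_row(sp = "sp_a", count = 3, lengths = list(numeric(0)))
  out <- aggregate_replicate_biomass(obs, toy_species(), toy_status())
  expect_equal(out$biomass[out$status == "targeted"], 3 * 1 * 10^3)
})

test_that("unresolvable species are reported as missing data", {
  err <- expect_error(
    aggregate_replicate_biomass(obs_row(sp = "mystery"), toy_species(),
                                toy_status()),
    class = "mpameta_missing_data")
  expect_true("mystery" %in% err$offenders)
})

test_that("paired summaries compute means, n-1 SDs and route exclusions", {
  repl <- tibble::tibble(
    mpa_id = "m1", ecosystem = "kelp_forest", year = 2020,
    side = rep(c("inside", "outside"), each = 2),
    replicate_id = rep(c("r1", "r2"), 2),
    status = "targeted",
    biomass = c(2, 4, 1, 1))
  out <- summarize_pairs(repl)
  expect_equal(out$mean_inside, 3)
  expect_equal(out$sd_inside, sqrt(2))
  expect_equal(out$n_inside, 2L)
  expect_equal(out$mean_outside, 1)
  expect_equal(out$sd_outside, 0)
  expect_false(out$sd_undefined)

  # single replicate per side: sd recorded 0 and flagged
  one <- summarize_pairs(repl[c(1, 3), ])
  expect_equal(one$sd_inside, 0)
  expect_true(one$sd_undefined)

  # a group missing one side is excluded with a reason, not dropped silently
  inside_only <- repl[1:2, ]
  res <- summarize_pairs(inside_only)
  expect_equal(nrow(res), 0)
  excl <- pair_exclusions(res)
  expect_equal(nrow(excl), 1)
  expect_equal(excl$reason, "no_outside_replicates")
})

test_that("status partition conserves total biomass", {
  cfg <- sim_config(n_mpas = 3, n_species = 6, years = 2021, seed = 12)
  sim <- simulate_mpa_dataset(cfg)
  st <- classify_target_status(sim$species[c("species_id", "annual_catch")],
                               bycatch_threshold = 10)
  repl <- aggregate_replicate_biomass(sim$surveys, sim$species, st)
  total_by_status <- sum(repl$biomass)
  lw <- sim$species[match(sim$surveys$species_id, sim$species$species_id), ]
  fish_total <- sum(purrr::pmap_dbl(
    list(sim$surveys$lengths, lw$lw_a, lw$lw_b),
    function(l, a, b) if (length(l)) sum(a * l^b) else 0))
  expect_equal(total_by_status, fish_total)
})
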