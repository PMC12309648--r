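test_that("species pool has forced status composition and respects draw bounds", {
  expect_error(generate_species_pool(1), class = "mpameta_invalid_argument")

  sp2 <- generate_species_pool(2, seed = 1)
  expect_setequal(sp2$targeted_truth, c(TRUE, FALSE))

  sp <- generate_species_pool(50, seed = 7)
  b <- attr(sp, "draw_bounds")
  expect_true(all(sp$lw_b >= b$lw_b[1] & sp$lw_b <= b$lw_b[2]))
  expect_true(all(sp$lw_a >= b$lw_a[1] & sp$lw_a <= b$lw_a[2]))
  expect_true(any(sp$targeted_truth) && any(!sp$targeted_truth))
  # hook-and-line sampling: nontargeted species uncatchable on the shallow reef
  expect_true(all(sp$q_shallow_reef[!sp$targeted_truth] == 0))
  expect_true(all(sp$q_shallow_reef[sp$targeted_truth] > 0))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_mpas = 5, n_species = 8, years = 2020:2021, seed = 7)
  s1 <- simulate_mpa_dataset(cfg)
  s2 <- simulate_mpa_dataset(cfg)
  expect_identical(s1$species, s2$species)
  expect_identical(s1$network, s2$network)
  expect_identical(s1$surveys, s2$surveys)
})

test_that("degenerate effect models produce the configured constant truths", {
  cfg0 <- sim_config(n_mpas = 12, sigma_between = 0, beta_age = 0,
                     beta_habdiv = 0, prop_no_take = 1, seed = 3)
  net0 <- generate_network(cfg0)
  expect_equal(net0$true_effect_targeted, rep(cfg0$beta0, 12))
  expect_equal(net0$true_effect_nontargeted,
               rep(cfg0$attenuation * cfg0$beta0, 12))

  cfg_null <- sim_config(n_mpas = 12, beta0 = 0, beta_age = 0,
                         beta_habdiv = 0, sigma_between = 0, seed = 3)
  expect_true(all(generate_network(cfg_null)$true_effect_targeted == 0))
})

test_that("mean recorded true effect matches the generating formula", {
  cfg <- sim_config(n_mpas = 400, prop_no_take = 1, seed = 5)
  net <- generate_network(cfg)
  age <- max(cfg$years) - net$implementation_year
  expected <- cfg$beta0 + cfg$beta_age * mean(age) +
    cfg$beta_habdiv * mean(net$habitat_diversity)
  mc_se <- sd(net$true_effect_targeted) / sqrt(nrow(net))
  expect_lt(abs(mean(net$true_effect_targeted) - expected), 3 * mc_se)
})

test_that("surveys respect structural invariants", {
  cfg <- sim_config(n_mpas = 6, n_species = 8, years = 2020:2021, seed = 2)
  sim <- simulate_mpa_dataset(cfg)
  surv <- sim$surveys

  expect_true(all(surv$count >= 0 & surv$count == floor(surv$count)))
  expect_true(all(unlist(surv$lengths) > 0))
  expect_true(all(lengths(surv$lengths) ==
                    ifelse(is.na(surv$species_id), 0, surv$count)))

  # no nontargeted species in any shallow-reef replicate
  nt <- sim$species$species_id[!sim$species$targeted_truth]
  shallow <- surv[surv$ecosystem == "shallow_reef" & !is.na(surv$species_id), ]
  expect_false(any(shallow$species_id %in% nt))

  expect_error(simulate_surveys(sim$network[0, ], sim$species, cfg),
               class = "mpameta_invalid_argument")
})

test_that("zero inflation of 1 empties every outside replicate", {
  cfg <- sim_config(n_mpas = 3, n_species = 5, years = 2021,
                    zero_inflation_outside = 1, seed = 4)
  sim <- simulate_mpa_dataset(cfg)
  outside <- sim$surveys[sim$surveys$side == "outside", ]
  expect_true(all(outside$count == 0))
  expect_true(all(is.na(outside$species_id)))
})

test_that("with no true effect the inside/outside count ratio is near 1", {
  cfg <- sim_config(n_mpas = 30, n_species = 10, years = 2021,
                    beta0 = 0, beta_age = 0, beta_habdiv = 0,
                    sigma_between = 0, zero_inflation_outside = 0,
                    replicate_count_range = c(20L, 20L), seed = 8)
  sim <- simulate_mpa_dataset(cfg)
  tot <- dplyr::summarise(sim$surveys,
                          total = sum(count),
                          .by = c("mpa_id", "ecosystem", "side"))
  wide <- tidyr::pivot_wider(tot, names_from = "side", values_from = "total")
  lr <- log(wide$inside / wide$outside)
  mc_se <- sd(lr) / sqrt(length(lr))
  expect_lt(abs(mean(lr)), 3 * mc_se + 0.02)
})

test_that("empirical per-MPA log biomass ratio recovers the recorded truth", {
  # generative consistency: large replicate counts, no between-MPA noise
  cfg <- sim_config(n_mpas = 8, n_species = 10, years = 2023,
                    sigma_between = 0, zero_inflation_outside = 0,
                    replicate_count_range = c(60L, 60L),
                    ecosystem_coverage = 1, seed = 21)
  sim <- simulate_mpa_dataset(cfg)
  st <- tibble::tibble(species_id = sim$species$species_id,
                       status = ifelse(sim$species$targeted_truth,
                                       "targeted", "nontargeted"))
  repl <- aggregate_replicate_biomass(sim$surveys, sim$species, st)
  tot <- dplyr::summarise(
    dplyr::filter(repl, status == "targeted"),
    m = mean(biomass), .by = c("mpa_id", "side"))
  wide <- tidyr::pivot_wider(tot, names_from = "side", values_from = "m")
  emp <- log(wide$inside / wide$outside)
  truth <- sim$network$true_effect_targeted[
    match(wide$mpa_id, sim$network$mpa_id)]
  mc_se <- sd(emp - truth) / sqrt(length(emp))
  expect_lt(abs(mean(emp - truth)), 3 * mc_se + 0.02)
})

test_that("CSV round trip preserves the survey table", {
  cfg <- sim_config(n_mpas = 2, n_species = 4, years = 2021, seed = 6)
  sim <- simulate_mpa_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_tables(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_surveys(file.path(dir, "surveys.csv"))
  expect_equal(nrow(back), nrow(sim$surveys))
  expect_equal(back$count, sim$surveys$count)
  expect_equal(unlist(back$lengths), unlist(sim$surveys$lengths),
               tolerance = 1e-3)
})
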