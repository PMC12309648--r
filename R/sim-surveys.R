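#' Simulate paired inside/outside survey observations
#'
#' Generates replicate-level survey records for every monitored
#' MPA x ecosystem x year x side combination. Ecosystem coverage is
#' subsampled (`ecosystem_coverage`), mirroring real monitoring networks
#' where not every MPA is surveyed in every ecosystem. Within a replicate,
#' per-species counts are negative-binomial with outside mean
#' `base_abundance * q` (catchability `q` is gear- and ecosystem-specific)
#' and inside mean multiplied by `exp(effect)`, where the effect is the
#' MPA's true log effect in that year for targeted species and its
#' attenuated multiple for nontargeted species. Outside replicates are
#' recorded as all-zero with probability `zero_inflation_outside`.
#' Individual body lengths are lognormal around the species median.
#'
#' Replicates in which no fish were recorded appear as a single row with
#' `species_id = NA` and `count = 0`, so the full replicate roster is
#' recoverable from the table.
#'
#' @param network Output of [generate_network()].
#' @param species Output of [generate_species_pool()].
#' @param config The [sim_config()] shared by both. The seed used is
#'   `config$seed + 2` so the survey stream is distinct from the species
#'   and network streams.
#'
#' @return A tibble of survey observations: `mpa_id`, `ecosystem`, `year`,
#'   `side` (`"inside"`/`"outside"`), `replicate_id`, `species_id`,
#'   `count`, and a `lengths` list-column of individual lengths (cm).
#' @export
simulate_surveys <- function(network, species, config) {
  if (nrow(network) == 0 || nrow(species) == 0) {
    stop_bad_arg("`network` and `species` must be non-empty")
  }
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  rr <- config$replicate_count_range

  # which ecosystems each MPA is monitored in
  cov <- tidyr::crossing(mpa_id = network$mpa_id,
                         ecosystem = config$ecosystems) |>
    arrange(.data$mpa_id, .data$ecosystem) |>
    mutate(keep = rbinom(n(), 1, config$ecosystem_coverage) == 1)
  none <- cov |> summarise(any = any(.data$keep), .by = "mpa_id") |>
    filter(!.data$any)
  if (nrow(none) > 0) {
    # guarantee every MPA is monitored somewhere
    forced <- sample(config$ecosystems, nrow(none), replace = TRUE)
    idx <- match(paste(none$mpa_id, forced), paste(cov$mpa_id, cov$ecosystem))
    cov$keep[idx] <- TRUE
  }
  cov <- filter(cov, .data$keep)

  roster <- tidyr::crossing(cov[c("mpa_id", "ecosystem")],
                            year = config$years,
                            side = c("inside", "outside")) |>
    arrange(.data$mpa_id, .data$ecosystem, .data$year, .data$side)
  roster$n_rep <- sample(seq(rr[1], rr[2]), nrow(roster), replace = TRUE)

  repl <- roster |>
    tidyr::uncount(.data$n_rep, .id = "rep") |>
    mutate(replicate_id = sprintf("r%02d", .data$rep), rep = NULL)
  repl$forced_zero <- repl$side == "outside" &
    rbinom(nrow(repl), 1, config$zero_inflation_outside) == 1

  q_long <- species |>
    select("species_id", dplyr::starts_with("q_")) |>
    tidyr::pivot_longer(dplyr::starts_with("q_"),
                        names_to = "ecosystem", names_prefix = "q_",
                        values_to = "q")

  eff <- tidyr::crossing(network, year = config$years)
  eff$effect <- true_effect_at(eff, eff$year, config)
  eff <- eff[, c("mpa_id", "year", "effect")]

  grid <- repl |>
    tidyr::crossing(species |> select("species_id", "lw_a", "lw_b",
                                      "targeted_truth", "base_abundance",
                                      "mean_length_cm", "length_cv")) |>
    inner_join(q_long, by = c("ecosystem", "species_id")) |>
    filter(.data$q > 0) |>
    left_join(eff, by = c("mpa_id", "year")) |>
    arrange(.data$mpa_id, .data$ecosystem, .data$year, .data$side,
            .data$replicate_id, .data$species_id)

  delta <- ifelse(grid$targeted_truth, grid$effect,
                  config$attenuation * grid$effect)
  mu <- grid$base_abundance * grid$q *
    ifelse(grid$side == "inside", exp(delta), 1)
  count <- rnbinom(nrow(grid), mu = mu, size = config$dispersion)
  count[grid$forced_zero] <- 0L
  grid$count <- count

  meanlog <- log(grid$mean_length_cm) +
    ifelse(grid$side == "inside", config$inside_length_shift, 0)
  sdlog <- sqrt(log(1 + grid$length_cv^2))
  all_len <- rlnorm(sum(count),
                    meanlog = rep.int(meanlog, count),
                    sdlog = rep.int(sdlog, count))
  grid$lengths <- chop_by_sizes(all_len, count)

  obs <- grid |>
    filter(.data$count > 0) |>
    select("mpa_id", "ecosystem", "year", "side", "replicate_id",
           "species_id", "count", "lengths")

  # sentinel rows for replicates in which nothing was caught
  empty <- repl |>
    anti_join(obs, by = c("mpa_id", "ecosystem", "year", "side",
                          "replicate_id")) |>
    transmute(.data$mpa_id, .data$ecosystem, .data$year, .data$side,
              .data$replicate_id, species_id = NA_character_,
              count = 0L, lengths = list(numeric(0)))

  bind_rows(obs, empty) |>
    arrange(.data$mpa_id, .data$ecosystem, .data$year, .data$side,
            .data$replicate_id, .data$species_id)
}

chop_by_sizes <- function(x, sizes) {
  out <- rep(list(numeric(0)), length(sizes))
  nz <- sizes > 0
  if (any(nz)) {
    f <- rep.int(seq_along(sizes), sizes)
    out[nz] <- unname(split(x, factor(f, levels = unique(f))))
  }
  out
}

#' Simulate a full synthetic dataset in one call
#'
#' Runs [generate_species_pool()], [generate_network()] and
#' [simulate_surveys()] under the single seed in `config`.
#'
#' @param config An [sim_config()].
#' @return A list of class `mpa_sim` with elements `species`, `network`,
#'   `surveys` and `config`.
#' @export
#' @examples
#' sim <- simulate_mpa_dataset(sim_config(n_mpas = 4, n_species = 6,
#'                                        years = 2020:2021, seed = 9))
#' nrow(sim$surveys)
simulate_mpa_dataset <- function(config = sim_config()) {
  species <- generate_species_pool(config$n_species, seed = config$seed,
                                   config = config)
  network <- generate_network(config)
  surveys <- simulate_surveys(network, species, config)
  structure(list(species = species, network = network, surveys = surveys,
                 config = config),
            class = "mpa_sim")
}

#' Write the synthetic tables to CSV
#'
#' Writes `species.csv`, `mpas.csv` and `surveys.csv` (individual lengths
#' collapsed into a `;`-separated string) plus a JSON sidecar
#' `sim_config.json` recording the configuration and draw bounds.
#'
#' @param sim Output of [simulate_mpa_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("species.csv", "mpas.csv", "surveys.csv",
                            "sim_config.json"))
  write.csv(sim$species, paths[1], row.names = FALSE)
  write.csv(sim$network, paths[2], row.names = FALSE)
  surv <- sim$surveys
  surv$lengths <- vapply(surv$lengths,
                         function(l) paste(sprintf("%.4f", l), collapse = ";"),
                         character(1))
  write.csv(surv, paths[3], row.names = FALSE)
  cfg <- unclass(sim$config)
  cfg$draw_bounds <- attr(sim$species, "draw_bounds")
  jsonlite::write_json(cfg, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a surveys table written by [write_sim_tables()]
#'
#' @param path Path to `surveys.csv`.
#' @return A survey tibble with the `lengths` list-column restored.
#' @export
read_surveys <- function(path) {
  surv <- as_tibble_strict(utils::read.csv(path, stringsAsFactors = FALSE))
  surv$lengths <- lapply(surv$lengths, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0) else as.numeric(strsplit(s, ";")[[1]])
  })
  surv
}

#' Simulate paired lognormal survey summaries
#'
#' A lightweight generator used for statistical calibration: `k`
#' independent studies, each with `n` lognormal replicates inside and
#' outside, where the inside meanlog is shifted by `delta`. Returns
#' paired summaries ready for [effect_sizes()]-style computation of log
#' response ratios and variances.
#'
#' @param k Number of studies (ecosystem-MPA combinations).
#' @param n Replicates per side.
#' @param delta True log effect (shift of the inside meanlog).
#' @param sdlog Lognormal sdlog of replicate values.
#' @param meanlog Baseline (outside) meanlog.
#' @param seed Optional integer seed.
#' @return A tibble with columns `mpa_id`, `ecosystem`, `year`, `status`,
#'   `mean_inside`, `mean_outside`, `sd_inside`, `sd_outside`,
#'   `n_inside`, `n_outside`.
#' @export
simulate_paired_lognormal <- function(k, n, delta = 0, sdlog = 0.5,
                                      meanlog = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one <- function(i) {
    inside <- rlnorm(n, meanlog + delta, sdlog)
    outside <- rlnorm(n, meanlog, sdlog)
    tibble(mpa_id = sprintf("mpa_%03d", i), ecosystem = "kelp_forest",
           year = 2023L, status = "targeted",
           mean_inside = mean(inside), mean_outside = mean(outside),
           sd_inside = sd(inside), sd_outside = sd(outside),
           n_inside = n, n_outside = n)
  }
  purrr::map_dfr(seq_len(k), one)
}
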