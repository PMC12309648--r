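#' Generate a synthetic species pool
#'
#' Draws a pool of fish species with allometric length-weight parameters
#' (weight in grams = `lw_a * length_cm ^ lw_b`), a true target status,
#' simulated annual fisheries catch volumes consistent with that status,
#' per-ecosystem gear catchabilities, and the baseline abundance and body
#' size distribution used by [simulate_surveys()].
#'
#' The first two species are forced to be one targeted and one
#' nontargeted, so both statuses are always represented. Because the
#' shallow reef is sampled by hook and line — the same gear fishers use —
#' nontargeted species have catchability 0 there and never appear in
#' shallow-reef surveys.
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param config An [sim_config()] supplying draw ranges.
#'
#' @return A tibble with one row per species: `species_id`, `lw_a`,
#'   `lw_b`, `targeted_truth`, `annual_catch`, `base_abundance`,
#'   `mean_length_cm`, `length_cv`, and catchability columns
#'   `q_<ecosystem>`. The draw bounds actually used are recorded in the
#'   `draw_bounds` attribute.
#' @export
#' @examples
#' sp <- generate_species_pool(6, seed = 1)
#' sp[, c("species_id", "lw_a", "lw_b", "targeted_truth")]
generate_species_pool <- function(n_species, seed = NULL,
                                  config = sim_config(n_species = n_species)) {
  if (n_species < 2) stop_bad_arg("`n_species` must be at least 2")
  if (!is.null(seed)) set.seed(seed)

  lw_a <- exp(runif(n_species, log(config$lw_a_range[1]), log(config$lw_a_range[2])))
  lw_b <- runif(n_species, config$lw_b_range[1], config$lw_b_range[2])
  targeted <- as.logical(rbinom(n_species, 1, 0.5))
  targeted[1:2] <- c(TRUE, FALSE)

  # catch volumes consistent with status: targeted species have substantial
  # landings, nontargeted are either absent from catch records or
  # low-volume bycatch
  catch <- numeric(n_species)
  catch[targeted] <- rlnorm(sum(targeted), meanlog = log(200), sdlog = 1)
  bycatch <- !targeted & as.logical(rbinom(n_species, 1, 0.3))
  catch[bycatch] <- runif(sum(bycatch), 0, 5)

  base_ab <- exp(runif(n_species,
                       log(config$base_abundance_range[1]),
                       log(config$base_abundance_range[2])))
  mean_len <- runif(n_species, config$mean_length_range[1],
                    config$mean_length_range[2])

  sp <- tibble(
    species_id = sprintf("sp_%03d", seq_len(n_species)),
    lw_a = lw_a, lw_b = lw_b,
    targeted_truth = targeted,
    annual_catch = catch,
    base_abundance = base_ab,
    mean_length_cm = mean_len,
    length_cv = config$length_cv
  )
  for (eco in config$ecosystems) {
    q <- runif(n_species, 0.6, 1)
    if (eco == "shallow_reef") q[!targeted] <- 0
    sp[[paste0("q_", eco)]] <- q
  }

  attr(sp, "draw_bounds") <- list(
    lw_a = config$lw_a_range, lw_b = config$lw_b_range,
    base_abundance = config$base_abundance_range,
    mean_length_cm = config$mean_length_range
  )
  sp
}
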