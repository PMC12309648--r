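#' Configuration for the synthetic MPA survey generator
#'
#' Bundles every knob of the synthetic-data module into a validated list.
#' The generator emulates a statewide network of marine protected areas
#' (MPAs) monitored with a paired design: replicate sampling units (seine
#' hauls, transects, or fishing cells) surveyed inside each MPA and at a
#' neighbouring fished reference area, across four ecosystems and four
#' coastal regions.
#'
#' The true protection effect for targeted species in MPA *j* surveyed in
#' year *t* is, on the log scale of expected abundance,
#' \deqn{\delta_{jt} = m_j\,(\beta_0 + \beta_{age}\,a_{jt} +
#'   \beta_{hd}\,H_j + b_j), \qquad b_j \sim N(0, \sigma_b^2),}
#' where \eqn{a_{jt}} is MPA age in years, \eqn{H_j} its habitat
#' diversity, \eqn{m_j} is 1 for no-take MPAs and
#' `partial_take_multiplier` for partial-take MPAs, and the effect is 0
#' before implementation. Nontargeted species respond with an attenuated
#' multiple (`attenuation`) of \eqn{\delta_{jt}}: they experience only
#' indirect effects of protection and act as a quasi-control.
#'
#' @param n_mpas Number of MPAs in the network.
#' @param n_species Number of species in the pool (at least 2).
#' @param years Integer vector of survey years.
#' @param regions,ecosystems Labels for the four regions / ecosystems.
#' @param beta0 Baseline log effect of no-take protection on targeted
#'   species abundance.
#' @param beta_age Per-year slope of the true effect on MPA age.
#' @param beta_habdiv Slope of the true effect on habitat diversity.
#' @param sigma_between Between-MPA SD of the true effect (log scale).
#' @param attenuation Multiplier applied to the targeted-species effect to
#'   obtain the nontargeted-species effect (default 0.25).
#' @param partial_take_multiplier Multiplier applied to the effect in
#'   partial-take MPAs relative to no-take MPAs.
#' @param prop_no_take Probability that an MPA is no-take.
#' @param replicate_count_range Integer interval (min, max) of replicate
#'   units per MPA x ecosystem x year x side; minimum must be >= 2 so that
#'   a variance is computable.
#' @param dispersion Negative-binomial size parameter for replicate counts
#'   (smaller = more overdispersed).
#' @param zero_inflation_outside Probability that an outside (reference)
#'   replicate is recorded with no fish at all.
#' @param ecosystem_coverage Probability that a given MPA is monitored in
#'   a given ecosystem (not every MPA is sampled in every ecosystem).
#' @param base_abundance_range Log-uniform range of the mean outside
#'   count per species per replicate.
#' @param lw_a_range Log-uniform draw range for the length-weight
#'   coefficient *a* (weight in g for length in cm).
#' @param lw_b_range Uniform draw range for the allometric exponent *b*.
#' @param mean_length_range Uniform draw range (cm) of the species median
#'   body length.
#' @param length_cv Coefficient of variation of individual body lengths
#'   (lognormal).
#' @param inside_length_shift Additive shift, on the log-length scale,
#'   applied to fish inside MPAs (0 = protection acts on abundance only).
#' @param seed Integer seed; all draws flow from it in documented order
#'   (species pool, then network, then surveys).
#'
#' @return A list of class `mpa_sim_config`.
#' @seealso [generate_species_pool()], [generate_network()],
#'   [simulate_surveys()], [simulate_mpa_dataset()]
#' @export
#' @examples
#' cfg <- sim_config(n_mpas = 6, n_species = 8, years = 2019:2021, seed = 42)
#' cfg$beta0
sim_config <- function(n_mpas = 50,
                       n_species = 20,
                       years = 2018:2023,
                       regions = c("north", "north_central", "central", "south"),
                       ecosystems = c("surf_zone", "kelp_forest",
                                      "shallow_reef", "deep_reef"),
                       beta0 = 0.5,
                       beta_age = 0.02,
                       beta_habdiv = 0.15,
                       sigma_between = 0.2,
                       attenuation = 0.25,
                       partial_take_multiplier = 0.4,
                       prop_no_take = 0.6,
                       replicate_count_range = c(4L, 8L),
                       dispersion = 4,
                       zero_inflation_outside = 0.05,
                       ecosystem_coverage = 0.75,
                       base_abundance_range = c(0.1, 2),
                       lw_a_range = c(0.005, 0.05),
                       lw_b_range = c(2.5, 3.5),
                       mean_length_range = c(8, 40),
                       length_cv = 0.25,
                       inside_length_shift = 0,
                       seed = 1L) {
  cfg <- list(
    n_mpas = as.integer(n_mpas), n_species = as.integer(n_species),
    years = as.integer(years), regions = regions, ecosystems = ecosystems,
    beta0 = beta0, beta_age = beta_age, beta_habdiv = beta_habdiv,
    sigma_between = sigma_between, attenuation = attenuation,
    partial_take_multiplier = partial_take_multiplier,
    prop_no_take = prop_no_take,
    replicate_count_range = as.integer(replicate_count_range),
    dispersion = dispersion,
    zero_inflation_outside = zero_inflation_outside,
    ecosystem_coverage = ecosystem_coverage,
    base_abundance_range = base_abundance_range,
    lw_a_range = lw_a_range, lw_b_range = lw_b_range,
    mean_length_range = mean_length_range, length_cv = length_cv,
    inside_length_shift = inside_length_shift,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "mpa_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_mpas < 1) stop_bad_arg("`n_mpas` must be a positive integer")
  if (cfg$n_species < 2) stop_bad_arg("`n_species` must be at least 2")
  if (length(cfg$years) < 1) stop_bad_arg("`years` must be non-empty")
  for (p in c("prop_no_take", "zero_inflation_outside", "ecosystem_coverage")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop_bad_arg(sprintf("`%s` must lie in [0, 1]", p))
    }
  }
  if (cfg$sigma_between < 0) stop_bad_arg("`sigma_between` must be >= 0")
  if (cfg$dispersion <= 0) stop_bad_arg("`dispersion` must be > 0")
  rr <- cfg$replicate_count_range
  if (length(rr) != 2 || rr[1] > rr[2]) {
    stop_bad_arg("`replicate_count_range` must be an interval c(min, max)")
  }
  if (rr[1] < 2) {
    stop_bad_arg("`replicate_count_range` minimum must be >= 2 (a variance must be computable)")
  }
  if (any(cfg$lw_a_range <= 0) || any(cfg$lw_b_range <= 0)) {
    stop_bad_arg("length-weight parameter ranges must be positive")
  }
  invisible(cfg)
}

#' @export
print.mpa_sim_config <- function(x, ...) {
  cat("<mpa_sim_config>\n")
  cat(sprintf("  %d MPAs, %d species, years %d-%d, seed %d\n",
              x$n_mpas, x$n_species, min(x$years), max(x$years), x$seed))
  cat(sprintf("  effect: beta0 %.3g + %.3g*age + %.3g*habdiv, sigma_b %.3g\n",
              x$beta0, x$beta_age, x$beta_habdiv, x$sigma_between))
  cat(sprintf("  attenuation %.3g (nontargeted), partial-take multiplier %.3g\n",
              x$attenuation, x$partial_take_multiplier))
  invisible(x)
}
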