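#' MPA-level species richness and Shannon diversity
#'
#' Richness and diversity are computed at the MPA level — abundances are
#' first summed across all replicate units of a given
#' (MPA, ecosystem, year, side) — because sampling is often depth
#' stratified and many species are associated with particular depths,
#' making replicate-level community metrics unrepresentative. Richness is
#' the count of species with positive total abundance; Shannon diversity
#' is \eqn{H = -\sum_i p_i \ln p_i} over species relative abundances
#' (natural log, computed with [vegan::diversity()]).
#'
#' @param observations Survey observations (see [simulate_surveys()] for
#'   the schema); rows with `species_id = NA` mark empty replicates.
#' @return A tibble with one row per (mpa_id, ecosystem, year, side):
#'   `richness`, `shannon`, and an `empty` flag for sides with zero total
#'   abundance (both metrics 0).
#' @export
#' @examples
#' obs <- tibble::tibble(mpa_id = "m1", ecosystem = "kelp_forest",
#'                       year = 2020, side = "inside", replicate_id = "r1",
#'                       species_id = c("a", "b", "c"), count = c(2, 2, 4))
#' mpa_level_metrics(obs)$shannon  # about 1.0397
mpa_level_metrics <- function(observations) {
  check_columns(observations, c("mpa_id", "ecosystem", "year", "side",
                                "species_id", "count"),
                "`observations`")
  if (nrow(observations) == 0) stop_bad_arg("`observations` must be non-empty")

  sides <- distinct(as_tibble_strict(observations),
                    .data$mpa_id, .data$ecosystem, .data$year, .data$side)

  ab <- observations |>
    filter(!is.na(.data$species_id), .data$count > 0) |>
    summarise(abundance = sum(.data$count),
              .by = c("mpa_id", "ecosystem", "year", "side", "species_id"))

  metrics <- ab |>
    summarise(richness = sum(.data$abundance > 0),
              shannon = vegan::diversity(.data$abundance, index = "shannon"),
              .by = c("mpa_id", "ecosystem", "year", "side"))

  sides |>
    left_join(metrics, by = c("mpa_id", "ecosystem", "year", "side")) |>
    mutate(empty = is.na(.data$richness),
           richness = ifelse(.data$empty, 0L, .data$richness),
           shannon = ifelse(.data$empty, 0, .data$shannon)) |>
    arrange(.data$mpa_id, .data$ecosystem, .data$year, .data$side)
}

#' Log response ratios of richness and diversity
#'
#' Pairs the inside and outside diversity records of each
#' (MPA, ecosystem, year), applies the same zero-adjustment machinery as
#' the biomass effect sizes (strata keyed by metric, ecosystem, year and
#' protection level), and returns the log response ratio per metric.
#' Pairs that remain undefined (all-zero stratum) are excluded with a
#' recorded reason.
#'
#' @param records Output of [mpa_level_metrics()].
#' @param mpas Optional MPA table supplying `protection` (and `region`)
#'   per `mpa_id` (or per `mpa_id` x `ecosystem`).
#' @param zero_adjust_mode Passed to [zero_adjust()].
#' @return A tibble with columns `mpa_id`, `ecosystem`, `year`, `metric`
#'   (`"richness"`/`"shannon"`), `Y`; attributes `"exclusions"` and
#'   `"constants"`.
#' @export
diversity_response <- function(records, mpas = NULL,
                               zero_adjust_mode = c("zero_pairs",
                                                    "all_pairs")) {
  zero_adjust_mode <- match.arg(zero_adjust_mode)
  check_columns(records, c("mpa_id", "ecosystem", "year", "side",
                           "richness", "shannon"), "`records`")

  long <- records |>
    tidyr::pivot_longer(c("richness", "shannon"),
                        names_to = "metric", values_to = "value") |>
    tidyr::pivot_wider(id_cols = c("mpa_id", "ecosystem", "year", "metric"),
                       names_from = "side", values_from = "value")

  one_sided <- is.na(long$inside) | is.na(long$outside)
  excl <- long[one_sided, c("mpa_id", "ecosystem", "year", "metric")]
  excl$reason <- rep("missing_side", nrow(excl))
  long <- long[!one_sided, ]
  long <- dplyr::rename(long, mean_inside = "inside", mean_outside = "outside")

  if (!is.null(mpas)) {
    keep <- intersect(c("mpa_id", "ecosystem", "region", "protection"),
                      names(mpas))
    by <- intersect(c("mpa_id", "ecosystem"), keep)
    long <- left_join(long, mpas[keep], by = by)
  }
  if (!"protection" %in% names(long)) long$protection <- NA_character_

  adj <- zero_adjust(long, mode = zero_adjust_mode)
  undefined <- adj$mean_inside_adj <= 0 | adj$mean_outside_adj <= 0
  excl <- bind_rows(
    excl,
    adj[undefined, c("mpa_id", "ecosystem", "year", "metric")] |>
      mutate(reason = "all_zero_stratum"))

  res <- adj[!undefined, ]
  res$Y <- log_response_ratio(res$mean_inside_adj, res$mean_outside_adj)
  res <- res |>
    select("mpa_id", "ecosystem", "year", "metric", "Y",
           dplyr::any_of(c("protection", "region")), "zero_adjusted") |>
    arrange(.data$mpa_id, .data$ecosystem, .data$year, .data$metric)
  attr(res, "exclusions") <- excl
  attr(res, "constants") <- attr(adj, "constants")
  res
}

#' Per-ecosystem t-test of diversity log response ratios
#'
#' Two-tailed one-sample t-test of the log response ratios against zero,
#' for each ecosystem and metric. By default only the most recent year
#' per MPA enters the test, avoiding pseudo-replication from repeated
#' surveys of the same MPA; set `most_recent_only = FALSE` to pool all
#' MPA-years.
#'
#' @param responses Output of [diversity_response()].
#' @param most_recent_only Keep only each MPA's most recent year per
#'   ecosystem and metric (default `TRUE`).
#' @return A tibble with one row per (ecosystem, metric): `n`, `mean_Y`,
#'   `t`, `df`, `p`, and a `note` column flagging degenerate groups
#'   (fewer than 2 responses, or zero variance).
#' @export
ecosystem_ttest <- function(responses, most_recent_only = TRUE) {
  check_columns(responses, c("mpa_id", "ecosystem", "year", "metric", "Y"),
                "`responses`")
  dat <- as_tibble_strict(responses)
  if (most_recent_only) {
    dat <- dat |>
      dplyr::slice_max(.data$year, n = 1, with_ties = FALSE,
                       by = c("mpa_id", "ecosystem", "metric"))
  }

  dat |>
    dplyr::group_by(.data$ecosystem, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      y <- d$Y
      if (length(y) < 2) {
        return(tibble(n = length(y), mean_Y = mean(y), t = NA_real_,
                      df = NA_real_, p = NA_real_,
                      note = "insufficient_data"))
      }
      if (sd(y) == 0) {
        return(tibble(n = length(y), mean_Y = mean(y), t = NA_real_,
                      df = length(y) - 1, p = NA_real_,
                      note = "zero_variance"))
      }
      tt <- t.test(y, mu = 0, alternative = "two.sided")
      tibble(n = length(y), mean_Y = mean(y),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, note = NA_character_)
    }) |>
    dplyr::ungroup()
}
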