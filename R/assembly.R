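#' Classify species target status from fisheries catch records
#'
#' Two-stage classification: any species with positive annual catch is
#' targeted, except that low-volume bycatch species (catch at or below
#' `bycatch_threshold`) are reclassified as nontargeted. Manual overrides
#' are applied last; they implement the re-inclusion of cryptic species
#' that are targeted by fishers but poorly represented in catch records.
#'
#' @param catch_table Data frame with columns `species_id` and
#'   `annual_catch` (nonnegative).
#' @param bycatch_threshold Catch volume at or below which a caught
#'   species is still treated as nontargeted. The threshold is a study
#'   design choice; the default of 0 reclassifies nothing.
#' @param overrides Named character vector or list mapping `species_id`
#'   to `"targeted"` / `"nontargeted"`; applied after the catch rule.
#'
#' @return A tibble with columns `species_id` and
#'   `status` (`"targeted"`/`"nontargeted"`).
#' @export
#' @examples
#' classify_target_status(
#'   data.frame(species_id = c("A", "B"), annual_catch = c(1000, 0)))
classify_target_status <- function(catch_table, bycatch_threshold = 0,
                                   overrides = NULL) {
  check_columns(catch_table, c("species_id", "annual_catch"), "`catch_table`")
  if (any(catch_table$annual_catch < 0)) {
    stop_bad_arg("`annual_catch` must be nonnegative")
  }
  if (bycatch_threshold < 0) stop_bad_arg("`bycatch_threshold` must be >= 0")

  out <- tibble(
    species_id = catch_table$species_id,
    status = ifelse(catch_table$annual_catch > 0 &
                      catch_table$annual_catch > bycatch_threshold,
                    "targeted", "nontargeted")
  )
  if (length(overrides)) {
    ov <- unlist(overrides)
    bad <- setdiff(ov, STATUSES)
    if (length(bad)) {
      stop_bad_arg(sprintf("override status must be one of %s",
                           paste(STATUSES, collapse = ", ")))
    }
    hit <- match(out$species_id, names(ov))
    out$status <- ifelse(is.na(hit), out$status, ov[hit])
  }
  out
}

#' Classify regulatory protection, including de facto no-take status
#'
#' An MPA is no-take for an ecosystem when it formally prohibits all take,
#' or when the take it allows is flagged as not affecting the species that
#' reside in that ecosystem (a *de facto* no-take MPA — e.g. an SMCA that
#' allows only salmon take does not affect nearshore reef residents).
#' Otherwise it is partial-take.
#'
#' @param regulations Data frame with one row per MPA x ecosystem:
#'   `mpa_id`, `ecosystem`, `allows_take` (logical; does the MPA allow any
#'   extraction) and `take_affects_ecosystem` (logical; does the allowed
#'   take affect this ecosystem's resident species; ignored when
#'   `allows_take` is `FALSE`).
#'
#' @return The regulations tibble with a `protection` column
#'   (`"no_take"`/`"partial_take"`).
#' @export
#' @examples
#' regs <- data.frame(mpa_id = "m1", ecosystem = "kelp_forest",
#'                    allows_take = TRUE, take_affects_ecosystem = FALSE)
#' classify_protection(regs)$protection  # de facto no-take
classify_protection <- function(regulations) {
  check_columns(regulations,
                c("mpa_id", "ecosystem", "allows_take",
                  "take_affects_ecosystem"),
                "`regulations`")
  if (anyNA(regulations$allows_take)) {
    stop_missing_data("`allows_take` contains missing values")
  }
  affected <- regulations$allows_take &
    (is.na(regulations$take_affects_ecosystem) |
       regulations$take_affects_ecosystem)
  as_tibble_strict(regulations) |>
    mutate(protection = ifelse(affected, "partial_take", "no_take"))
}

#' Look up protection for one MPA x ecosystem pair
#'
#' @inheritParams classify_protection
#' @param mpa_id,ecosystem The pair to look up.
#' @return `"no_take"` or `"partial_take"`.
#' @export
protection_for <- function(mpa_id, ecosystem, regulations) {
  cls <- classify_protection(regulations)
  row <- cls[cls$mpa_id == mpa_id & cls$ecosystem == ecosystem, ]
  if (nrow(row) == 0) {
    stop_missing_data(sprintf("no regulation row for MPA '%s' x ecosystem '%s'",
                              mpa_id, ecosystem))
  }
  row$protection[[1]]
}

#' Allometric length-to-weight conversion
#'
#' Converts fish length (cm) to weight (g) with the standard allometric
#' power law `W = a * L^b`.
#'
#' @param length_cm Length(s) in cm; must be positive.
#' @param lw_a,lw_b Species length-weight parameters; must be positive.
#' @return Weight(s) in grams.
#' @export
#' @examples
#' length_to_weight(10, 0.01, 3)  # 10 g
length_to_weight <- function(length_cm, lw_a, lw_b) {
  if (any(length_cm <= 0) || any(lw_a <= 0) || any(lw_b <= 0)) {
    stop_bad_arg("`length_cm`, `lw_a` and `lw_b` must all be positive")
  }
  lw_a * length_cm^lw_b
}

#' Aggregate biomass at the smallest replicable unit
#'
#' Sums fish biomass within each replicate sampling unit (seine haul,
#' transect, or fishing cell), separately for targeted and nontargeted
#' species. Individual lengths are converted with [length_to_weight()];
#' counts recorded without individual lengths use the species' configured
#' mean length as a documented fallback. Every replicate contributes an
#' explicit row for *both* statuses — zero biomass when no fish of that
#' status were recorded — so that downstream means include true zeros.
#'
#' @param observations Survey observations (see [simulate_surveys()] for
#'   the schema). Rows with `species_id = NA` mark empty replicates.
#' @param species Species table with `species_id`, `lw_a`, `lw_b` and,
#'   for the no-lengths fallback, `mean_length_cm`.
#' @param status_map Output of [classify_target_status()].
#'
#' @return A tibble with one row per replicate x status: `mpa_id`,
#'   `ecosystem`, `year`, `side`, `replicate_id`, `status`, `biomass` (g).
#' @export
aggregate_replicate_biomass <- function(observations, species, status_map) {
  check_columns(observations,
                c("mpa_id", "ecosystem", "year", "side", "replicate_id",
                  "species_id", "count"),
                "`observations`")
  obs <- as_tibble_strict(observations)
  seen <- unique(obs$species_id[!is.na(obs$species_id)])
  unknown <- union(setdiff(seen, species$species_id),
                   setdiff(seen, status_map$species_id))
  if (length(unknown)) {
    stop_missing_data(
      sprintf("species without length-weight parameters or status: %s",
              paste(unknown, collapse = ", ")),
      offenders = unknown)
  }

  roster <- distinct(obs, .data$mpa_id, .data$ecosystem, .data$year,
                     .data$side, .data$replicate_id)

  fish <- obs |>
    filter(!is.na(.data$species_id), .data$count > 0) |>
    left_join(select(species, "species_id", "lw_a", "lw_b",
                     dplyr::any_of("mean_length_cm")),
              by = "species_id") |>
    left_join(status_map, by = "species_id")

  if (nrow(fish)) {
    has_len <- if ("lengths" %in% names(fish)) {
      lengths(fish$lengths) > 0
    } else {
      rep(FALSE, nrow(fish))
    }
    if (any(has_len)) {
      n_len <- lengths(fish$lengths)[has_len]
      if (any(n_len != fish$count[has_len])) {
        stop_bad_arg("when individual lengths are recorded, their number must equal `count`")
      }
    }
    weight_of <- function(lens, count, a, b, mean_len, use_lens) {
      if (use_lens) sum(length_to_weight(lens, a, b))
      else count * length_to_weight(mean_len, a, b)
    }
    if (!all(has_len) && !"mean_length_cm" %in% names(fish)) {
      stop_missing_data("counts without individual lengths require `mean_length_cm` in the species table")
    }
    fish$biomass <- purrr::pmap_dbl(
      list(if ("lengths" %in% names(fish)) fish$lengths else list(numeric(0)),
           fish$count, fish$lw_a, fish$lw_b,
           if ("mean_length_cm" %in% names(fish)) fish$mean_length_cm else NA_real_,
           has_len),
      weight_of)
  } else {
    fish$biomass <- numeric(0)
  }

  agg <- fish |>
    summarise(biomass = sum(.data$biomass),
              .by = c("mpa_id", "ecosystem", "year", "side", "replicate_id",
                      "status"))

  # explicit zero rows: every replicate reports both statuses
  tidyr::crossing(roster, status = STATUSES) |>
    left_join(agg, by = c("mpa_id", "ecosystem", "year", "side",
                          "replicate_id", "status")) |>
    mutate(biomass = ifelse(is.na(.data$biomass), 0, .data$biomass)) |>
    arrange(.data$mpa_id, .data$ecosystem, .data$year, .data$side,
            .data$replicate_id, .data$status)
}

#' Summarize paired inside/outside replicates
#'
#' Collapses replicate-level biomass to one row per
#' (MPA, ecosystem, year, status): means, sample standard deviations
#' (denominator n - 1) and replicate counts for each side. Groups missing
#' one side cannot form a pair; they are emitted to the exclusion report
#' (attribute `"exclusions"`, also returned by [pair_exclusions()]) rather
#' than silently dropped. A side with a single replicate has its SD
#' recorded as 0 and is flagged (`sd_undefined`).
#'
#' @param replicate_biomass Output of [aggregate_replicate_biomass()].
#' @param value Name of the value column to summarise (default
#'   `"biomass"`).
#' @return A tibble of paired summaries with columns `mpa_id`,
#'   `ecosystem`, `year`, `status`, `mean_inside`, `mean_outside`,
#'   `sd_inside`, `sd_outside`, `n_inside`, `n_outside`, `sd_undefined`.
#' @export
summarize_pairs <- function(replicate_biomass, value = "biomass") {
  check_columns(replicate_biomass,
                c("mpa_id", "ecosystem", "year", "side", "status", value),
                "`replicate_biomass`")
  side_stats <- replicate_biomass |>
    summarise(mean = mean(.data[[value]]),
              sd = ifelse(n() > 1, sd(.data[[value]]), 0),
              n = n(),
              .by = c("mpa_id", "ecosystem", "year", "status", "side"))

  wide <- side_stats |>
    tidyr::pivot_wider(names_from = "side",
                       values_from = c("mean", "sd", "n"))
  for (col in c("mean_inside", "mean_outside", "sd_inside", "sd_outside",
                "n_inside", "n_outside")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }

  missing_side <- is.na(wide$n_inside) | is.na(wide$n_outside)
  excl <- wide[missing_side, c("mpa_id", "ecosystem", "year", "status")]
  if (nrow(excl)) {
    excl$reason <- ifelse(is.na(wide$n_inside[missing_side]),
                          "no_inside_replicates", "no_outside_replicates")
  } else {
    excl$reason <- character(0)
  }

  out <- wide[!missing_side, ] |>
    mutate(sd_undefined = .data$n_inside < 2 | .data$n_outside < 2) |>
    select("mpa_id", "ecosystem", "year", "status",
           "mean_inside", "mean_outside", "sd_inside", "sd_outside",
           "n_inside", "n_outside", "sd_undefined") |>
    arrange(.data$mpa_id, .data$ecosystem, .data$year, .data$status)
  attr(out, "exclusions") <- as_tibble_strict(excl)
  out
}

#' Exclusion report attached to a paired summary or effect-size table
#'
#' @param x Output of [summarize_pairs()], [effect_sizes()] or
#'   [diversity_response()].
#' @return A tibble of excluded groups with a `reason` column (empty if
#'   nothing was excluded).
#' @export
pair_exclusions <- function(x) {
  attr(x, "exclusions") %||% tibble()
}
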