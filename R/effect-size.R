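#' Zero-adjust paired means with a stratum-level fractional constant
#'
#' Log response ratios are undefined when either member of an
#' inside/outside pair is zero. Following the fractional-constant rule, a
#' constant equal to 10% of the mean of all values in the same stratum —
#' by default (ecosystem, year, protection level, and any `status`/
#' `metric` column present), computed separately for inside and outside
#' values — is added to both members of any pair that contains a zero.
#' Adding to both members avoids biasing the ratio toward either side; a
#' fractional (rather than fixed) constant respects interannual
#' variability in the scale of the data. With `mode = "all_pairs"` the
#' constant is added to every pair in the stratum (sensitivity analysis).
#'
#' A stratum whose values are all zero yields a constant of 0; its pairs
#' remain undefined and are excluded downstream with a recorded reason.
#'
#' @param pairs Paired summaries (see [summarize_pairs()]) with at least
#'   `mean_inside` and `mean_outside`, plus the stratum columns.
#' @param mode `"zero_pairs"` (default: adjust only pairs containing a
#'   zero) or `"all_pairs"`.
#' @param strata Character vector of stratum columns; defaults to those
#'   of `"metric"`, `"status"`, `"ecosystem"`, `"year"`, `"protection"`
#'   present in `pairs`. Inside and outside values always form separate
#'   strata.
#'
#' @return `pairs` with added columns `mean_inside_adj`,
#'   `mean_outside_adj` and `zero_adjusted`; the per-stratum constants are
#'   attached as the `"constants"` attribute (see [adjust_constants()]).
#' @export
#' @examples
#' p <- tibble::tibble(ecosystem = "kelp_forest", year = 2020,
#'                     protection = "no_take",
#'                     mean_inside = c(1, 2, 3, 0),
#'                     mean_outside = c(0, 1, 2, 3))
#' zero_adjust(p)$mean_inside_adj  # pair 1 becomes (1.15, 0.15)
zero_adjust <- function(pairs, mode = c("zero_pairs", "all_pairs"),
                        strata = NULL) {
  mode <- match.arg(mode)
  check_columns(pairs, c("mean_inside", "mean_outside"), "`pairs`")
  if (any(pairs$mean_inside < 0) || any(pairs$mean_outside < 0)) {
    stop_bad_arg("paired means must be nonnegative before zero-adjustment")
  }
  strata <- strata %||%
    intersect(c("metric", "status", "ecosystem", "year", "protection"),
              names(pairs))
  out <- as_tibble_strict(pairs)

  grp <- if (length(strata)) {
    do.call(paste, c(out[strata], sep = "\r"))
  } else {
    rep("", nrow(out))
  }
  c_in <- stats::ave(out$mean_inside, grp, FUN = function(v) 0.10 * mean(v))
  c_out <- stats::ave(out$mean_outside, grp, FUN = function(v) 0.10 * mean(v))

  affected <- if (mode == "zero_pairs") {
    out$mean_inside == 0 | out$mean_outside == 0
  } else {
    rep(TRUE, nrow(out))
  }
  out$mean_inside_adj <- out$mean_inside + ifelse(affected, c_in, 0)
  out$mean_outside_adj <- out$mean_outside + ifelse(affected, c_out, 0)
  out$zero_adjusted <- affected & (c_in > 0 | c_out > 0)

  consts <- dplyr::distinct(dplyr::bind_cols(
    out[strata],
    tibble(constant_inside = c_in, constant_outside = c_out)))
  attr(out, "constants") <- consts
  out
}

#' Per-stratum zero-adjustment constants
#'
#' @param x Output of [zero_adjust()] or [effect_sizes()].
#' @return A tibble of stratum keys and their inside/outside constants.
#' @export
adjust_constants <- function(x) {
  attr(x, "constants") %||% tibble()
}

#' Log response ratio of paired means
#'
#' The unitless effect size used throughout the package:
#' \eqn{Y = \ln(\bar{X}_{inside} / \bar{X}_{outside})}. Positive values
#' indicate a higher metric inside the MPA. Natural logarithms are used.
#'
#' @param mean_inside,mean_outside Positive means (after any
#'   zero-adjustment).
#' @return The log response ratio(s).
#' @export
#' @examples
#' log_response_ratio(1.15, 0.15)  # about 2.0369
log_response_ratio <- function(mean_inside, mean_outside) {
  if (any(mean_inside <= 0) || any(mean_outside <= 0)) {
    abort("log response ratio undefined: nonpositive mean after adjustment",
          class = "mpameta_undefined_ratio")
  }
  log(mean_inside / mean_outside)
}

#' Within-study variance of a paired log response ratio
#'
#' Computes the sampling variance attached to one ecosystem-MPA effect
#' size. Two forms are offered:
#' \describe{
#'   \item{`as_printed`}{\eqn{v = \sigma^2_{in}/(n_{in}\bar{X}_{in}) +
#'     \sigma^2_{out}/(n_{out}\bar{X}_{out})}, with the means entering to
#'     the first power. This form is not invariant to rescaling the
#'     measurement units (see the methods vignette for the trade-off)
#'     and is the package default.}
#'   \item{`delta`}{\eqn{v = \sigma^2_{in}/(n_{in}\bar{X}^2_{in}) +
#'     \sigma^2_{out}/(n_{out}\bar{X}^2_{out})}, the standard delta-method
#'     variance of a log ratio, invariant to rescaling; used by the
#'     statistical-calibration checks.}
#' }
#'
#' @param mean_inside,mean_outside Positive means.
#' @param sd_inside,sd_outside Replicate standard deviations.
#' @param n_inside,n_outside Replicate counts; both must be >= 2.
#' @param method `"as_printed"` (default) or `"delta"`.
#' @return The variance(s); 0 when both SDs are 0 (such effects receive a
#'   variance floor before weighting, see [pooled_effect()]).
#' @export
#' @examples
#' within_study_variance(2, 2, 1, 1, 4, 4)                    # 0.25
#' within_study_variance(2, 2, 1, 1, 4, 4, method = "delta")  # 0.125
within_study_variance <- function(mean_inside, mean_outside,
                                  sd_inside, sd_outside,
                                  n_inside, n_outside,
                                  method = c("as_printed", "delta")) {
  method <- match.arg(method)
  if (any(n_inside < 2) || any(n_outside < 2)) {
    abort("within-study variance requires at least 2 replicates per side",
          class = "mpameta_insufficient_replication")
  }
  if (any(mean_inside <= 0) || any(mean_outside <= 0)) {
    stop_bad_arg("means must be positive to compute a within-study variance")
  }
  pw <- if (method == "as_printed") 1 else 2
  sd_inside^2 / (n_inside * mean_inside^pw) +
    sd_outside^2 / (n_outside * mean_outside^pw)
}

#' Effect sizes for every ecosystem-MPA pair
#'
#' Chains [zero_adjust()], [log_response_ratio()] and
#' [within_study_variance()] over a table of paired summaries, carrying
#' protection level and region from the MPA table. One row is produced
#' per (MPA, ecosystem, year, status); pairs that cannot yield a defined,
#' finite effect size (all-zero stratum, or fewer than 2 replicates on a
#' side) are routed to the exclusion report (attribute `"exclusions"`,
#' see [pair_exclusions()]).
#'
#' @param pairs Output of [summarize_pairs()].
#' @param mpas MPA table carrying `mpa_id`, `region` and `protection`
#'   (optionally per `ecosystem`, for de facto no-take classifications
#'   that differ among ecosystems). Ignored for columns already present
#'   in `pairs`.
#' @param zero_adjust_mode Passed to [zero_adjust()].
#' @param variance_method Passed to [within_study_variance()].
#' @return A tibble of effect sizes: `mpa_id`, `ecosystem`, `year`,
#'   `status`, `Y`, `v`, `protection`, `region`, `zero_adjusted`,
#'   `variance_method`; attributes `"exclusions"` and `"constants"`.
#' @export
effect_sizes <- function(pairs, mpas = NULL,
                         zero_adjust_mode = c("zero_pairs", "all_pairs"),
                         variance_method = c("as_printed", "delta")) {
  zero_adjust_mode <- match.arg(zero_adjust_mode)
  variance_method <- match.arg(variance_method)
  check_columns(pairs, c("mpa_id", "ecosystem", "year", "status",
                         "mean_inside", "mean_outside", "sd_inside",
                         "sd_outside", "n_inside", "n_outside"),
                "`pairs`")
  out <- as_tibble_strict(pairs)
  if (!is.null(mpas)) {
    keep <- setdiff(intersect(c("mpa_id", "ecosystem", "region", "protection"),
                              names(mpas)),
                    setdiff(names(out), c("mpa_id", "ecosystem")))
    by <- intersect(c("mpa_id", "ecosystem"), keep)
    out <- left_join(out, mpas[keep], by = by)
  }
  for (col in c("protection", "region")) {
    if (!col %in% names(out)) out[[col]] <- NA_character_
  }

  out <- zero_adjust(out, mode = zero_adjust_mode)
  consts <- attr(out, "constants")

  undefined <- out$mean_inside_adj <= 0 | out$mean_outside_adj <= 0
  under_rep <- out$n_inside < 2 | out$n_outside < 2
  excl <- bind_rows(
    out[undefined, c("mpa_id", "ecosystem", "year", "status")] |>
      mutate(reason = "all_zero_stratum"),
    out[!undefined & under_rep,
        c("mpa_id", "ecosystem", "year", "status")] |>
      mutate(reason = "insufficient_replication")
  )

  keep <- !undefined & !under_rep
  res <- out[keep, ]
  res$Y <- log_response_ratio(res$mean_inside_adj, res$mean_outside_adj)
  res$v <- within_study_variance(res$mean_inside_adj, res$mean_outside_adj,
                                 res$sd_inside, res$sd_outside,
                                 res$n_inside, res$n_outside,
                                 method = variance_method)
  res <- res |>
    mutate(variance_method = .env$variance_method) |>
    select("mpa_id", "ecosystem", "year", "status", "Y", "v",
           "protection", "region", "zero_adjusted", "variance_method")
  attr(res, "exclusions") <- excl
  attr(res, "constants") <- consts
  res
}

#' Retain the most recent year per ecosystem-MPA combination
#'
#' When an MPA was surveyed in an ecosystem over several years, only the
#' most recent result is retained for pooling, reflecting the longest
#' duration of protection. Different ecosystems of the same MPA may
#' retain different years.
#'
#' @param effects An effect-size tibble with `mpa_id`, `ecosystem`,
#'   `status` and `year` columns.
#' @return The filtered tibble: exactly one row per
#'   (mpa_id, ecosystem, status).
#' @export
most_recent_filter <- function(effects) {
  check_columns(effects, c("mpa_id", "ecosystem", "status", "year"),
                "`effects`")
  effects |>
    dplyr::slice_max(.data$year, n = 1, with_ties = FALSE,
                     by = c("mpa_id", "ecosystem", "status")) |>
    arrange(.data$mpa_id, .data$ecosystem, .data$status)
}
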