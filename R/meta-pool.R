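#' Heterogeneity statistic Q
#'
#' The weighted sum of squared deviations of effect sizes around their
#' weighted mean, \eqn{Q = \sum_i w_i (Y_i - \bar{R}_w)^2}. In the
#' random-effects sequence Q is computed with fixed-effect weights
#' \eqn{w_i = 1/v_i} (see [pooled_effect()]).
#'
#' @param Y Effect sizes.
#' @param w Positive weights (same length as `Y`).
#' @return Q (nonnegative scalar; 0 when a single effect is supplied).
#' @export
#' @examples
#' heterogeneity_Q(c(0, 1), c(1, 1))  # 0.5
heterogeneity_Q <- function(Y, w) {
  if (length(Y) == 0) stop_bad_arg("`Y` must be non-empty")
  if (length(w) != length(Y) || any(w <= 0)) {
    stop_bad_arg("`w` must be positive and match `Y` in length")
  }
  R_w <- sum(w * Y) / sum(w)
  sum(w * (Y - R_w)^2)
}

#' Between-study variance tau-squared
#'
#' Method-of-moments estimate of the between-study variance, truncated at
#' zero. Two denominators are available:
#' \describe{
#'   \item{`as_printed`}{\eqn{\hat\tau^2 = (Q - (k-1))/(k-1)}, i.e. the
#'     scaling constant is \eqn{c = k - 1}. This is the package default;
#'     note it is on the scale of the Q statistic, not of the effect
#'     sizes, except when the fixed-effect weights are near 1.}
#'   \item{`dl`}{the DerSimonian-Laird constant
#'     \eqn{c = \sum w_i - \sum w_i^2 / \sum w_i} with fixed-effect
#'     weights \eqn{w_i = 1/v_i}; this is the estimator with correct
#'     sampling units, used by the statistical-calibration checks. It
#'     reduces to `as_printed` when all \eqn{v_i = 1}.}
#' }
#'
#' @param Q Heterogeneity statistic.
#' @param k Number of pooled effect sizes (>= 1).
#' @param method `"as_printed"` (default) or `"dl"`.
#' @param w Fixed-effect weights, required for `method = "dl"`.
#' @return tau-squared (>= 0; 0 when `k = 1`). The attribute
#'   `"truncated"` records whether the raw estimate was negative.
#' @export
#' @examples
#' tau_squared(5, 3)  # (5 - 2) / 2 = 1.5
tau_squared <- function(Q, k, method = c("as_printed", "dl"), w = NULL) {
  method <- match.arg(method)
  if (k < 1) stop_bad_arg("`k` must be >= 1")
  if (Q < 0) stop_bad_arg("`Q` must be nonnegative")
  if (k == 1) {
    return(structure(0, truncated = FALSE))
  }
  cc <- if (method == "as_printed") {
    k - 1
  } else {
    if (is.null(w)) stop_bad_arg("`method = \"dl\"` requires fixed-effect weights `w`")
    sum(w) - sum(w^2) / sum(w)
  }
  raw <- (Q - (k - 1)) / cc
  structure(max(0, raw), truncated = raw < 0)
}

# variance floor: zero within-study variances would give infinite weight
floor_variances <- function(v) {
  zero <- v <= 0
  if (!any(zero)) return(list(v = v, floored = zero))
  pos <- v[v > 0]
  fl <- if (length(pos)) min(pos) * 0.1 else 1e-8
  v[zero] <- fl
  list(v = v, floored = zero)
}

#' Pool effect sizes with inverse-variance random-effects weights
#'
#' Implements the random-effects pooling sequence:
#' \enumerate{
#'   \item fixed-effect weights \eqn{1/v_i} give the fixed-effect mean
#'     and the heterogeneity statistic Q;
#'   \item \eqn{\hat\tau^2} is estimated from Q ([tau_squared()]);
#'   \item random-effects weights \eqn{w_i = 1/(v_i + \hat\tau^2)};
#'   \item \eqn{\bar{R} = \sum w_i Y_i / \sum w_i};
#'   \item \eqn{se = \sqrt{1 / \sum w_i}}; the confidence interval is
#'     \eqn{\bar{R} \pm z_{\alpha/2}\,se} and the two-sided p-value comes
#'     from the normal reference distribution of \eqn{\bar{R}/se} (a
#'     t reference with k - 1 df is available via `reference = "t"`).
#' }
#' Effects with a zero within-study variance receive a floor of one tenth
#' of the smallest positive variance in the group before weighting.
#' A single effect is returned as-is (`R_bar = Y`, `se = sqrt(v)`) and
#' flagged `single_study`.
#'
#' @param Y Effect sizes.
#' @param v Within-study variances (nonnegative; zeros are floored).
#' @param tau2_method Passed to [tau_squared()].
#' @param reference `"normal"` (default) or `"t"` for the CI and p-value.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `mpa_pool`; see [tidy.mpa_pool()] and
#'   [glance.mpa_pool()].
#' @export
#' @examples
#' p <- pooled_effect(c(0, 2), c(1, 1))
#' glance(p)  # R_bar 1, Q 2, tau2 1, se 1
pooled_effect <- function(Y, v, tau2_method = c("as_printed", "dl"),
                          reference = c("normal", "t"), conf_level = 0.95) {
  tau2_method <- match.arg(tau2_method)
  reference <- match.arg(reference)
  if (length(Y) == 0) stop_bad_arg("`Y` must be non-empty")
  if (length(v) != length(Y) || any(v < 0)) {
    stop_bad_arg("`v` must be nonnegative and match `Y` in length")
  }
  k <- length(Y)
  fl <- floor_variances(v)
  v_use <- fl$v

  w_fe <- 1 / v_use
  Q <- heterogeneity_Q(Y, w_fe)
  tau2 <- tau_squared(Q, k, method = tau2_method, w = w_fe)
  w <- 1 / (v_use + as.numeric(tau2))
  R_bar <- sum(w * Y) / sum(w)
  se <- sqrt(1 / sum(w))

  z <- R_bar / se
  crit <- if (reference == "t" && k > 1) {
    qt(1 - (1 - conf_level) / 2, df = k - 1)
  } else {
    qnorm(1 - (1 - conf_level) / 2)
  }
  p <- if (reference == "t" && k > 1) {
    2 * pt(-abs(z), df = k - 1)
  } else {
    2 * pnorm(-abs(z))
  }

  structure(
    list(k = k, Y = Y, v = v, v_used = v_use,
         w_fixed = w_fe, weights = w,
         Q = if (k == 1) 0 else Q,
         tau2 = as.numeric(tau2),
         tau2_truncated = isTRUE(attr(tau2, "truncated")),
         tau2_method = tau2_method,
         R_bar = R_bar, se = se,
         ci_low = R_bar - crit * se, ci_high = R_bar + crit * se,
         p = p, conf_level = conf_level, reference = reference,
         single_study = k == 1,
         variance_floored = any(fl$floored)),
    class = "mpa_pool")
}

#' @export
print.mpa_pool <- function(x, ...) {
  cat(sprintf(
    "<mpa_pool> k = %d | R_bar = %.4f (se %.4f, %g%% CI %.4f to %.4f)\n",
    x$k, x$R_bar, x$se, 100 * x$conf_level, x$ci_low, x$ci_high))
  cat(sprintf("  Q = %.4f, tau2 = %.4f (%s), p = %.4g%s\n",
              x$Q, x$tau2, x$tau2_method, x$p,
              if (x$single_study) " [single study]" else ""))
  invisible(x)
}

#' Tidy a pooled effect: one row per pooled study
#'
#' @param x An `mpa_pool` object.
#' @param ... Unused.
#' @return A tibble with `Y`, `v`, the random-effects `weight` and the
#'   normalized weight.
#' @method tidy mpa_pool
#' @export
tidy.mpa_pool <- function(x, ...) {
  tibble(Y = x$Y, v = x$v, weight = x$weights,
         weight_norm = x$weights / sum(x$weights))
}

#' Glance at a pooled effect: one-row summary
#'
#' @param x An `mpa_pool` object.
#' @param ... Unused.
#' @return A one-row tibble with `k`, `R_bar`, `se`, `ci_low`, `ci_high`,
#'   `p`, `Q`, `tau2`, and flags.
#' @method glance mpa_pool
#' @export
glance.mpa_pool <- function(x, ...) {
  tibble(k = x$k, R_bar = x$R_bar, se = x$se,
         ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
         Q = x$Q, tau2 = x$tau2, tau2_truncated = x$tau2_truncated,
         single_study = x$single_study,
         variance_floored = x$variance_floored)
}

#' Pool effect sizes at a spatial scale
#'
#' Pools effect sizes at one of four scales, always stratified by target
#' status and protection level:
#' \describe{
#'   \item{`mpa`}{one pool per MPA across its sampled ecosystems;}
#'   \item{`ecosystem`}{one pool per ecosystem across MPAs (set
#'     `by_region = TRUE` for region-within-ecosystem pools);}
#'   \item{`region`}{one pool per region across its ecosystem-MPA
#'     effects;}
#'   \item{`network`}{a single pool of everything.}
#' }
#' Effects should normally pass [most_recent_filter()] first.
#'
#' @param effects Effect-size tibble (see [effect_sizes()]).
#' @param scale One of `"mpa"`, `"ecosystem"`, `"region"`, `"network"`.
#' @param by_region For `scale = "ecosystem"`, additionally split by
#'   region.
#' @param status,protection Optional filters (character vectors) applied
#'   before pooling.
#' @inheritParams pooled_effect
#' @return A tibble of class `mpa_pooled`: one row per group with the
#'   [glance.mpa_pool()] columns, the grouping key, and a `weights`
#'   list-column. Groups with no effects are simply absent.
#' @export
pool_at_scale <- function(effects,
                          scale = c("mpa", "ecosystem", "region", "network"),
                          by_region = FALSE,
                          status = NULL, protection = NULL,
                          tau2_method = c("as_printed", "dl"),
                          reference = c("normal", "t"),
                          conf_level = 0.95) {
  if (is.character(scale) && length(scale) == 1 && !scale %in% SCALES) {
    stop_bad_arg(sprintf("unknown scale '%s'; must be one of %s",
                         scale, paste(SCALES, collapse = ", ")))
  }
  scale <- match.arg(scale)
  check_columns(effects, c("mpa_id", "ecosystem", "status", "protection",
                           "Y", "v"), "`effects`")
  tau2_method <- match.arg(tau2_method)
  reference <- match.arg(reference)

  dat <- as_tibble_strict(effects)
  if (!"region" %in% names(dat)) dat$region <- NA_character_
  if (!is.null(status)) dat <- filter(dat, .data$status %in% .env$status)
  if (!is.null(protection)) {
    dat <- filter(dat, .data$protection %in% .env$protection)
  }
  if (nrow(dat) == 0) stop_bad_arg("no effects left to pool")

  group_cols <- switch(scale,
    mpa = "mpa_id",
    ecosystem = if (by_region) c("ecosystem", "region") else "ecosystem",
    region = "region",
    network = character(0))
  strat <- c(group_cols, "status", "protection")

  dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strat))) |>
    dplyr::group_modify(function(d, key) {
      pool <- pooled_effect(d$Y, d$v, tau2_method = tau2_method,
                            reference = reference, conf_level = conf_level)
      g <- glance(pool)
      g$weights <- list(pool$weights)
      g
    }) |>
    dplyr::ungroup() |>
    mutate(scale = .env$scale, .before = 1) |>
    structure(class = c("mpa_pooled", class(tibble())))
}
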