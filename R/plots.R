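#' Forest plot of pooled effect sizes
#'
#' Weighted mean effect sizes with their confidence intervals, one panel
#' per scale, coloured by protection level and shaped by target status.
#' The dashed vertical line marks the null of equal biomass inside and
#' outside MPAs.
#'
#' @param object An `mpa_pooled` tibble from [pool_at_scale()] (or
#'   several scales row-bound together).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpa_pooled
#' @export
autoplot.mpa_pooled <- function(object, ...) {
  group_cols <- intersect(c("mpa_id", "ecosystem", "region"), names(object))
  dat <- as_tibble_strict(object)
  dat$group <- if (length(group_cols)) {
    lab <- do.call(paste, c(dat[group_cols], sep = " / "))
    ifelse(is.na(lab) | lab == "NA", "network", lab)
  } else {
    "network"
  }
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$R_bar,
                               y = stats::reorder(.data$group, .data$R_bar),
                               colour = .data$protection,
                               shape = .data$status)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2,
                            position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k),
                        position = ggplot2::position_dodge(0.5)) +
    ggplot2::scale_size_continuous(range = c(1.5, 4)) +
    ggplot2::facet_wrap(~scale, scales = "free_y") +
    ggplot2::labs(x = "log response ratio (biomass)", y = NULL,
                  size = "k", colour = "protection", shape = "status") +
    ggplot2::theme_minimal()
}

#' Partial-effect curves of a fitted feature model
#'
#' One panel per smooth term: the centred partial effect with its 95%
#' band, on the scale of the log response ratio.
#'
#' @param object An `mpa_gam` from [fit_weighted_gam()], or an
#'   `mpa_gam_forward` from [forward_select_gcv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpa_gam
#' @export
autoplot.mpa_gam <- function(object, ...) {
  partials <- object$partials
  if (is.null(partials) || nrow(partials) == 0) {
    stop_bad_arg("no smooth terms to plot")
  }
  ggplot2::ggplot(partials, ggplot2::aes(x = .data$x, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "feature value",
                  y = "partial effect on log response ratio") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mpa_gam
#' @method autoplot mpa_gam_forward
#' @export
autoplot.mpa_gam_forward <- function(object, ...) {
  autoplot.mpa_gam(object$fit, ...)
}
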