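#' Pipeline configuration
#'
#' Collects every analysis choice of the pipeline — simulation settings,
#' target-status threshold, zero-adjustment mode, variance and
#' tau-squared methods, t-test mode, GAM settings and significance level
#' — into one validated object, so a run is fully described by its
#' configuration and seed.
#'
#' @param sim An [sim_config()] describing the synthetic dataset (the
#'   pipeline currently runs on simulated data; pass pre-built tables to
#'   the stage functions directly for real data).
#' @param bycatch_threshold Catch volume at or below which a caught
#'   species is treated as nontargeted ([classify_target_status()]).
#' @param overrides Status overrides for cryptic species.
#' @param zero_adjust_mode,variance_method,tau2_method,reference Passed
#'   to the respective stages.
#' @param ttest_most_recent Use only each MPA's most recent year in the
#'   diversity t-tests.
#' @param gam_basis_dim,gam_tol Feature-model settings.
#' @param alpha Significance level used when counting significant pools.
#' @param outdir Output directory for CSV tables and the manifest, or
#'   `NULL` to skip writing.
#' @return A list of class `mpa_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            bycatch_threshold = 10,
                            overrides = NULL,
                            zero_adjust_mode = "zero_pairs",
                            variance_method = "as_printed",
                            tau2_method = "as_printed",
                            reference = "normal",
                            ttest_most_recent = TRUE,
                            gam_basis_dim = 5,
                            gam_tol = 0.02,
                            alpha = 0.05,
                            outdir = NULL) {
  if (alpha <= 0 || alpha >= 1) stop_bad_arg("`alpha` must lie in (0, 1)")
  validate_sim_config(sim)
  structure(list(sim = sim, bycatch_threshold = bycatch_threshold,
                 overrides = overrides,
                 zero_adjust_mode = zero_adjust_mode,
                 variance_method = variance_method,
                 tau2_method = tau2_method, reference = reference,
                 ttest_most_recent = ttest_most_recent,
                 gam_basis_dim = gam_basis_dim, gam_tol = gam_tol,
                 alpha = alpha, outdir = outdir),
            class = "mpa_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-data generation, target-status
#' classification, replicate biomass assembly, paired summaries, effect
#' sizes, most-recent-year filtering, pooling at all four scales,
#' diversity metrics and per-ecosystem t-tests, and the feature model
#' with forward GCV selection. When `config$outdir` is set, nine CSV
#' tables and a JSON manifest (configuration hash, seed, per-stage row
#' counts, package version) are written; identical configuration and
#' seed yield identical outputs.
#'
#' @param config An [pipeline_config()].
#' @return A list of class `mpa_pipeline_result` with all intermediate
#'   and final objects plus the `manifest`.
#' @export
run_mpa_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "mpa_pipeline_config")) {
    stop_bad_arg("`config` must be created with pipeline_config()")
  }

  sim <- simulate_mpa_dataset(config$sim)
  status <- classify_target_status(
    sim$species[c("species_id", "annual_catch")],
    bycatch_threshold = config$bycatch_threshold,
    overrides = config$overrides)

  repl <- aggregate_replicate_biomass(sim$surveys, sim$species, status)
  pairs <- summarize_pairs(repl)
  eff_annual <- effect_sizes(pairs, sim$network,
                             zero_adjust_mode = config$zero_adjust_mode,
                             variance_method = config$variance_method)
  eff <- most_recent_filter(eff_annual)

  pooled <- bind_rows(lapply(SCALES, function(sc) {
    pool_at_scale(eff, scale = sc, tau2_method = config$tau2_method,
                  reference = config$reference)
  }))

  div <- mpa_level_metrics(sim$surveys)
  div_resp <- diversity_response(div, sim$network,
                                 zero_adjust_mode = config$zero_adjust_mode)
  div_tests <- ecosystem_ttest(div_resp,
                               most_recent_only = config$ttest_most_recent)

  frame <- build_model_frame(eff_annual, sim$network,
                             tau2_method = config$tau2_method)
  gam_sel <- forward_select_gcv(frame, basis_dim = config$gam_basis_dim,
                                tol = config$gam_tol)

  result <- list(
    sim = sim, status = status, replicate_biomass = repl, pairs = pairs,
    effects_annual = eff_annual, effects = eff, pooled = pooled,
    diversity = div, diversity_responses = div_resp,
    diversity_tests = div_tests, model_frame = frame,
    gam_selection = gam_sel, config = config)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mpameta")),
    seed = config$sim$seed,
    config_hash = rlang::hash(unclass_recursive(
      config[setdiff(names(config), "outdir")])),
    n_rows = list(
      surveys = nrow(sim$surveys), replicate_biomass = nrow(repl),
      pairs = nrow(pairs), effects_annual = nrow(eff_annual),
      effects = nrow(eff), pooled = nrow(pooled),
      diversity = nrow(div), diversity_tests = nrow(div_tests),
      model_frame = nrow(frame)),
    n_excluded = list(
      pairs = nrow(pair_exclusions(pairs)),
      effects = nrow(pair_exclusions(eff_annual)),
      diversity = nrow(pair_exclusions(div_resp))),
    selected_features = gam_sel$included,
    files = character(0))

  if (!is.null(config$outdir)) {
    manifest$files <- write_pipeline_outputs(result, config$outdir)
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result$manifest <- manifest
  structure(result, class = "mpa_pipeline_result")
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_sim_tables(result$sim, outdir)

  flat_csv <- function(df, name) {
    df <- as.data.frame(df)
    for (col in names(df)) {
      if (is.list(df[[col]])) {
        df[[col]] <- vapply(df[[col]],
                            function(v) paste(format(v, digits = 10),
                                              collapse = ";"),
                            character(1))
      }
    }
    write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  flat_csv(result$effects_annual, "effects.csv")
  flat_csv(result$pooled, "pooled.csv")
  flat_csv(result$diversity, "diversity.csv")
  flat_csv(result$diversity_tests, "diversity_tests.csv")
  flat_csv(tidy(result$gam_selection$fit) |>
             mutate(gcv = result$gam_selection$fit$gcv,
                    r2_adj = result$gam_selection$fit$r2_adj),
           "gam_summary.csv")
  flat_csv(result$gam_selection$trace, "selection_trace.csv")

  c("species.csv", "mpas.csv", "surveys.csv", "effects.csv", "pooled.csv",
    "diversity.csv", "diversity_tests.csv", "gam_summary.csv",
    "selection_trace.csv")
}

#' @export
print.mpa_pipeline_result <- function(x, ...) {
  cat("<mpa_pipeline_result>\n")
  cat(sprintf("  %d MPAs, %d effect sizes (%d annual), %d pooled groups\n",
              x$config$sim$n_mpas, nrow(x$effects), nrow(x$effects_annual),
              nrow(x$pooled)))
  net <- x$pooled |>
    filter(.data$scale == "network", .data$status == "targeted",
           .data$protection == "no_take")
  if (nrow(net)) {
    cat(sprintf("  network no-take targeted effect: %.3f (p = %.3g)\n",
                net$R_bar[1], net$p[1]))
  }
  cat("  selected features:",
      if (length(x$gam_selection$included))
        paste(x$gam_selection$included, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}
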