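# internal helpers shared across modules

ECOSYSTEMS <- c("surf_zone", "kelp_forest", "shallow_reef", "deep_reef")
REGIONS <- c("north", "north_central", "central", "south")
STATUSES <- c("targeted", "nontargeted")
PROTECTIONS <- c("no_take", "partial_take")
SCALES <- c("mpa", "ecosystem", "region", "network")

stop_bad_arg <- function(msg, class = "mpameta_invalid_argument") {
  abort(msg, class = class)
}

stop_missing_data <- function(msg, offenders = NULL) {
  abort(msg, class = "mpameta_missing_data", offenders = offenders)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_bad_arg(sprintf(
      "%s is missing required column(s): %s", what, paste(miss, collapse = ", ")
    ))
  }
  invisible(df)
}

# sample() without the length-1 surprise
sample_int <- function(n, size, replace = FALSE) {
  sample.int(n, size = size, replace = replace)
}

as_tibble_strict <- function(x) tibble::as_tibble(x)
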