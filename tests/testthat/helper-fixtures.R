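# small builders shared across test files

toy_species <- function() {
  tibble::tibble(
    species_id = c("sp_a", "sp_b"),
    lw_a = c(1, 0.01), lw_b = c(3, 3),
    targeted_truth = c(TRUE, FALSE),
    annual_catch = c(500, 0),
    mean_length_cm = c(10, 10), length_cv = 0.2
  )
}

toy_status <- function() {
  tibble::tibble(species_id = c("sp_a", "sp_b"),
                 status = c("targeted", "nontargeted"))
}

# one observation row
obs_row <- function(mpa = "m1", eco = "kelp_forest", year = 2020,
                    side = "inside", rep = "r1", sp = "sp_a",
                    count = 1, lengths = list(2)) {
  tibble::tibble(mpa_id = mpa, ecosystem = eco, year = year, side = side,
                 replicate_id = rep, species_id = sp, count = count,
                 lengths = lengths)
}

# paired summary row with sensible defaults
pair_row <- function(mpa = "m1", eco = "kelp_forest", year = 2020,
                     status = "targeted", protection = "no_take",
                     m_in = 2, m_out = 1, s_in = 1, s_out = 1,
                     n_in = 4, n_out = 4) {
  tibble::tibble(mpa_id = mpa, ecosystem = eco, year = year, status = status,
                 protection = protection,
                 mean_inside = m_in, mean_outside = m_out,
                 sd_inside = s_in, sd_outside = s_out,
                 n_inside = n_in, n_outside = n_out)
}

# independent brute-force transcription of the pooling equations:
# weighted mean (Eq. 3), weights 1/(v+tau2) (Eq. 4), tau2 = (Q-(k-1))/(k-1)
# (Eq. 5), Q with fixed-effect weights (Eq. 6). Written directly from the
# formulas, sharing no code with the package implementation.
oracle_pool <- function(Y, v) {
  k <- length(Y)
  w_fe <- 1 / v
  Rfe <- sum(w_fe * Y) / sum(w_fe)
  Q <- sum(w_fe * (Y - Rfe)^2)
  tau2 <- if (k >= 2) max(0, (Q - (k - 1)) / (k - 1)) else 0
  w <- 1 / (v + tau2)
  R <- sum(w * Y) / sum(w)
  se <- sqrt(1 / sum(w))
  list(R_bar = R, Q = if (k == 1) 0 else Q, tau2 = tau2, se = se)
}
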