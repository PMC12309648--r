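test_that("Q and tau-squared match hand-worked values", {
  expect_equal(heterogeneity_Q(c(0.5, 0.5), c(10, 10)), 0)
  expect_equal(heterogeneity_Q(c(0, 1), c(1, 1)), 0.5)
  expect_equal(heterogeneity_Q(0.3, 2), 0)  # single study
  expect_error(heterogeneity_Q(numeric(0), numeric(0)),
               class = "mpameta_invalid_argument")

  expect_equal(as.numeric(tau_squared(5, 3)), 1.5)  # (5-2)/2
  t0 <- tau_squared(0, 3)
  expect_equal(as.numeric(t0), 0)
  expect_true(attr(t0, "truncated"))
  expect_equal(as.numeric(tau_squared(7, 1)), 0)
  expect_error(tau_squared(1, 0), class = "mpameta_invalid_argument")

  # DL constant reduces to k-1 when all v = 1
  w1 <- c(1, 1, 1)
  expect_equal(as.numeric(tau_squared(5, 3, method = "dl", w = w1)),
               as.numeric(tau_squared(5, 3)))
})

test_that("pooled effect follows the documented random-effects sequence", {
  p1 <- pooled_effect(c(0.5, 0.5), c(0.1, 0.1))
  expect_equal(p1$R_bar, 0.5)
  expect_equal(p1$Q, 0)
  expect_equal(p1$tau2, 0)
  expect_equal(p1$se, sqrt(0.05))

  p2 <- pooled_effect(c(0, 2), c(1, 1))
  expect_equal(p2$Q, 2)
  expect_equal(p2$tau2, 1)        # (2-1)/1
  expect_equal(p2$weights, c(0.5, 0.5))
  expect_equal(p2$R_bar, 1)
  expect_equal(p2$se, 1)

  # equal v and tau2 = 0: weighted mean equals the arithmetic mean
  y <- c(0.2, 0.3, 0.25)
  p3 <- pooled_effect(y, rep(0.5, 3))
  expect_equal(p3$R_bar, mean(y), tolerance = 1e-12)

  # single study passthrough
  p4 <- pooled_effect(0.7, 0.04)
  expect_true(p4$single_study)
  expect_equal(p4$R_bar, 0.7)
  expect_equal(p4$se, 0.2)

  # zero variances receive the group floor rather than infinite weight
  p5 <- pooled_effect(c(0, 1), c(0, 0.1))
  expect_true(p5$variance_floored)
  expect_equal(p5$v_used[1], 0.01)

  g <- glance(p2)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$R_bar, 1)
  td <- tidy(p2)
  expect_equal(sum(td$weight_norm), 1)
})

test_that("pooling matches the brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(1:6, 1)
    Y <- runif(k, -3, 3)
    v <- runif(k, 0.01, 1)
    o <- oracle_pool(Y, v)
    p <- pooled_effect(Y, v)
    expect_equal(p$R_bar, o$R_bar, tolerance = 1e-12)
    expect_equal(p$Q, o$Q, tolerance = 1e-12)
    expect_equal(p$tau2, o$tau2, tolerance = 1e-12)
    expect_equal(p$se, o$se, tolerance = 1e-12)
  }
})

test_that("pooling agrees with metafor's DerSimonian-Laird fit when v = 1", {
  # with unit within-study variances the as-printed constant c = k-1 equals
  # the DL constant, so an independent implementation must agree
  set.seed(7)
  Y <- rnorm(8, 0.4, 0.8)
  v <- rep(1, 8)
  p <- pooled_effect(Y, v)
  m <- metafor::rma(yi = Y, vi = v, method = "DL")
  expect_equal(p$R_bar, as.numeric(m$beta), tolerance = 1e-10)
  expect_equal(p$tau2, m$tau2, tolerance = 1e-10)
  expect_equal(p$se, m$se, tolerance = 1e-10)
  expect_equal(p$Q, m$QE, tolerance = 1e-10)
})

test_that("standard error shrinks as studies accumulate", {
  set.seed(11)
  ks <- c(3, 10, 30, 100)
  ses <- vapply(ks, function(k) {
    mean(replicate(30, pooled_effect(rnorm(k, 0.3, 0.2),
                                     runif(k, 0.05, 0.15))$se))
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("pool_at_scale groups and stratifies correctly", {
  eff <- tibble::tibble(
    mpa_id = c("m1", "m1", "m2", "m2"),
    ecosystem = c("kelp_forest", "surf_zone", "kelp_forest", "surf_zone"),
    year = 2020, status = "targeted", protection = "no_take",
    region = c("north", "north", "south", "south"),
    Y = c(0.2, 0.4, 0.6, 0.8), v = c(0.1, 0.2, 0.1, 0.2))

  # region scale: two groups of k = 2, each matching a hand-pooled oracle
  by_region <- pool_at_scale(eff, "region")
  expect_equal(nrow(by_region), 2)
  for (r in c("north", "south")) {
    sub <- eff[eff$region == r, ]
    o <- oracle_pool(sub$Y, sub$v)
    row <- by_region[by_region$region == r, ]
    expect_equal(row$R_bar, o$R_bar, tolerance = 1e-12)
    expect_equal(row$Q, o$Q, tolerance = 1e-12)
  }

  # one MPA with one ecosystem pools to its own effect size
  single <- pool_at_scale(eff[1, ], "mpa")
  expect_equal(single$R_bar, 0.2)
  expect_equal(single$se, sqrt(0.1))
  expect_true(single$single_study)

  # network scale collapses everything within the status/protection stratum
  net <- pool_at_scale(eff, "network")
  expect_equal(nrow(net), 1)
  expect_equal(net$k, 4L)

  expect_error(pool_at_scale(eff, "continent"),
               class = "mpameta_invalid_argument")
})

test_that("normalized pooling weights sum to one and CI brackets R_bar", {
  set.seed(3)
  eff <- tibble::tibble(
    mpa_id = sprintf("m%d", 1:12),
    ecosystem = sample(c("kelp_forest", "deep_reef"), 12, TRUE),
    year = 2020, status = "targeted", protection = "no_take",
    region = sample(c("north", "south"), 12, TRUE),
    Y = rnorm(12, 0.5, 0.5), v = runif(12, 0.02, 0.3))
  pooled <- pool_at_scale(eff, "network")
  w <- pooled$weights[[1]]
  expect_equal(sum(w / sum(w)), 1)
  expect_true(pooled$ci_low <= pooled$R_bar && pooled$R_bar <= pooled$ci_high)
  expect_gte(pooled$Q, 0)
  expect_gte(pooled$tau2, 0)
})
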