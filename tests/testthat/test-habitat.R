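test_that("Pearson chi-square matches the hand formula", {
  cls <- rep(c("a", "b"), each = 40)
  veg <- c(rep("MMW", 30), rep("MWP", 10), rep("MMW", 10), rep("MWP", 30))
  r <- habitat_association_test(cls, veg)
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)
  # identical row distributions give statistic 0, p = 1
  veg2 <- rep(c("MMW", "MWP"), 40)
  r2 <- habitat_association_test(cls, veg2)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
  expect_error(habitat_association_test(rep("a", 10), veg[1:10]),
               "2 levels")
})

test_that("chi-square association has near-nominal null rejection", {
  set.seed(60)
  rej <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    cls <- sample(c("E", "H", "K"), 120, replace = TRUE)
    veg <- sample(c("MMW", "MWP"), 120, replace = TRUE)
    r <- suppressWarnings(habitat_association_test(cls, veg))
    if (r$p < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.025)
})

test_that("habitat-and-cline nests cline-only and recovers injected offsets", {
  # no habitat effect: delta small, G small
  d <- simulate_zone(sim_config(n = 400, mix_amplitude = 0,
                                mt_asymmetry = 0, seed = 71))
  pr <- project_positions(d, 207)
  f <- fit_habitat_cline(pr, "vegetation")
  expect_gte(f$habitat["loglik"], f$cline_only["loglik"] - 1e-6)
  expect_equal(f$df, 1)
  # injected effect: shift the cline by +0.3 km for MWP individuals
  deltas <- numeric(6)
  for (s in seq_along(deltas)) {
    set.seed(100 + s)
    n <- 500
    x <- runif(n, -1.75, 1.75)
    veg <- ifelse(runif(n) < plogis(x / 0.3), "MWP", "MMW")
    ctr <- ifelse(veg == "MWP", 0.3, 0)
    k <- rbinom(n, 2, tanh_p(x, ctr, 0.75))
    dd <- make_dataset(cbind(A = k), vegetation = veg)
    prr <- structure(list(base = dd, heading = 0, origin = c(0, 0),
                          position = x),
                     class = "projected_dataset")
    ff <- fit_habitat_cline(prr, "vegetation")
    deltas[s] <- ff$habitat["delta"]
  }
  expect_lt(abs(mean(deltas) - 0.3), 0.09)  # within +/- 30%
})

test_that("habitat LRT detects a real effect with high power", {
  set.seed(72)
  n <- 300
  x <- runif(n, -1.75, 1.75)
  veg <- ifelse(runif(n) < plogis(x / 0.3), "MWP", "MMW")
  ctr <- ifelse(veg == "MWP", 0.3, 0)
  k <- rbinom(n, 2, tanh_p(x, ctr, 0.75))
  dd <- make_dataset(cbind(A = k), vegetation = veg)
  prr <- structure(list(base = dd, heading = 0, origin = c(0, 0),
                        position = x),
                   class = "projected_dataset")
  ff <- fit_habitat_cline(prr, "vegetation")
  expect_lt(ff$p, 0.05)
})

test_that("constant covariates and poor coverage are refused", {
  d <- simulate_zone(sim_config(n = 100, seed = 73))
  d$individuals$vegetation <- "MMW"
  pr <- project_positions(d, 207)
  expect_error(fit_habitat_cline(pr, "vegetation"), "constant")
  d$individuals$vegetation <- NA_character_
  d$individuals$vegetation[1:5] <- "MWP"
  pr2 <- project_positions(d, 207)
  expect_error(fit_habitat_cline(pr2, "vegetation"), "covariate")
})

test_that("elevation summaries and omnibus F behave", {
  d <- make_dataset(cbind(A = rep(0, 5)),
                    elevation = c(1200, 1300, 1400, 1500, 1650),
                    phenotype = c("eschscholtzii", "eschscholtzii",
                                  "hybrid", "klauberi", "klauberi"))
  es <- elevation_summary(d)
  expect_equal(es$summary$mean[es$summary$class == "eschscholtzii"], 1250)
  expect_equal(es$summary$min[es$summary$class == "hybrid"], 1400)
  expect_equal(es$summary$max[es$summary$class == "hybrid"], 1400)
  # two classes with equal means and variances at large n: F near 1
  set.seed(61)
  fs <- replicate(60, {
    dd <- make_dataset(cbind(A = rep(0, 400)),
                       elevation = rnorm(400, 1400, 60),
                       phenotype = rep(c("x", "y"), 200))
    elevation_summary(dd)$F
  })
  expect_equal(mean(fs), 1, tolerance = 0.35)
})
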