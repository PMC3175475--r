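test_that("planar projection matches closed forms", {
  # two points: origin-ish anchor and 1 km due north
  lat0 <- 33.0
  dlat <- 1 / 6371.0088 * 180 / pi   # 1 km of latitude
  d <- make_dataset(cbind(A = c(0, 2)), lat = c(lat0, lat0 + dlat),
                    lon = c(-116.5, -116.5))
  pr0 <- project_positions(d, 0, origin = c(lat0, -116.5))
  expect_equal(pr0$position[1], 0, tolerance = 1e-9)
  expect_equal(pr0$position[2], 1, tolerance = 1e-6)
  pr207 <- project_positions(d, 207, origin = c(lat0, -116.5))
  expect_equal(pr207$position[2], cos(207 * pi / 180), tolerance = 1e-6)
  # heading reversal flips the sign of every position
  pr27 <- project_positions(d, 27)
  pr207c <- project_positions(d, 207)
  expect_equal(pr27$position, -pr207c$position, tolerance = 1e-12)
})

test_that("projection reports individuals with missing coordinates", {
  d <- make_dataset(cbind(A = c(0, 1)), lat = c(33, NA), lon = c(-116, -116))
  expect_error(project_positions(d, 0), "i002")
})

test_that("monotone data is a PAVA fixed point; violators pool to means", {
  f <- pava_fit(c(0, 1, 2), k = c(0, 1, 2), n = c(2, 2, 2))
  expect_equal(f$fitted, c(0, 0.5, 1))
  # one increasing violator with equal weights pools to the mean
  f2 <- pava_fit(c(0, 1), k = c(8, 2), n = c(10, 10),
                 direction = "increasing")
  expect_equal(f2$fitted, c(0.5, 0.5))
  # pooled-block value is the weighted mean of member observations
  f3 <- pava_fit(c(0, 1), k = c(9, 1), n = c(10, 30))
  expect_equal(f3$fitted, rep(10 / 40, 2))
  # ties in position are pooled before fitting
  f4 <- pava_fit(c(0, 0, 1), k = c(0, 2, 1), n = c(2, 2, 2))
  expect_equal(f4$position, c(0, 1))
  expect_equal(f4$n, c(4, 2))
})

test_that("PAVA attains the exhaustive grid-search maximum (<= 6 obs)", {
  set.seed(20)
  for (rep in 1:25) {
    m <- sample(2:6, 1)
    n <- sample(1:2, m, replace = TRUE)
    k <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
    f <- pava_fit(seq_len(m), k, n)
    orc <- pava_oracle_ll(k, n)
    expect_lt(abs(f$loglik - orc), 1e-3)
    expect_gte(f$loglik, orc - 1e-12)  # exact ML dominates the grid
  }
})

test_that("PAVA log-likelihood dominates random monotone candidates", {
  set.seed(21)
  for (rep in 1:20) {
    m <- 12
    n <- rep(2, m)
    k <- rbinom(m, 2, seq(0.1, 0.9, length.out = m))
    f <- pava_fit(seq_len(m), k, n)
    for (j in 1:20) {
      cand <- sort(runif(m))
      ll <- sum(ifelse(k > 0, k * log(cand), 0) +
                  ifelse(n - k > 0, (n - k) * log(1 - cand), 0))
      expect_gte(f$loglik, ll - 1e-10)
    }
  }
})

test_that("orientation recovers the simulated heading", {
  d <- simulate_zone(sim_config(n = 335, seed = 2))
  o <- fit_orientation(d, grid = 2)
  lo <- o$support["lower"]
  hi <- o$support["upper"]
  in_support <- (207 >= lo && 207 <= hi) ||
    (207 >= lo + 180 && 207 <= hi + 180) ||
    (207 >= lo - 180 && 207 <= hi - 180)
  expect_true(in_support)
  expect_lt(min(abs(c(o$heading - 207, o$heading - 27))) %% 360, 15)
})

test_that("rotating the coordinates rotates the ML heading", {
  d <- simulate_zone(sim_config(n = 150, seed = 4))
  o1 <- fit_orientation(d, grid = 3, refine = FALSE)
  # rotate all planar coordinates by +30 degrees about the centroid
  pr <- project_positions(d, 0)
  ang <- 30 * pi / 180   # +30 compass = clockwise in the (east, north) plane
  e <- pr$planar[, "east"] * cos(ang) + pr$planar[, "north"] * sin(ang)
  n2 <- -pr$planar[, "east"] * sin(ang) + pr$planar[, "north"] * cos(ang)
  ll <- clinezone:::latlon_from_planar(
    e, n2, mean(d$individuals$lat), mean(d$individuals$lon))
  d2 <- d
  d2$individuals$lat <- ll[, "lat"]
  d2$individuals$lon <- ll[, "lon"]
  o2 <- fit_orientation(d2, grid = 3, refine = FALSE)
  expect_equal((o2$heading - o1$heading) %% 180, 30, tolerance = 1e-6)
})

test_that("orientation demands at least three distinct locations", {
  d <- make_dataset(cbind(A = c(0, 1, 2)), lat = c(33, 33, 33.01),
                    lon = c(-116, -116, -116))
  expect_error(fit_orientation(d), "distinct")
})
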