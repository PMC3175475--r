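test_that("heterozygote deficit plug-in arithmetic", {
  expect_equal(het_deficit_ml(c(25, 50, 25))$D, 0)
  expect_equal(het_deficit_ml(c(50, 0, 50))$D, 0.25)
  expect_equal(het_deficit_ml(c(30, 40, 30))$D, 0.05)
  expect_equal(het_deficit_ml(c(0, 100, 0))$D, -0.25)
  expect_equal(het_deficit_ml(c(30, 40, 30))$p, 0.5)
  expect_error(het_deficit_ml(c(0, 0, 0)), "no individuals")
})

test_that("pairwise D: full coupling and exact independence", {
  full <- matrix(0, 3, 3)
  full[3, 3] <- 50   # 50 KK/KK
  full[1, 1] <- 50   # 50 EE/EE
  est <- pairwise_D_ml(full)
  expect_equal(est$D, 0.25, tolerance = 1e-6)
  expect_equal(est$p_A, 0.5)
  # table at exact HWE/LE expectations, p = 0.5 both loci
  g <- c(0.25, 0.5, 0.25)
  le <- outer(g, g) * 400
  est0 <- pairwise_D_ml(le)
  expect_lt(abs(est0$D), 1e-6)
})

test_that("EM matches the grid-search oracle on random small tables", {
  set.seed(40)
  n_checked <- 0
  for (rep in 1:40) {
    N <- sample(8:30, 1)
    tab <- matrix(0, 3, 3)
    cells <- sample(1:9, N, replace = TRUE,
                    prob = c(4, 2, 1, 2, 4, 2, 1, 2, 4))
    for (cc in cells) tab[cc] <- tab[cc] + 1
    est <- pairwise_D_ml(tab)
    if (is.na(est$D) || est$degenerate) next
    orc <- pair_D_oracle(tab)
    expect_lt(abs(est$D - orc$D), 2e-3)
    expect_gte(est$loglik, orc$loglik - 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 20)
})

test_that("ML margins equal observed allele frequencies (3-D oracle)", {
  tabs <- list(matrix(c(6, 2, 1, 3, 5, 2, 0, 3, 8), 3, 3),
               matrix(c(2, 4, 1, 3, 6, 3, 2, 2, 5), 3, 3))
  for (tab in tabs) {
    est <- pairwise_D_ml(tab)
    expect_gte(est$loglik, pair_oracle_check3d(tab) - 1e-6)
  }
})

test_that("EM log-likelihood trace is non-decreasing", {
  set.seed(41)
  for (rep in 1:10) {
    tab <- matrix(rpois(9, 4), 3, 3)
    est <- pairwise_D_ml(tab)
    if (!length(est$trace)) next
    expect_true(all(diff(est$trace) >= -1e-8))
  }
})

test_that("cytonuclear D closed form and oracle agreement", {
  full <- rbind(E = c(50, 0, 0), K = c(0, 0, 50))
  expect_equal(cytonuclear_D_ml(full)$D, 0.25)
  indep <- rbind(E = c(25, 50, 25), K = c(25, 50, 25))
  expect_equal(cytonuclear_D_ml(indep)$D, 0)
  set.seed(42)
  for (rep in 1:20) {
    tab <- matrix(rpois(6, 4) + 1, 2, 3)
    est <- cytonuclear_D_ml(tab)
    orc <- cyto_D_oracle(tab)
    expect_lt(abs(est$D - orc$D), 2e-3)
  }
})

test_that("window centres follow the stated sliding scheme", {
  d <- make_dataset(cbind(A = rep(0:2, 4)), lat = rep(33, 12),
                    lon = rep(-116, 12))
  pr <- structure(list(base = d, heading = 0, origin = c(0, 0),
                       position = seq(0, 0.5, length.out = 12)),
                  class = "projected_dataset")
  sc <- ld_scan(pr, window = 0.2, step = 0.1, min_n = 1)
  expect_equal(sc$center, c(0.1, 0.2, 0.3, 0.4), tolerance = 1e-9)
})

test_that("all components vanish without mixing (HWE/LE null)", {
  d <- simulate_zone(sim_config(n = 1000, mix_amplitude = 0,
                                mt_asymmetry = 0, seed = 3))
  pr <- project_positions(d, 207)
  sc <- ld_scan(pr, min_n = 25)
  expect_lt(abs(mean(sc$D_within, na.rm = TRUE)), 0.02)
  expect_lt(abs(mean(sc$D_between, na.rm = TRUE)), 0.02)
  expect_lt(abs(mean(sc$D_cyto, na.rm = TRUE)), 0.02)
})

test_that("the D peak falls on the flank where mixing concentrates", {
  hits <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    d <- simulate_zone(sim_config(n = 400, mix_center = -0.3, seed = s))
    pr <- project_positions(d, 207)
    sc <- ld_scan(pr, min_n = 10)
    ok <- !is.na(sc$D_between)
    if (!any(ok)) next
    peak <- sc$center[ok][which.max(sc$D_between[ok])]
    centre_shift <- -mean(d$individuals$true_x)
    if (peak < centre_shift) hits <- hits + 1
  }
  expect_gt(hits, n_seeds * 0.7)
})

test_that("degenerate pairwise tables return a flagged zero", {
  # single double-heterozygote: +D and -D fit equally well
  tab <- matrix(0, 3, 3)
  tab[2, 2] <- 5
  est <- pairwise_D_ml(tab)
  expect_true(est$degenerate)
  expect_equal(est$D, 0)
  # monomorphic margin gives no estimate
  mono <- matrix(0, 3, 3)
  mono[1, 2] <- 10
  expect_true(is.na(pairwise_D_ml(mono)$D))
})
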