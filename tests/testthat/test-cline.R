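test_that("tanh cline closed forms hold", {
  expect_equal(tanh_p(0.3, 0.3, 0.7), 0.5)
  expect_equal(tanh_p(0.3 + 0.35, 0.3, 0.7), (1 + tanh(1)) / 2)
  expect_equal((1 + tanh(1)) / 2, 0.88080, tolerance = 1e-5)
  d <- runif(5, 0, 2)
  expect_equal(tanh_p(0.1 - d, 0.1, 0.8) + tanh_p(0.1 + d, 0.1, 0.8),
               rep(1, 5))
  # slope at the centre equals 1/w (width = inverse of maximum slope)
  for (w in c(0.3, 0.718, 2)) {
    h <- 1e-6
    slope <- (tanh_p(h, 0, w) - tanh_p(-h, 0, w)) / (2 * h)
    expect_equal(slope, 1 / w, tolerance = 1e-6)
  }
  expect_error(tanh_p(0, 0, -1), "width")
})

test_that("cline log-likelihood follows the binomial convention", {
  ob1 <- data.frame(position = 0, k = 1, n = 2)
  expect_equal(cline_loglik(0, 0.75, ob1), 2 * log(0.5))
  ob2 <- data.frame(position = 0, k = 1, n = 1)
  expect_equal(cline_loglik(0, 0.75, ob2), log(0.5))
  # perfect-fit data far out on each flank has log-likelihood near 0
  ob3 <- data.frame(position = c(-100, 100), k = c(0, 2), n = c(2, 2))
  expect_gt(cline_loglik(0, 0.5, ob3), -1e-6)
  expect_lte(cline_loglik(0, 0.5, ob3), 0)
  expect_error(cline_loglik(0, 0.5, ob3[0, ]), "observations")
})

test_that("duplicating every observation keeps the MLE, narrows support", {
  obs <- obs_from_cline(150, center = 0.1, width = 0.8, seed = 31)
  f1 <- fit_cline(obs, profile = FALSE)
  f2 <- fit_cline(rbind(obs, obs), profile = FALSE)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-4)
  w1 <- f1$support[, "upper"] - f1$support[, "lower"]
  w2 <- f2$support[, "upper"] - f2$support[, "lower"]
  expect_true(all(w2 < w1))
})

test_that("profile maximum equals the joint MLE log-likelihood", {
  obs <- obs_from_cline(200, center = -0.1, width = 0.75, seed = 32)
  f <- fit_cline(obs, profile = TRUE)
  fc <- clinezone:::.profile_c_fun(f$obs, c(1e-3, 4 * 3.5))
  fw <- clinezone:::.profile_w_fun(f$obs, range(f$obs$position) +
                                     c(-3.5, 3.5))
  # profile evaluated at the MLE reproduces the joint maximum
  expect_lt(abs(fc(coef(f)[["center"]]) - f$loglik), 1e-4)
  expect_lt(abs(fw(coef(f)[["width"]]) - f$loglik), 1e-4)
  # nothing on the stored profile grids beats the joint maximum
  expect_lte(max(f$profiles$center$loglik), f$loglik + 1e-4)
  expect_lte(max(f$profiles$width$loglik), f$loglik + 1e-4)
  expect_gt(max(f$profiles$center$loglik), f$loglik - 0.1)
  # support intervals contain the MLE
  expect_true(f$support["center", "lower"] <= coef(f)["center"] &&
                coef(f)["center"] <= f$support["center", "upper"])
  expect_true(f$support["width", "lower"] <= coef(f)["width"] &&
                coef(f)["width"] <= f$support["width", "upper"])
  # profile drops by ~2 units at the support limits
  expect_lt(abs(fc(f$support["center", "lower"]) - (f$loglik - 2)), 1e-2)
  expect_lt(abs(fc(f$support["center", "upper"]) - (f$loglik - 2)), 1e-2)
})

test_that("the fit is consistent on exact tanh data at large n", {
  obs <- obs_from_cline(10000, center = 0.05, width = 0.75, seed = 33)
  f <- fit_cline(obs, profile = FALSE)
  expect_lt(abs(coef(f)[["center"]] - 0.05), 0.03)
  expect_lt(abs(coef(f)[["width"]] - 0.75), 0.06)
})

test_that("degenerate inputs are refused", {
  mono <- data.frame(position = c(-1, 0, 1), k = c(0, 0, 0), n = 2)
  expect_error(fit_cline(mono), "monomorphic")
  onepos <- data.frame(position = rep(0, 5), k = c(0, 1, 2, 1, 0), n = 2)
  expect_error(fit_cline(onepos), "position")
})

test_that("G arithmetic and df follow the likelihood-ratio definition", {
  # two loci with identical data: shared fit equals per-locus fits, G ~ 0
  obs <- obs_from_cline(120, center = 0, width = 0.7, seed = 34)
  d <- make_dataset(cbind(A = obs$k, B = obs$k), mito = NULL,
                    nuclear = c("A", "B"))
  pr <- structure(list(base = d, heading = 0, origin = c(0, 0),
                       position = obs$position),
                  class = "projected_dataset")
  for (sh in c("center", "width", "both")) {
    t <- fit_shared_and_test(pr, sh)
    expect_lt(abs(t$G), 0.02)
    expect_equal(t$df, if (sh == "both") 2 else 1)
    expect_gte(t$G, -1e-6)
  }
  # arithmetic: G = 2 (LL_free - LL_shared), df = (L - 1) * n_shared
  expect_equal(2 * (-100 - (-103.2)), 6.4)
  expect_equal((4 - 1) * 1, 3)
})

test_that("coincidence test separates shifted centres", {
  set.seed(35)
  x <- runif(250, -1.75, 1.75)
  kA <- rbinom(250, 2, tanh_p(x, -0.3, 0.75))
  kB <- rbinom(250, 2, tanh_p(x, 0.3, 0.75))
  d <- make_dataset(cbind(A = kA, B = kB), nuclear = c("A", "B"))
  pr <- structure(list(base = d, heading = 0, origin = c(0, 0),
                       position = x),
                  class = "projected_dataset")
  t <- fit_shared_and_test(pr, "center")
  expect_lt(t$p, 1e-6)
  expect_gt(t$G, 20)
})

test_that("cline_fit methods are coherent", {
  obs <- obs_from_cline(150, center = 0, width = 0.8, seed = 38)
  f <- fit_cline(obs, profile = FALSE)
  expect_equal(unname(predict(f, coef(f)["center"])), 0.5)
  expect_equal(length(residuals(f)), nrow(obs))
  expect_equal(as.numeric(logLik(f)), f$loglik)
  ci <- confint(f)
  expect_equal(dim(ci), c(2, 2))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(obs), 3))
  expect_true(all(sims >= 0 & sims <= 2))
})
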