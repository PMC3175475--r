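# Independent brute-force oracles used to validate the ML machinery.

# Exhaustive search over monotone frequency sequences on a grid, as a
# dynamic program: best_j(v) = ll_j(v) + max_{u <= v} best_{j-1}(u).
# Searches exactly the space of non-decreasing sequences on the grid.
pava_oracle_ll <- function(k, n, grid_step = 0.001) {
  p <- seq(0, 1, by = grid_step)
  ll_term <- function(ki, ni) {
    t1 <- if (ki > 0) ki * log(p) else rep(0, length(p))
    t2 <- if (ni - ki > 0) (ni - ki) * log(1 - p) else rep(0, length(p))
    t1 + t2
  }
  best <- rep(0, length(p))
  for (j in seq_along(k)) best <- ll_term(k[j], n[j]) + cummax(best)
  max(best)
}

# Multinomial log-likelihood of a 3x3 two-locus genotype table given
# haplotype frequencies; mirrors the random-union-of-gametes model but
# written independently (explicit 9-cell formulas).
pair_table_ll <- function(tab, hKK, hKE, hEK, hEE) {
  P <- matrix(0, 3, 3)
  P[3, 3] <- hKK^2
  P[3, 2] <- 2 * hKK * hKE
  P[3, 1] <- hKE^2
  P[2, 3] <- 2 * hKK * hEK
  P[2, 2] <- 2 * hKK * hEE + 2 * hKE * hEK
  P[2, 1] <- 2 * hKE * hEE
  P[1, 3] <- hEK^2
  P[1, 2] <- 2 * hEK * hEE
  P[1, 1] <- hEE^2
  sum(tab[tab > 0] * log(pmax(P[tab > 0], 1e-300)))
}

# Grid-search ML of gametic D for a 3x3 table.  The ML margins equal the
# observed allele frequencies (phase resolution preserves margins), so D
# is scanned on a fine grid at fixed margins; pair_oracle_check3d below
# verifies the margin claim on sample tables with a coarse 3-D scan.
pair_D_oracle <- function(tab, grid_step = 0.001) {
  N <- sum(tab)
  pA <- (2 * sum(tab[3, ]) + sum(tab[2, ])) / (2 * N)
  pB <- (2 * sum(tab[, 3]) + sum(tab[, 2])) / (2 * N)
  d_lo <- -min(pA * pB, (1 - pA) * (1 - pB))
  d_hi <- min(pA * (1 - pB), (1 - pA) * pB)
  ds <- seq(d_lo, d_hi, by = grid_step)
  lls <- vapply(ds, function(D)
    pair_table_ll(tab, pA * pB + D, pA * (1 - pB) - D,
                  (1 - pA) * pB - D, (1 - pA) * (1 - pB) + D),
    numeric(1))
  list(D = ds[which.max(lls)], loglik = max(lls), p_A = pA, p_B = pB)
}

pair_oracle_check3d <- function(tab, step = 0.02) {
  best <- -Inf
  for (pA in seq(step, 1 - step, by = step))
    for (pB in seq(step, 1 - step, by = step)) {
      d_lo <- -min(pA * pB, (1 - pA) * (1 - pB))
      d_hi <- min(pA * (1 - pB), (1 - pA) * pB)
      for (D in seq(d_lo, d_hi, length.out = 21)) {
        ll <- pair_table_ll(tab, pA * pB + D, pA * (1 - pB) - D,
                            (1 - pA) * pB - D, (1 - pA) * (1 - pB) + D)
        best <- max(best, ll)
      }
    }
  best
}

# Grid-search ML of cytonuclear D for a 2x3 table under the constrained
# joint model: mitotype m ~ Bernoulli(p_mt); each of the two nuclear
# copies K with probability P(K | m) consistent with margins and D.
cyto_D_oracle <- function(tab, grid_step = 0.001) {
  N <- sum(tab)
  p_mt <- sum(tab[2, ]) / N
  p_nuc <- (2 * sum(tab[, 3]) + sum(tab[, 2])) / (2 * N)
  d_lo <- -min(p_mt * p_nuc, (1 - p_mt) * (1 - p_nuc))
  d_hi <- min(p_mt * (1 - p_nuc), (1 - p_mt) * p_nuc)
  ds <- seq(d_lo, d_hi, by = grid_step)
  lls <- vapply(ds, function(D) {
    piK <- p_nuc + D / p_mt
    piE <- p_nuc - D / (1 - p_mt)
    if (piK < 0 || piK > 1 || piE < 0 || piE > 1) return(-Inf)
    ll <- 0
    for (m in 1:2) for (g in 1:3) {
      if (tab[m, g] == 0) next
      pm <- if (m == 2) p_mt else 1 - p_mt
      pk <- if (m == 2) piK else piE
      ll <- ll + tab[m, g] *
        log(max(pm * stats::dbinom(g - 1, 2, pk), 1e-300))
    }
    ll
  }, numeric(1))
  list(D = ds[which.max(lls)], loglik = max(lls))
}
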