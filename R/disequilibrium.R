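#' ML heterozygote deficit at one diploid locus
#'
#' The single-diploid-locus analogue of gametic disequilibrium: under the
#' multinomial genotype model the ML genotype frequencies are the observed
#' proportions, so `D_within = P(KK) - p^2` with
#' `p = (2 n_KK + n_KE) / (2N)`.  Positive values mean homozygote excess;
#' the estimate is bounded in `[-0.25, 0.25]`.
#'
#' @param counts genotype counts `c(n_KK, n_KE, n_EE)`.
#' @return list with `D`, the K-allele frequency `p`, and `N`.
#' @export
het_deficit_ml <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  N <- sum(counts)
  if (N < 1) stop("no individuals")
  p <- (2 * counts[1] + counts[2]) / (2 * N)
  D <- counts[1] / N - p^2
  list(D = unname(D), p = unname(p), N = N)
}

# Genotype-class probabilities from haplotype frequencies under random
# union of gametes.  h = c(KK, KE, EK, EE) meaning (A allele, B allele).
.geno_probs <- function(h) {
  pAB <- function(i, j) {
    # P(i K-copies at A, j K-copies at B)
    tot <- 0
    haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
    for (u in 1:4) for (v in 1:4) {
      if (haps[u, 1] + haps[v, 1] == i && haps[u, 2] + haps[v, 2] == j)
        tot <- tot + h[u] * h[v]
    }
    tot
  }
  outer(0:2, 0:2, Vectorize(pAB))
}

.pair_ll <- function(tab, h) {
  P <- .geno_probs(h)
  sum(tab[tab > 0] * log(pmax(P[tab > 0], 1e-300)))
}

#' ML gametic disequilibrium between two diploid loci (EM)
#'
#' Estimates the gametic disequilibrium
#' `D = h_KK - p_A p_B` from unphased two-locus diploid genotype counts by
#' maximum likelihood under random union of gametes, resolving the
#' double-heterozygote phase ambiguity with an EM algorithm on the four
#' haplotype frequencies.  Positive `D` means K alleles co-occur.  Multiple
#' deterministic starts (`D0` at 0 and at plus/minus 0.02, 0.1, 0.2,
#' clipped to the admissible range) guard against the saddle at `D = 0`;
#' when the likelihood is maximised to within `1e-6` at both `+D` and
#' `-D` the estimate is degenerate and 0 is returned with a flag.
#'
#' @param tab 3x3 genotype count matrix, rows = K-copies at locus A
#'   (0, 1, 2), columns = K-copies at locus B.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter EM iteration cap per start.
#' @return list with `D`, allele frequencies `p_A`, `p_B`, `loglik`,
#'   `converged`, `degenerate`, and the log-likelihood `trace` of the best
#'   start (non-decreasing by construction of EM).
#' @export
pairwise_D_ml <- function(tab, tol = 1e-10, max_iter = 10000) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(3, 3)), all(tab >= 0))
  N <- sum(tab)
  if (N < 1) stop("no individuals")
  nA <- rowSums(tab)
  nB <- colSums(tab)
  pA <- (2 * nA[3] + nA[2]) / (2 * N)
  pB <- (2 * nB[3] + nB[2]) / (2 * N)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(D = NA_real_, p_A = unname(pA), p_B = unname(pB),
                loglik = NA_real_, converged = FALSE, degenerate = FALSE,
                trace = numeric(0)))
  d_lo <- -min(pA * pB, (1 - pA) * (1 - pB))
  d_hi <- min(pA * (1 - pB), (1 - pA) * pB)
  starts <- unique(clamp(c(0, 0.02, -0.02, 0.1, -0.1, 0.2, -0.2),
                         d_lo + 1e-4, d_hi - 1e-4))
  run_em <- function(D0) {
    h <- c(pA * pB + D0, pA * (1 - pB) - D0,
           (1 - pA) * pB - D0, (1 - pA) * (1 - pB) + D0)
    h <- pmax(h, 1e-9)
    h <- h / sum(h)
    ll_old <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      # E-step: expected haplotype counts; only the double heterozygote
      # (cell 2,2) is phase-ambiguous
      u <- h[1] * h[4] / (h[1] * h[4] + h[2] * h[3])
      if (!is.finite(u)) u <- 0.5
      cKK <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + tab[2, 2] * u
      cKE <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + tab[2, 2] * (1 - u)
      cEK <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3] + tab[2, 2] * (1 - u)
      cEE <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + tab[2, 2] * u
      h <- c(cKK, cKE, cEK, cEE) / (2 * N)
      ll <- .pair_ll(tab, h)
      trace <- c(trace, ll)
      if (ll < ll_old - 1e-8)
        stop("EM log-likelihood decreased; numerical failure")
      if (abs(ll - ll_old) < tol)
        return(list(h = h, loglik = ll, converged = TRUE, trace = trace))
      ll_old <- ll
    }
    list(h = h, loglik = ll_old, converged = FALSE, trace = trace)
  }
  runs <- lapply(starts, run_em)
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- runs[[which.max(lls)]]
  Ds <- vapply(runs, function(r) r$h[1] - pA * pB, numeric(1))
  D_hat <- best$h[1] - pA * pB
  near_max <- lls >= max(lls) - 1e-6
  degenerate <- abs(D_hat) > 1e-8 &&
    any(near_max & Ds <= -abs(D_hat) + 1e-6) &&
    any(near_max & Ds >= abs(D_hat) - 1e-6)
  list(D = if (degenerate) 0 else unname(D_hat),
       p_A = unname(pA), p_B = unname(pB),
       loglik = best$loglik, converged = best$converged,
       degenerate = degenerate, trace = best$trace)
}

#' ML cytonuclear disequilibrium (closed form)
#'
#' Association between the haploid mitochondrial haplotype and a random
#' nuclear allele copy of the same individual:
#' `D = P(mito = K, nuclear = K) - p_mt p_nuc` with
#' `P(K, K) = (2 n(K, KK) + n(K, KE)) / (2N)`.  Because the mitochondrial
#' marker is haploid there is no phase ambiguity and the plug-in estimate
#' is the exact ML estimate.
#'
#' @param tab 2x3 count matrix, rows = mitotype (`E`, `K`), columns =
#'   nuclear K-copies (0, 1, 2).
#' @return list with `D`, `p_mt`, `p_nuc` and `N`.
#' @export
cytonuclear_D_ml <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 3)), all(tab >= 0))
  N <- sum(tab)
  if (N < 1) stop("no individuals")
  p_mt <- sum(tab[2, ]) / N
  p_nuc <- (2 * sum(tab[, 3]) + sum(tab[, 2])) / (2 * N)
  if (p_mt %in% c(0, 1) || p_nuc %in% c(0, 1))
    return(list(D = NA_real_, p_mt = p_mt, p_nuc = p_nuc, N = N))
  PKK <- (2 * tab[2, 3] + tab[2, 2]) / (2 * N)
  list(D = unname(PKK - p_mt * p_nuc), p_mt = unname(p_mt),
       p_nuc = unname(p_nuc), N = N)
}

# D must respect the allele-frequency bounds; tiny slack for float error.
.check_D_bounds <- function(D, pA, pB) {
  if (is.na(D)) return(invisible(TRUE))
  lo <- -min(pA * pB, (1 - pA) * (1 - pB)) - 1e-9
  hi <- min(pA * (1 - pB), (1 - pA) * pB) + 1e-9
  stopifnot(D >= max(lo, -0.25 - 1e-9), D <= min(hi, 0.25 + 1e-9))
  invisible(TRUE)
}

#' Sliding-window ML disequilibrium scan
#'
#' Moves a spatial window along the transect (defaults: 200 m window,
#' 100 m steps) and reports, per window, the unweighted mean over loci or
#' locus pairs of three ML disequilibrium components: within-locus
#' heterozygote deficit ([het_deficit_ml()]), between-nuclear-locus
#' gametic D ([pairwise_D_ml()]), and cytonuclear D
#' ([cytonuclear_D_ml()]).  Window membership is half-open on the right
#' (`[center - window/2, center + window/2)`); a component is omitted
#' (`NA`) in windows with fewer than `min_n` complete individuals, and
#' monomorphic loci or pairs contribute no estimate.
#'
#' @param projected a `projected_dataset`.
#' @param window window size (km).
#' @param step window increment (km).
#' @param min_n minimum complete individuals per component.
#' @param loci nuclear loci to use (default: all nuclear).
#' @return data.frame of class `ld_scan`: `center`, `n`, `D_within`,
#'   `D_between`, `D_cyto`.
#' @export
ld_scan <- function(projected, window = 0.2, step = 0.1, min_n = 5,
                    loci = NULL) {
  stopifnot(window > 0, step > 0)
  dataset <- projected$base
  nuc <- loci %||% nuclear_loci(dataset)
  mt <- mito_locus(dataset)
  pos <- projected$position
  lo <- min(pos) + window / 2
  hi <- max(pos) - window / 2
  if (hi < lo) {
    warning("transect shorter than one window")
    return(structure(data.frame(), class = c("ld_scan", "data.frame")))
  }
  centers <- seq(lo, hi + 1e-9, by = step)
  kmat <- k_counts(dataset, nuc)
  mito <- dataset$individuals$mito
  pairs <- if (length(nuc) >= 2) utils::combn(nuc, 2, simplify = FALSE)
           else list()
  rows <- lapply(centers, function(ct) {
    inw <- pos >= ct - window / 2 & pos < ct + window / 2
    km <- kmat[inw, , drop = FALSE]
    mt_w <- mito[inw]
    # within-locus heterozygote deficit
    dw <- vapply(nuc, function(l) {
      k <- km[, l]
      k <- k[!is.na(k)]
      if (length(k) < min_n) return(NA_real_)
      cnt <- c(sum(k == 2), sum(k == 1), sum(k == 0))
      hd <- het_deficit_ml(cnt)
      if (hd$p %in% c(0, 1)) return(NA_real_)
      stopifnot(hd$D >= -0.25 - 1e-9, hd$D <= 0.25 + 1e-9)
      hd$D
    }, numeric(1))
    # between-nuclear gametic D
    db <- vapply(pairs, function(pr) {
      ka <- km[, pr[1]]
      kb <- km[, pr[2]]
      ok <- !is.na(ka) & !is.na(kb)
      if (sum(ok) < min_n) return(NA_real_)
      tb <- table(factor(ka[ok], 0:2), factor(kb[ok], 0:2))
      est <- pairwise_D_ml(tb)
      .check_D_bounds(est$D, est$p_A, est$p_B)
      est$D
    }, numeric(1))
    # cytonuclear D
    dc <- if (length(mt)) vapply(nuc, function(l) {
      k <- km[, l]
      ok <- !is.na(k) & !is.na(mt_w)
      if (sum(ok) < min_n) return(NA_real_)
      tb <- table(factor(mt_w[ok], c("E", "K")), factor(k[ok], 0:2))
      est <- cytonuclear_D_ml(tb)
      .check_D_bounds(est$D, est$p_mt, est$p_nuc)
      est$D
    }, numeric(1)) else NA_real_
    data.frame(center = ct, n = sum(inw),
               D_within = if (all(is.na(dw))) NA_real_
                          else mean(dw, na.rm = TRUE),
               D_between = if (!length(pairs) || all(is.na(db))) NA_real_
                           else mean(db, na.rm = TRUE),
               D_cyto = if (all(is.na(dc))) NA_real_
                        else mean(dc, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$D_within)) && all(is.na(out$D_between)) &&
      all(is.na(out$D_cyto)))
    warning("no window met the min_n requirement for any component")
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("ld_scan", "data.frame")
  out
}

#' @export
plot.ld_scan <- function(x, ...) {
  graphics::matplot(x$center, cbind(x$D_within, x$D_between, x$D_cyto),
                    type = "l", lty = 1:3, col = 1,
                    xlab = "transect position (km)", ylab = "D", ...)
  graphics::legend("topleft", c("within-locus", "between-nuclear",
                                "cytonuclear"), lty = 1:3, bty = "n")
  invisible(x)
}
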