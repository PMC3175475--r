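#' Per-individual hybrid indices
#'
#' The hybrid index (HI) of an individual is the fraction of its scored
#' allele copies that are K-type (klauberi-derived); each diploid nuclear
#' locus contributes two copies, the mitochondrial marker one.  The same
#' fraction restricted to a single locus gives the individual-by-locus
#' index `HI_loc`; the copy-weighted mean of the per-locus indices over
#' scored loci equals the overall HI exactly.
#'
#' @param dataset a [genotype_dataset()].
#' @param loci loci to include (default: all).
#' @return data.frame with one row per individual: `id`, `HI`, `copies`,
#'   and per-locus `HI_<locus>` / `copies_<locus>` columns.  `HI` is `NA`
#'   when no allele copy was scored.
#' @export
hybrid_index <- function(dataset, loci = NULL) {
  loci <- loci %||% dataset$loci$name
  ind <- dataset$individuals
  kmat <- matrix(NA_real_, nrow(ind), length(loci),
                 dimnames = list(NULL, loci))
  nmat <- matrix(0, nrow(ind), length(loci), dimnames = list(NULL, loci))
  for (l in loci) {
    if (l %in% nuclear_loci(dataset)) {
      k <- ind[[paste0("k_", l)]]
      kmat[, l] <- k
      nmat[, l] <- ifelse(is.na(k), 0, 2)
    } else {
      k <- ifelse(is.na(ind$mito), NA_real_,
                  as.numeric(ind$mito == "K"))
      kmat[, l] <- k
      nmat[, l] <- ifelse(is.na(k), 0, 1)
    }
  }
  ktot <- rowSums(kmat, na.rm = TRUE)
  ntot <- rowSums(nmat)
  out <- data.frame(id = ind$id,
                    HI = ifelse(ntot > 0, ktot / ntot, NA_real_),
                    copies = ntot, stringsAsFactors = FALSE)
  for (l in loci) {
    out[[paste0("HI_", l)]] <- ifelse(nmat[, l] > 0,
                                      kmat[, l] / nmat[, l], NA_real_)
    out[[paste0("copies_", l)]] <- nmat[, l]
  }
  out
}

#' Barton's hybrid-index concordance fit for one locus
#'
#' Models the expected per-locus hybrid index of an individual as
#' `HI_loc = HI + He (alpha + beta (2 HI - 1))` with
#' `He = 2 HI (1 - HI)`: `alpha` (directionality) shifts introgression at
#' the locus toward one genetic background (positive = toward K), `beta`
#' (abruptness) makes its transition steeper or shallower than the
#' equal-introgression diagonal.  Fitted by binomial maximum likelihood on
#' the locus's K-copy counts with success probability clamped to
#' `[1e-6, 1 - 1e-6]`, and tested against `alpha = beta = 0` with a
#' 2-df likelihood-ratio (G) test.  Individuals with `HI` of 0 or 1 have
#' `He = 0` and contribute no information about `(alpha, beta)`.
#'
#' @param dataset a [genotype_dataset()].
#' @param locus focal locus name.
#' @param loci loci over which the regressor `HI` is computed (default:
#'   all, including the focal locus).
#' @param leave_one_out exclude the focal locus from the regressor `HI`.
#' @return An object of class `concordance_fit` with `alpha`, `beta`,
#'   `loglik`, and the LRT (`G`, `df`, `p`).
#' @export
fit_concordance <- function(dataset, locus, loci = NULL,
                            leave_one_out = FALSE) {
  loci <- loci %||% dataset$loci$name
  hi_loci <- if (leave_one_out) setdiff(loci, locus) else loci
  hi <- hybrid_index(dataset, hi_loci)
  ob <- .locus_obs(dataset, locus)
  keep <- ob$keep & !is.na(hi$HI)
  # .locus_obs returns k/n already subset to scored individuals
  k <- ob$k[keep[ob$keep]]
  n <- ob$n[keep[ob$keep]]
  HI <- hi$HI[keep]
  if (length(k) < 10)
    stop("need at least 10 individuals with both HI and the locus scored")
  if (sum(k) == 0 || sum(k) == sum(n))
    stop("locus monomorphic in sample; concordance not identifiable")
  He <- 2 * HI * (1 - HI)
  nll <- function(par) {
    p <- clamp(HI + He * (par[1] + par[2] * (2 * HI - 1)), 1e-6, 1 - 1e-6)
    -binom_ll(k, n, p)
  }
  best <- NULL
  for (st in list(c(0, 0), c(0.5, 0), c(-0.5, 0), c(0, 1), c(0, -1))) {
    fit <- try(stats::optim(st, nll, method = "Nelder-Mead",
                            control = list(reltol = 1e-12,
                                           maxit = 2000)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$convergence != 0)
    stop("concordance optimiser failed to converge for ", locus)
  ll0 <- -nll(c(0, 0))
  G <- 2 * (-best$value - ll0)
  structure(list(locus = locus, alpha = best$par[1], beta = best$par[2],
                 loglik = -best$value, loglik0 = ll0,
                 G = G, df = 2,
                 p = stats::pchisq(max(G, 0), 2, lower.tail = FALSE),
                 data = data.frame(HI = HI, k = k, n = n),
                 leave_one_out = leave_one_out),
            class = "concordance_fit")
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat("Concordance fit for ", x$locus, ":\n", sep = "")
  cat(sprintf("  alpha (directionality) = %.3f\n", x$alpha))
  cat(sprintf("  beta  (abruptness)     = %.3f\n", x$beta))
  cat(sprintf("  G = %.3f (df 2), p = %.4g vs equal introgression\n",
              x$G, x$p))
  invisible(x)
}

#' Predicted per-locus hybrid index under a concordance fit
#' @param object a `concordance_fit`.
#' @param newdata optional vector of `HI` values.
#' @param ... unused.
#' @return Predicted `HI_loc`, clamped to `[0, 1]`.
#' @export
predict.concordance_fit <- function(object, newdata = NULL, ...) {
  HI <- newdata %||% object$data$HI
  He <- 2 * HI * (1 - HI)
  clamp(HI + He * (object$alpha + object$beta * (2 * HI - 1)), 0, 1)
}

#' @export
plot.concordance_fit <- function(x, ...) {
  graphics::plot(x$data$HI, x$data$k / x$data$n,
                 xlab = "individual HI",
                 ylab = paste0("HI at ", x$locus),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  hs <- seq(0, 1, length.out = 200)
  graphics::lines(hs, predict(x, hs))
  invisible(x)
}
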