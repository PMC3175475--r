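#' Sigmoid (tanh) cline frequency
#'
#' `p(x) = (1 + tanh(2 (x - c) / w)) / 2`: strictly increasing in `x`,
#' equal to 1/2 at the centre `c`, with maximum slope `1/w` at the centre
#' (the width `w` is the inverse of the maximum slope).
#'
#' @param x transect position (km).
#' @param c cline centre (km).
#' @param w cline width (km), strictly positive.
#' @return Allele frequency in (0, 1).
#' @export
tanh_p <- function(x, c, w) {
  if (any(w <= 0)) stop("cline width must be > 0")
  (1 + tanh(2 * (x - c) / w)) / 2
}

#' Binomial log-likelihood of a tanh cline
#'
#' Sums `k log p + (n - k) log(1 - p)` over observations, with `p` from
#' [tanh_p()] clamped to `[1e-12, 1 - 1e-12]`.  Diploid loci contribute
#' `n = 2` allele copies per individual (Hardy-Weinberg within site); the
#' parameter-free binomial coefficient is omitted.
#'
#' @param c cline centre (km).
#' @param w cline width (km).
#' @param obs data.frame with columns `position`, `k`, `n`.
#' @return Log-likelihood (scalar).
#' @export
cline_loglik <- function(c, w, obs) {
  if (is.null(obs) || nrow(obs) == 0) stop("no observations")
  p <- clamp(tanh_p(obs$position, c, w), 1e-12, 1 - 1e-12)
  binom_ll(obs$k, obs$n, p)
}

#' Per-locus cline observations of a projected dataset
#'
#' One row per scored individual-locus: transect `position` (km), K-allele
#' count `k`, allele copies `n` (2 nuclear, 1 mitochondrial), `locus`.
#'
#' @param projected a `projected_dataset` from [project_positions()].
#' @param loci loci to include (default: all in the dataset).
#' @return data.frame with columns `position`, `k`, `n`, `locus`.
#' @export
cline_obs <- function(projected, loci = NULL) {
  stopifnot(inherits(projected, "projected_dataset"))
  dataset <- projected$base
  loci <- loci %||% dataset$loci$name
  out <- lapply(loci, function(l) {
    ob <- .locus_obs(dataset, l)
    if (!sum(ob$keep)) return(NULL)
    data.frame(position = projected$position[ob$keep], k = ob$k, n = ob$n,
               locus = l, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Bounded quasi-Newton fit of a single (c, w) to pooled observations,
# deterministic multistarts: c at position quantiles 0.25/0.5/0.75, w at
# 0.5x and 2x of span/4.  Width optimised on the log scale.
.fit_tanh <- function(obs, w_min = 1e-3, w_max = NULL) {
  span <- diff(range(obs$position))
  if (span <= 0) stop("all observations at one position; no cline")
  if (sum(obs$k) == 0 || sum(obs$k) == sum(obs$n))
    stop("data monomorphic; no cline to fit")
  w_max <- w_max %||% (4 * span)
  c_lo <- min(obs$position) - span
  c_hi <- max(obs$position) + span
  nll <- function(par) -cline_loglik(par[1], exp(par[2]), obs)
  starts <- expand.grid(
    c0 = stats::quantile(obs$position, c(0.25, 0.5, 0.75), names = FALSE),
    lw0 = log(c(span / 8, span / 2)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(c(starts$c0[i], starts$lw0[i]), nll,
                            method = "L-BFGS-B",
                            lower = c(c_lo, log(w_min)),
                            upper = c(c_hi, log(w_max)),
                            control = list(factr = 1e4)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("cline optimiser failed to converge")
  list(center = best$par[1], width = exp(best$par[2]),
       loglik = -best$value,
       bounds = list(c = c(c_lo, c_hi), w = c(w_min, w_max)))
}

# Profile log-likelihood functions for a single shared (c, w).
.profile_c_fun <- function(obs, w_bounds) {
  function(cv) {
    -stats::optimize(function(lw) -cline_loglik(cv, exp(lw), obs),
                     lower = log(w_bounds[1]), upper = log(w_bounds[2]),
                     tol = 1e-9)$objective
  }
}

.profile_w_fun <- function(obs, c_bounds) {
  function(wv) {
    -stats::optimize(function(cv) -cline_loglik(cv, wv, obs),
                     lower = c_bounds[1], upper = c_bounds[2],
                     tol = 1e-9)$objective
  }
}

# Two-unit support limit on one side of the MLE: expand geometrically
# until the profile drops 2 log-units, then bisect.  `f` is the profile
# log-likelihood; returns the bound itself when the profile never drops.
.support_limit <- function(f, mle, llmax, bound, scale, tol = 1e-5) {
  target <- llmax - 2
  dirn <- sign(bound - mle)
  if (dirn == 0) return(mle)
  step <- scale / 10
  outer <- mle
  repeat {
    cand <- outer + dirn * step
    if ((dirn > 0 && cand >= bound) || (dirn < 0 && cand <= bound)) {
      if (f(bound) >= target) return(bound)
      cand <- bound
      break
    }
    if (f(cand) < target) break
    outer <- cand
    step <- step * 2
  }
  inner <- outer
  outer <- cand
  while (abs(outer - inner) > tol) {
    mid <- (inner + outer) / 2
    if (f(mid) >= target) inner <- mid else outer <- mid
  }
  (inner + outer) / 2
}

#' Fit a tanh cline by maximum likelihood
#'
#' Fits a single sigmoid cline (centre `c`, width `w`) to the pooled
#' observations of one locus or of several loci sharing both parameters.
#' Profile log-likelihoods (re-optimising the other parameter at each
#' point) give two-unit support limits, the likelihood analogue of 95%
#' confidence intervals.
#'
#' @param x a `projected_dataset`, or a data.frame of observations with
#'   columns `position`, `k`, `n`.
#' @param loci loci to pool when `x` is a projected dataset (default: all).
#' @param w_min,w_max bounds on the width (km); defaults `1e-3` and four
#'   times the position span.
#' @param profile also store profile curves on a grid (for plotting).
#' @param support compute two-unit support limits (skippable to speed up
#'   large simulation loops).
#' @return An object of class `cline_fit` with components `coefficients`
#'   (`center`, `width`), `loglik`, `support` (two-unit limits, one row
#'   per parameter), `profiles`, and the observations.
#' @export
fit_cline <- function(x, loci = NULL, w_min = 1e-3, w_max = NULL,
                      profile = TRUE, support = TRUE) {
  obs <- if (inherits(x, "projected_dataset")) cline_obs(x, loci)
         else x
  if (is.null(obs) || nrow(obs) == 0) stop("no observations")
  fit <- .fit_tanh(obs, w_min, w_max)
  fc <- .profile_c_fun(obs, fit$bounds$w)
  fw <- .profile_w_fun(obs, fit$bounds$c)
  if (!support) {
    sup <- matrix(NA_real_, 2, 2,
                  dimnames = list(c("center", "width"),
                                  c("lower", "upper")))
    return(structure(
      list(coefficients = c(center = fit$center, width = fit$width),
           loglik = fit$loglik, support = sup, profiles = NULL,
           obs = obs, loci = unique(as.character(obs$locus %||% "pooled")),
           nobs = nrow(obs), call = match.call()),
      class = "cline_fit"))
  }
  sup <- rbind(
    center = c(.support_limit(fc, fit$center, fit$loglik,
                              fit$bounds$c[1], fit$width),
               .support_limit(fc, fit$center, fit$loglik,
                              fit$bounds$c[2], fit$width)),
    width = c(.support_limit(fw, fit$width, fit$loglik,
                             fit$bounds$w[1], fit$width),
              .support_limit(fw, fit$width, fit$loglik,
                             fit$bounds$w[2], fit$width)))
  colnames(sup) <- c("lower", "upper")
  profiles <- NULL
  if (profile) {
    cgrid <- seq(fit$center - 2 * (fit$center - sup["center", "lower"]),
                 fit$center + 2 * (sup["center", "upper"] - fit$center),
                 length.out = 41)
    wgrid <- seq(max(fit$bounds$w[1],
                     fit$width - 2 * (fit$width - sup["width", "lower"])),
                 fit$width + 2 * (sup["width", "upper"] - fit$width),
                 length.out = 41)
    profiles <- list(
      center = data.frame(value = cgrid,
                          loglik = vapply(cgrid, fc, numeric(1))),
      width = data.frame(value = wgrid,
                         loglik = vapply(wgrid, fw, numeric(1))))
  }
  structure(list(coefficients = c(center = fit$center, width = fit$width),
                 loglik = fit$loglik, support = sup, profiles = profiles,
                 obs = obs,
                 loci = unique(as.character(obs$locus %||% "pooled")),
                 nobs = nrow(obs), call = match.call()),
            class = "cline_fit")
}

#' Coincidence and concordance tests across loci
#'
#' Compares independent per-locus tanh clines (the free model) against a
#' model sharing the centre, the width, or both across loci, using the
#' likelihood-ratio statistic `G = 2 (LL_free - LL_shared)` referred to a
#' chi-square distribution with `(n_loci - 1) x n_shared_parameters`
#' degrees of freedom.
#'
#' @param projected a `projected_dataset`.
#' @param shared which parameter(s) to share: `"center"`, `"width"` or
#'   `"both"`.
#' @param loci loci to include (default: all); loci with no scored data
#'   are excluded with a warning.
#' @param support compute two-unit support limits for the shared
#'   parameter.
#' @return An object of class `cline_coincidence`: per-locus `free_fits`,
#'   the `shared_fit` (shared parameter MLE with two-unit support limits
#'   and per-locus nuisance parameters), and `G`, `df`, `p`.
#' @export
fit_shared_and_test <- function(projected,
                                shared = c("center", "width", "both"),
                                loci = NULL, support = TRUE) {
  shared <- match.arg(shared)
  dataset <- projected$base
  loci <- loci %||% dataset$loci$name
  obs_all <- cline_obs(projected, loci)
  have <- loci %in% unique(obs_all$locus)
  if (any(!have)) {
    warning("excluding locus with no data: ",
            paste(loci[!have], collapse = ", "))
    loci <- loci[have]
  }
  if (length(loci) < 2) stop("need at least 2 loci with data")
  obs_by <- split(obs_all, obs_all$locus)[loci]
  free_fits <- lapply(obs_by, fit_cline, profile = FALSE,
                      support = FALSE)
  ll_free <- sum(vapply(free_fits, `[[`, numeric(1), "loglik"))
  if (shared == "both") {
    sf <- fit_cline(obs_all, profile = FALSE, support = support)
    shared_fit <- list(coefficients = coef(sf), loglik = sf$loglik,
                       support = sf$support, per_locus = NULL)
    n_shared <- 2
  } else {
    # profile over the shared parameter; the per-locus nuisance
    # parameter is separable, one 1D optimisation per locus
    bounds_w <- c(1e-3, 4 * diff(range(obs_all$position)))
    bounds_c <- range(obs_all$position) +
      c(-1, 1) * diff(range(obs_all$position))
    L <- length(obs_by)
    cen_free <- vapply(free_fits, function(f) coef(f)[["center"]],
                       numeric(1))
    wid_free <- vapply(free_fits, function(f) coef(f)[["width"]],
                       numeric(1))
    nobs_free <- vapply(free_fits, `[[`, numeric(1), "nobs")
    if (shared == "center") {
      # joint fit: one shared centre, free per-locus widths
      nll <- function(par) -sum(vapply(seq_len(L), function(i)
        cline_loglik(par[1], exp(par[1 + i]), obs_by[[i]]), numeric(1)))
      start <- c(stats::weighted.mean(cen_free, nobs_free),
                 log(wid_free))
      lo <- c(bounds_c[1], rep(log(bounds_w[1]), L))
      hi <- c(bounds_c[2], rep(log(bounds_w[2]), L))
      prof <- function(cv) {
        sum(vapply(obs_by, function(ob)
          .profile_c_fun(ob, bounds_w)(cv), numeric(1)))
      }
      lims <- bounds_c
    } else {
      nll <- function(par) -sum(vapply(seq_len(L), function(i)
        cline_loglik(par[1 + i], exp(par[1]), obs_by[[i]]), numeric(1)))
      start <- c(log(stats::weighted.mean(wid_free, nobs_free)),
                 cen_free)
      lo <- c(log(bounds_w[1]), rep(bounds_c[1], L))
      hi <- c(log(bounds_w[2]), rep(bounds_c[2], L))
      prof <- function(wv) {
        sum(vapply(obs_by, function(ob)
          .profile_w_fun(ob, bounds_c)(wv), numeric(1)))
      }
      lims <- bounds_w
    }
    opt <- stats::optim(start, nll, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(factr = 1e4))
    mle <- if (shared == "center") opt$par[1] else exp(opt$par[1])
    llmax <- -opt$value
    scale <- if (shared == "center")
      mean(vapply(free_fits, function(f) coef(f)["width"], numeric(1)))
    else mle
    sup <- if (support)
      c(.support_limit(prof, mle, llmax, lims[1], scale),
        .support_limit(prof, mle, llmax, lims[2], scale))
    else c(NA_real_, NA_real_)
    per_locus <- lapply(obs_by, function(ob) {
      if (shared == "center") {
        o <- stats::optimize(function(lw)
          -cline_loglik(mle, exp(lw), ob),
          lower = log(bounds_w[1]), upper = log(bounds_w[2]), tol = 1e-9)
        c(width = exp(o$minimum))
      } else {
        o <- stats::optimize(function(cv) -cline_loglik(cv, mle, ob),
                             lower = bounds_c[1], upper = bounds_c[2],
                             tol = 1e-9)
        c(center = o$minimum)
      }
    })
    shared_fit <- list(
      coefficients = stats::setNames(mle, shared), loglik = llmax,
      support = matrix(sup, 1, 2,
                       dimnames = list(shared, c("lower", "upper"))),
      per_locus = per_locus)
    n_shared <- 1
  }
  G <- 2 * (ll_free - shared_fit$loglik)
  df <- (length(loci) - 1) * n_shared
  structure(list(shared = shared, loci = loci, free_fits = free_fits,
                 shared_fit = shared_fit, ll_free = ll_free,
                 G = G, df = df,
                 p = stats::pchisq(max(G, 0), df, lower.tail = FALSE)),
            class = "cline_coincidence")
}

#' @export
print.cline_coincidence <- function(x, ...) {
  cat("Cline ", if (x$shared == "center") "coincidence"
      else if (x$shared == "width") "concordance" else "coincidence",
      " test: shared ", x$shared, " across ",
      length(x$loci), " loci\n", sep = "")
  cat(sprintf("  G = %.3f, df = %d, p = %.4g\n", x$G, x$df, x$p))
  cat(sprintf("  shared %s MLE: %s\n", x$shared,
              paste(sprintf("%.3f", x$shared_fit$coefficients),
                    collapse = ", ")))
  invisible(x)
}
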