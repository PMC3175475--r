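#' Project sampling coordinates onto a one-dimensional transect
#'
#' Coordinates are mapped to a local planar frame by an equirectangular
#' projection (adequate below a few tens of km; error under a metre at the
#' scale of a hybrid zone), then collapsed onto the axis with the given
#' compass heading: `position = east * sin(theta) + north * cos(theta)`.
#' With the default centroid origin positions are centred on zero.
#'
#' @param dataset a [genotype_dataset()].
#' @param heading compass heading of the transect axis, degrees.
#' @param origin `"centroid"` or an explicit `c(lat, lon)` anchor.
#' @return An object of class `projected_dataset`: the dataset plus
#'   `heading`, `origin` and per-individual `position` (km).
#' @export
project_positions <- function(dataset, heading, origin = "centroid") {
  ind <- dataset$individuals
  miss <- is.na(ind$lat) | is.na(ind$lon)
  if (any(miss))
    stop("missing coordinates for individual(s): ",
         paste(ind$id[miss], collapse = ", "))
  lat0 <- mean(ind$lat)
  lon0 <- mean(ind$lon)
  pl <- planar_from_latlon(ind$lat, ind$lon, lat0, lon0)
  if (!identical(origin, "centroid")) {
    anchor <- planar_from_latlon(origin[1], origin[2], lat0, lon0)
    pl <- sweep(pl, 2, as.numeric(anchor))
  } else {
    pl <- sweep(pl, 2, colMeans(pl))
  }
  th <- .deg2rad(heading)
  position <- pl[, "east"] * sin(th) + pl[, "north"] * cos(th)
  structure(list(base = dataset, heading = heading %% 360,
                 origin = if (identical(origin, "centroid"))
                   c(lat0, lon0) else origin,
                 planar = pl, position = as.numeric(position)),
            class = "projected_dataset")
}

#' @export
print.projected_dataset <- function(x, ...) {
  cat("Projected dataset: heading ", x$heading, " deg, positions ",
      sprintf("%.3f", min(x$position)), " to ",
      sprintf("%.3f", max(x$position)), " km (n = ",
      length(x$position), ")\n", sep = "")
  invisible(x)
}

# Weighted pool-adjacent-violators: non-decreasing fit minimising
# sum w_i (y_i - f_i)^2, which is also the binomial ML monotone fit when
# y = k/n and w = n.  Stack implementation, O(n).
.pava <- function(y, w) {
  n <- length(y)
  val <- numeric(n)
  wt <- numeric(n)
  len <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]
    wt[top] <- w[i]
    len[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      nw <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] +
                          wt[top] * val[top]) / nw
      wt[top - 1L] <- nw
      len[top - 1L] <- len[top - 1L] + len[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = len[seq_len(top)])
}

#' Maximum-likelihood monotone cline (pool adjacent violators)
#'
#' Fits the monotone allele-frequency sequence maximising the binomial
#' likelihood of the observations (isotonic regression of `k/n` with
#' weights `n`).  Observations tied in position are pooled before fitting,
#' since isotonic regression is defined on distinct abscissae.
#'
#' @param position transect positions (km), one per observation.
#' @param k K-allele successes per observation.
#' @param n trials per observation (1 for haploid, 2 for diploid).
#' @param direction `"increasing"` or `"decreasing"` frequency with
#'   position.
#' @return An object of class `pava_cline` with the pooled distinct
#'   positions, pooled `k` and `n`, the `fitted` monotone frequencies and
#'   the binomial `loglik`.
#' @export
pava_fit <- function(position, k, n,
                     direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  keep <- !is.na(position) & !is.na(k) & !is.na(n)
  position <- position[keep]; k <- k[keep]; n <- n[keep]
  if (!length(position)) stop("no scored observations for this locus")
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n))
  kp <- tapply(k, position, sum)
  np <- tapply(n, position, sum)
  xs <- as.numeric(names(kp))
  o <- order(xs)
  xs <- xs[o]; kp <- as.numeric(kp[o]); np <- as.numeric(np[o])
  y <- kp / np
  fitted <- if (direction == "increasing") .pava(y, np)
            else rev(.pava(rev(y), rev(np)))
  structure(list(position = xs, k = kp, n = np, fitted = fitted,
                 direction = direction,
                 loglik = binom_ll(kp, np, fitted),
                 nobs = sum(keep)),
            class = "pava_cline")
}

#' @export
print.pava_cline <- function(x, ...) {
  cat("Monotone (", x$direction, ") ML cline: ", length(x$position),
      " distinct positions, ", x$nobs, " observations, logLik ",
      sprintf("%.3f", x$loglik), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.pava_cline <- function(object, ...) {
  structure(object$loglik, df = NA, class = "logLik")
}

# Observations (k, n) per individual for one locus; NULL rows dropped.
.locus_obs <- function(dataset, locus) {
  ind <- dataset$individuals
  if (locus %in% nuclear_loci(dataset)) {
    k <- ind[[paste0("k_", locus)]]
    keep <- !is.na(k)
    list(k = k[keep], n = rep(2, sum(keep)), keep = keep)
  } else if (length(mito_locus(dataset)) && locus == mito_locus(dataset)) {
    keep <- !is.na(ind$mito)
    list(k = as.numeric(ind$mito[keep] == "K"), n = rep(1, sum(keep)),
         keep = keep)
  } else stop("unknown locus: ", locus)
}

# Summed PAVA loglik across loci at one heading; per-locus direction free.
.orientation_ll <- function(planar, obs_list, theta_deg) {
  th <- .deg2rad(theta_deg)
  pos <- planar[, "east"] * sin(th) + planar[, "north"] * cos(th)
  per <- lapply(obs_list, function(ob) {
    x <- pos[ob$keep]
    li <- pava_fit(x, ob$k, ob$n, "increasing")$loglik
    ld <- pava_fit(x, ob$k, ob$n, "decreasing")$loglik
    c(inc = li, dec = ld)
  })
  ll <- vapply(per, max, numeric(1))
  inc <- vapply(per, function(v) v["inc"] >= v["dec"], logical(1))
  list(loglik = sum(ll), increasing = inc)
}

#' Maximum-likelihood transect orientation
#'
#' Scans compass headings, projecting the sample onto each axis and
#' summing over loci the log-likelihood of the best monotone (PAVA) cline
#' (each locus choosing the better of increasing/decreasing), then refines
#' the grid argmax by golden-section search.  The profile has period 180
#' degrees up to direction relabelling; the reported heading follows the
#' convention that K-allele frequency increases along the positive axis.
#'
#' @param dataset a [genotype_dataset()].
#' @param grid heading grid step in degrees (must divide 360).
#' @param loci loci to include (default: all).
#' @param refine golden-section refinement around the grid argmax.
#' @return An object of class `orientation_fit` with the ML `heading`, the
#'   two-unit `support` limits (degrees, arc containing the MLE), the
#'   per-heading `profile`, and whether per-locus best directions agree.
#' @export
fit_orientation <- function(dataset, grid = 1, loci = NULL,
                            refine = TRUE) {
  stopifnot(360 %% grid == 0)
  loci <- loci %||% dataset$loci$name
  proj0 <- project_positions(dataset, 0)
  planar <- proj0$planar
  if (length(unique(round(planar[, 1], 9) + 1i * round(planar[, 2], 9)))
      < 3)
    stop("need at least 3 distinct sampling locations")
  obs_list <- lapply(loci, function(l) .locus_obs(dataset, l))
  names(obs_list) <- loci
  headings <- seq(0, 180 - grid, by = grid)
  half <- lapply(headings, function(h) .orientation_ll(planar, obs_list, h))
  ll_half <- vapply(half, `[[`, numeric(1), "loglik")
  i_best <- which.max(ll_half)
  h_best <- headings[i_best]
  if (refine) {
    opt <- stats::optimize(
      function(h) .orientation_ll(planar, obs_list, h)$loglik,
      lower = h_best - grid, upper = h_best + grid, maximum = TRUE,
      tol = 1e-3)
    if (opt$objective >= ll_half[i_best]) {
      h_best <- opt$maximum %% 180
      ll_best <- opt$objective
    } else ll_best <- ll_half[i_best]
  } else ll_best <- ll_half[i_best]
  best <- .orientation_ll(planar, obs_list, h_best)
  # representative orientation: majority of loci increasing along +axis
  if (mean(best$increasing) < 0.5) h_best <- (h_best + 180) %% 360
  best <- .orientation_ll(planar, obs_list, h_best)
  # full-circle profile (period 180)
  prof <- data.frame(heading = c(headings, headings + 180),
                     loglik = c(ll_half, ll_half))
  prof <- prof[order(prof$heading), ]
  # two-unit support set on the grid; the profile has period 180, so
  # offsets to the MLE are mapped to (-90, 90] and the reported limits
  # are the range of the in-support headings around the MLE
  ok <- prof$loglik >= ll_best - 2
  rel <- ((prof$heading - h_best + 90) %% 180) - 90
  lo <- h_best + min(rel[ok])
  hi <- h_best + max(rel[ok])
  structure(list(heading = h_best, loglik = ll_best,
                 support = c(lower = lo, upper = hi),
                 profile = prof, loci = loci,
                 increasing = best$increasing,
                 directions_agree = length(unique(best$increasing)) == 1,
                 grid = grid),
            class = "orientation_fit")
}

#' @export
print.orientation_fit <- function(x, ...) {
  cat("ML transect heading: ", sprintf("%.1f", x$heading),
      " deg (two-unit support ", sprintf("%.0f", x$support["lower"]),
      ", ", sprintf("%.0f", x$support["upper"]), ")\n", sep = "")
  cat("logLik ", sprintf("%.3f", x$loglik), " over ",
      length(x$loci), " loci; per-locus directions ",
      if (x$directions_agree) "agree" else "disagree", "\n", sep = "")
  invisible(x)
}

#' @export
plot.orientation_fit <- function(x, ...) {
  graphics::plot(x$profile$heading, x$profile$loglik, type = "l",
                 xlab = "heading (deg)", ylab = "log-likelihood", ...)
  graphics::abline(v = x$heading, lty = 2)
  graphics::abline(h = x$loglik - 2, lty = 3)
  invisible(x)
}
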