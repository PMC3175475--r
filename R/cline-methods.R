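#' @export
print.cline_fit <- function(x, digits = 3, ...) {
  cat("Tanh cline fit (", paste(x$loci, collapse = ", "), ")\n", sep = "")
  cat(sprintf("  center %.*f km (%.*f, %.*f)\n", digits,
              x$coefficients["center"], digits,
              x$support["center", "lower"], digits,
              x$support["center", "upper"]))
  cat(sprintf("  width  %.*f km (%.*f, %.*f)\n", digits,
              x$coefficients["width"], digits,
              x$support["width", "lower"], digits,
              x$support["width", "upper"]))
  cat(sprintf("  logLik %.3f on %d observations\n", x$loglik, x$nobs))
  invisible(x)
}

#' @export
coef.cline_fit <- function(object, ...) object$coefficients

#' @export
logLik.cline_fit <- function(object, ...) {
  structure(object$loglik, df = 2, nobs = object$nobs, class = "logLik")
}

#' Two-unit support limits of a cline fit
#'
#' Returns the profile-likelihood interval within 2 log-units of the
#' maximum for each parameter, the likelihood analogue of a 95% confidence
#' interval.  `level` is ignored (the two-unit convention is fixed).
#'
#' @param object a `cline_fit`.
#' @param parm parameters to report (default both).
#' @param level ignored; present for generic consistency.
#' @param ... unused.
#' @return Matrix with columns `lower`, `upper`.
#' @export
confint.cline_fit <- function(object, parm = c("center", "width"),
                              level = NULL, ...) {
  object$support[parm, , drop = FALSE]
}

#' @export
predict.cline_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$obs$position
       else if (is.data.frame(newdata)) newdata$position
       else as.numeric(newdata)
  tanh_p(x, object$coefficients["center"], object$coefficients["width"])
}

#' @export
fitted.cline_fit <- function(object, ...) predict(object)

#' @export
residuals.cline_fit <- function(object, type = c("pearson", "response"),
                                ...) {
  type <- match.arg(type)
  p <- predict(object)
  obs <- object$obs
  r <- obs$k / obs$n - p
  if (type == "pearson") r / sqrt(p * (1 - p) / obs$n)
  else r
}

#' @export
simulate.cline_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  obs <- object$obs
  p <- predict(object)
  out <- as.data.frame(replicate(nsim,
    stats::rbinom(nrow(obs), obs$n, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "position") <- obs$position
  out
}

#' @export
summary.cline_fit <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients, object$support)
  structure(list(loci = object$loci, table = tab, loglik = object$loglik,
                 nobs = object$nobs,
                 slope_at_center = 1 / object$coefficients[["width"]]),
            class = "summary.cline_fit")
}

#' @export
print.summary.cline_fit <- function(x, ...) {
  cat("Tanh cline fit (", paste(x$loci, collapse = ", "), ")\n", sep = "")
  print(round(x$table, 4))
  cat(sprintf("Maximum slope (at center): %.4f per km\n",
              x$slope_at_center))
  cat(sprintf("logLik %.3f on %d observations\n", x$loglik, x$nobs))
  invisible(x)
}

#' Plot a fitted cline over binned observed frequencies
#'
#' @param x a `cline_fit`.
#' @param bins number of position bins for the observed frequencies.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cline_fit <- function(x, bins = 15, ...) {
  obs <- x$obs
  br <- seq(min(obs$position), max(obs$position), length.out = bins + 1)
  cut_i <- cut(obs$position, br, include.lowest = TRUE)
  pf <- tapply(obs$k, cut_i, sum) / tapply(obs$n, cut_i, sum)
  mid <- (br[-1] + br[-length(br)]) / 2
  graphics::plot(mid, pf, xlab = "transect position (km)",
                 ylab = "K-allele frequency", ylim = c(0, 1), ...)
  xs <- seq(min(obs$position), max(obs$position), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  graphics::abline(v = x$coefficients["center"], lty = 3)
  invisible(x)
}
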