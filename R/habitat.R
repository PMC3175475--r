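#' Genotype-class by vegetation association test
#'
#' Pearson chi-square test (no continuity correction) of independence
#' between per-individual class labels and vegetation series, on the
#' contingency table after dropping missing values.
#'
#' @param classes per-individual class labels.
#' @param vegetation per-individual vegetation labels.
#' @return list with `statistic`, `df`, `p`, the `table` and the
#'   `expected` counts (a warning is raised when any expected count is
#'   below 5).
#' @export
habitat_association_test <- function(classes, vegetation) {
  ok <- !is.na(classes) & !is.na(vegetation)
  tab <- table(class = classes[ok], vegetation = vegetation[ok])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 levels on each margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("expected count below 5; chi-square approximation is rough")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, expected = expected)
}

# Shared-cline negative log-likelihood with a per-observation centre
# shift z * delta (z = covariate value attached to each observation).
.habitat_nll <- function(obs, z) {
  function(par) {
    p <- clamp(tanh_p(obs$position, par[1] + par[3] * z, exp(par[2])),
               1e-12, 1 - 1e-12)
    -binom_ll(obs$k, obs$n, p)
  }
}

#' Habitat-and-cline versus cline-only model comparison
#'
#' The cline-only model is the tanh cline with centre and width shared
#' across the chosen loci.  The habitat-and-cline model lets the centre
#' shift with the covariate: `c + delta * 1[veg = MWP]` for vegetation, or
#' `c + gamma * (elevation - mean elevation)` for elevation (units km per
#' metre).  Both models are fitted by ML on the same individuals and
#' compared with a 1-df likelihood-ratio test; the richer model is
#' accepted only on a significant likelihood increase.
#'
#' @param projected a `projected_dataset`.
#' @param covariate `"vegetation"` or `"elevation"`.
#' @param loci loci to pool (default: all).
#' @param min_coverage minimum fraction of individuals with the covariate
#'   scored; others are dropped with a warning.
#' @return An object of class `habitat_cline_fit` with both fits and the
#'   LRT (`G`, `df`, `p`).
#' @export
fit_habitat_cline <- function(projected,
                              covariate = c("vegetation", "elevation"),
                              loci = NULL, min_coverage = 0.9) {
  covariate <- match.arg(covariate)
  dataset <- projected$base
  ind <- dataset$individuals
  cv <- if (covariate == "vegetation") ind$vegetation else ind$elevation
  have <- !is.na(cv)
  if (mean(have) < min_coverage)
    stop("covariate scored for under ", round(100 * min_coverage),
         "% of individuals")
  if (any(!have))
    warning("dropping ", sum(!have),
            " individual(s) with missing covariate")
  if (length(unique(cv[have])) < 2)
    stop("covariate is constant; habitat effect unidentifiable")
  sub <- dataset
  sub$individuals <- ind[have, , drop = FALSE]
  proj_sub <- projected
  proj_sub$base <- sub
  proj_sub$position <- projected$position[have]
  z_ind <- if (covariate == "vegetation")
    as.numeric(sub$individuals$vegetation == "MWP")
  else sub$individuals$elevation - mean(sub$individuals$elevation)
  # observations with the covariate value attached to each row
  all_loci <- loci %||% dataset$loci$name
  obs_list <- lapply(all_loci, function(l) {
    ob <- .locus_obs(sub, l)
    if (!sum(ob$keep)) return(NULL)
    data.frame(position = proj_sub$position[ob$keep], k = ob$k, n = ob$n,
               z = z_ind[ob$keep], locus = l, stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, obs_list)
  base_fit <- .fit_tanh(obs)
  nll <- .habitat_nll(obs, obs$z)
  z_scale <- stats::sd(obs$z)
  fit <- stats::optim(c(base_fit$center, log(base_fit$width), 0), nll,
                      method = "L-BFGS-B",
                      lower = c(base_fit$bounds$c[1],
                                log(base_fit$bounds$w[1]),
                                -10 / z_scale),
                      upper = c(base_fit$bounds$c[2],
                                log(base_fit$bounds$w[2]),
                                10 / z_scale),
                      control = list(factr = 1e4))
  ll_hab <- -fit$value
  G <- 2 * (ll_hab - base_fit$loglik)
  eff_name <- if (covariate == "vegetation") "delta" else "gamma"
  structure(list(covariate = covariate,
                 cline_only = c(center = base_fit$center,
                                width = base_fit$width,
                                loglik = base_fit$loglik),
                 habitat = stats::setNames(
                   c(fit$par[1], exp(fit$par[2]), fit$par[3], ll_hab),
                   c("center", "width", eff_name, "loglik")),
                 G = G, df = 1,
                 p = stats::pchisq(max(G, 0), 1, lower.tail = FALSE),
                 n_dropped = sum(!have)),
            class = "habitat_cline_fit")
}

#' @export
print.habitat_cline_fit <- function(x, ...) {
  cat("Habitat-and-cline vs cline-only (covariate: ", x$covariate,
      ")\n", sep = "")
  cat(sprintf("  cline only:        logLik %.3f\n",
              x$cline_only["loglik"]))
  cat(sprintf("  habitat-and-cline: logLik %.3f (effect %s = %.4g)\n",
              x$habitat["loglik"], names(x$habitat)[3], x$habitat[3]))
  cat(sprintf("  G = %.3f (df 1), p = %.4g -> %s\n", x$G, x$p,
              if (x$p < 0.05) "habitat model preferred"
              else "no significant improvement"))
  invisible(x)
}

#' Per-class elevation summary with one-way ANOVA
#'
#' @param dataset a [genotype_dataset()].
#' @param classes per-individual class labels (default: the `phenotype`
#'   column).
#' @return list with a per-class `summary` data.frame (n, mean, min,
#'   max), the omnibus `F`, `df` and `p`, and the count of individuals
#'   dropped for missing data.
#' @export
elevation_summary <- function(dataset, classes = NULL) {
  classes <- classes %||% dataset$individuals$phenotype
  elev <- dataset$individuals$elevation
  ok <- !is.na(classes) & !is.na(elev)
  n_dropped <- sum(!ok)
  if (n_dropped)
    message(n_dropped, " individual(s) dropped for missing data")
  cl <- factor(classes[ok])
  ev <- elev[ok]
  smry <- do.call(rbind, lapply(levels(cl), function(lv) {
    e <- ev[cl == lv]
    data.frame(class = lv, n = length(e), mean = mean(e),
               min = min(e), max = max(e), stringsAsFactors = FALSE)
  }))
  Fv <- df1 <- df2 <- p <- NA_real_
  if (nlevels(cl) >= 2 && all(table(cl) >= 2)) {
    a <- stats::anova(stats::aov(ev ~ cl))
    Fv <- a$`F value`[1]
    df1 <- a$Df[1]
    df2 <- a$Df[2]
    p <- a$`Pr(>F)`[1]
  }
  list(summary = smry, F = Fv, df = c(df1, df2), p = p,
       n_dropped = n_dropped)
}
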