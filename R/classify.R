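#' Threshold classification from an admixture proportion
#'
#' Calls an individual a pure parental or a hybrid from its admixture
#' proportion `q` (fraction of K ancestry).  The default thresholds are
#' the conventional printed pair (0.1, 0.9); `mode = "formula"` instead
#' uses the midpoint rule for `L` diploid diagnostic loci, for which the
#' possible ancestry fractions are `0, 1/(2L+1), ..., 1` once the
#' mitochondrial copy is included: `lower = (0 + 1/(2L+1))/2`,
#' `upper = (1 + 2L/(2L+1))/2` (for `L = 3`: 1/14 and 13/14).
#'
#' @param q admixture proportion(s) in `[0, 1]`.
#' @param n_diagnostic_loci number of diploid diagnostic loci `L`.
#' @param mode `"printed"` (0.1 / 0.9) or `"formula"`.
#' @return list with `class` (`"pure_E"`, `"hybrid"`, `"pure_K"` per
#'   element of `q`), and the thresholds `lower`, `upper`, `mode` used.
#' @export
classify_by_q <- function(q, n_diagnostic_loci = 3,
                          mode = c("printed", "formula")) {
  mode <- match.arg(mode)
  stopifnot(n_diagnostic_loci >= 1)
  if (any(is.na(q)) || any(q < 0 | q > 1))
    stop("q must lie in [0, 1]")
  if (mode == "printed") {
    lower <- 0.1
    upper <- 0.9
  } else {
    L <- n_diagnostic_loci
    lower <- (0 + 1 / (2 * L + 1)) / 2
    upper <- (1 + 2 * L / (2 * L + 1)) / 2
  }
  cls <- ifelse(q < lower, "pure_E", ifelse(q > upper, "pure_K", "hybrid"))
  list(class = cls, lower = lower, upper = upper, mode = mode)
}

.GENO_CLASSES <- c("pure_E", "pure_K", "F1", "F2", "BC_E", "BC_K")

# P(K-copies = 0, 1, 2) at a diagnostic locus under each class.
.CLASS_GENO_PROBS <- rbind(
  pure_E = c(1, 0, 0),
  pure_K = c(0, 0, 1),
  F1 = c(0, 1, 0),
  F2 = c(0.25, 0.5, 0.25),
  BC_E = c(0.5, 0.5, 0),
  BC_K = c(0, 0.5, 0.5))

#' Closed-form genotype-frequency-class posterior at diagnostic loci
#'
#' For fully diagnostic markers the expected genotype frequencies of the
#' six early-generation classes (two parentals, F1, F2, two backcrosses)
#' are known exactly, so the class posterior of a multilocus genotype is a
#' product over scored loci times the prior, normalised.  Classes
#' assigning zero likelihood get posterior exactly 0.  This is a
#' closed-form classifier for diagnostic loci, not an admixture sampler;
#' it is only valid when both parental taxa are fixed for different
#' alleles at every locus used.
#'
#' @param k_counts per-locus K-allele counts (0, 1, 2 or `NA`).
#' @param prior prior over the six classes in the order `pure_E`,
#'   `pure_K`, `F1`, `F2`, `BC_E`, `BC_K`; must sum to 1.
#' @return An object of class `class_posterior`: named probability vector
#'   with attribute `loci_used`.
#' @export
genotype_class_posterior <- function(k_counts,
                                     prior = rep(1 / 6, 6)) {
  stopifnot(length(prior) == 6, abs(sum(prior) - 1) < 1e-9)
  scored <- which(!is.na(k_counts))
  if (!length(scored)) stop("all loci missing; cannot classify")
  stopifnot(all(k_counts[scored] %in% 0:2))
  lik <- rep(1, 6)
  for (i in scored)
    lik <- lik * .CLASS_GENO_PROBS[, k_counts[i] + 1]
  post <- lik * prior
  if (sum(post) == 0)
    stop("genotype impossible under every class")
  post <- post / sum(post)
  names(post) <- .GENO_CLASSES
  structure(post, loci_used = length(scored), class = "class_posterior")
}

#' @export
print.class_posterior <- function(x, ...) {
  cat("Genotype-frequency-class posterior (", attr(x, "loci_used"),
      " loci):\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Classify every individual of a dataset
#'
#' Applies [classify_by_q()] (with `q` taken from the nuclear hybrid index
#' or from the externally supplied classification column) and
#' [genotype_class_posterior()] to each individual.
#'
#' @param dataset a [genotype_dataset()].
#' @param q_source `"hybrid-index"` (nuclear-locus hybrid index as the
#'   admixture proxy; the choice is logged) or `"column"` (numeric
#'   `external_class` column).
#' @param mode threshold mode passed to [classify_by_q()].
#' @param prior class prior passed to [genotype_class_posterior()].
#' @return data.frame with `id`, `q`, `class_q`, the six posterior
#'   columns, and the MAP class `class_map`.
#' @export
classify_dataset <- function(dataset,
                             q_source = c("hybrid-index", "column"),
                             mode = c("printed", "formula"),
                             prior = rep(1 / 6, 6)) {
  q_source <- match.arg(q_source)
  mode <- match.arg(mode)
  nuc <- nuclear_loci(dataset)
  if (q_source == "hybrid-index") {
    message("using the nuclear hybrid index as the admixture proportion")
    q <- hybrid_index(dataset, nuc)$HI
  } else {
    q <- suppressWarnings(as.numeric(dataset$individuals$external_class))
    if (all(is.na(q)))
      stop("external_class column is not numeric; cannot use as q")
  }
  kmat <- k_counts(dataset, nuc)
  cls_q <- rep(NA_character_, nrow(kmat))
  okq <- !is.na(q)
  thr <- classify_by_q(q[okq], length(nuc), mode)
  cls_q[okq] <- thr$class
  post <- t(apply(kmat, 1, function(kk) {
    if (all(is.na(kk))) rep(NA_real_, 6)
    else as.numeric(genotype_class_posterior(kk, prior))
  }))
  colnames(post) <- .GENO_CLASSES
  map <- apply(post, 1, function(p)
    if (all(is.na(p))) NA_character_ else .GENO_CLASSES[which.max(p)])
  out <- data.frame(id = dataset$individuals$id, q = q, class_q = cls_q,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(post), class_map = map,
        stringsAsFactors = FALSE)
}
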