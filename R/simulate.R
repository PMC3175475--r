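#' Configuration for the synthetic hybrid-zone generator
#'
#' The defaults emulate a salamander contact zone of the kind the package
#' targets: 335 individuals on a 3.5 x 1.75 km strip crossed obliquely by
#' the zone (compass heading 207 degrees), three diploid diagnostic nuclear
#' loci plus one haploid mitochondrial marker with tanh allele-frequency
#' clines 0.72-0.80 km wide, a mitochondrial centre offset of 0.105 km
#' toward the E flank, dispersal of unrecombined parentals into the zone
#' concentrated on the E flank (the source of heterozygote deficit and of
#' inter-locus and cytonuclear disequilibrium), strongly asymmetric
#' mitochondrial inheritance in admixed individuals, and a vegetation
#' boundary and elevation gradient confounded with transect position.
#'
#' @param n number of individuals.
#' @param strip strip extent `c(length_km, width_km)`; the length axis runs
#'   along the cline (K-allele frequency increases along it).
#' @param heading_true compass heading (degrees) of the cline axis.
#' @param origin `c(lat, lon)` of the strip centre, used to emit
#'   geographic coordinates.
#' @param loci character vector of nuclear locus names.
#' @param mito mitochondrial locus name, or `NULL` to omit the marker.
#' @param center_per_locus named numeric: tanh cline centre (km, relative
#'   to the strip centre) for each nuclear locus and the mito marker.
#' @param width_per_locus named numeric: tanh cline width (km), same names.
#' @param mix_amplitude peak probability that an individual is drawn as an
#'   unrecombined parental (all loci jointly KK.../K or EE.../E).
#' @param mix_scale km; Laplacian decay scale of that probability with
#'   distance from `mix_center`.
#' @param mix_center km; where parental mixing peaks (defaults to the E
#'   flank so disequilibrium concentrates there).
#' @param mt_asymmetry probability that an admixed individual (one carrying
#'   both E and K nuclear alleles) carries the K mitotype regardless of
#'   position; with probability `1 - mt_asymmetry` its mitotype follows the
#'   mitochondrial cline.
#' @param veg_boundary km position of the MMW/MWP vegetation transition.
#' @param veg_blur km; logistic blur scale of that transition.
#' @param elev_base mean elevation (m) at the strip centre.
#' @param elev_slope elevation trend (m per km of transect position).
#' @param elev_noise_sd Gaussian elevation noise (m).
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n = 335,
                       strip = c(3.5, 1.75),
                       heading_true = 207,
                       origin = c(33.34, -116.90),
                       loci = c("CXCR4", "SLC8A3", "RAG1"),
                       mito = "ND4",
                       center_per_locus = NULL,
                       width_per_locus = NULL,
                       mix_amplitude = 0.6,
                       mix_scale = 0.5,
                       mix_center = -0.2,
                       mt_asymmetry = 0.9,
                       veg_boundary = 0,
                       veg_blur = 0.3,
                       elev_base = 1420,
                       elev_slope = 50,
                       elev_noise_sd = 60,
                       seed = 1L) {
  all_loci <- c(loci, mito)
  if (is.null(center_per_locus)) {
    center_per_locus <- stats::setNames(rep(0, length(loci)), loci)
    if (!is.null(mito)) center_per_locus[mito] <- -0.105
  }
  if (is.null(width_per_locus)) {
    width_per_locus <- stats::setNames(
      rep_len(c(0.770, 0.799, 0.725), length(loci)), loci)
    if (!is.null(mito)) width_per_locus[mito] <- 0.718
  }
  stopifnot(n >= 1, length(strip) == 2, all(strip > 0),
            all(width_per_locus > 0),
            mix_amplitude >= 0, mix_amplitude <= 1,
            mix_scale > 0,
            mt_asymmetry >= 0, mt_asymmetry <= 1,
            all(all_loci %in% names(center_per_locus)),
            all(all_loci %in% names(width_per_locus)))
  structure(list(n = as.integer(n), strip = strip,
                 heading_true = heading_true %% 360, origin = origin,
                 loci = loci, mito = mito,
                 center_per_locus = center_per_locus,
                 width_per_locus = width_per_locus,
                 mix_amplitude = mix_amplitude, mix_scale = mix_scale,
                 mix_center = mix_center, mt_asymmetry = mt_asymmetry,
                 veg_boundary = veg_boundary, veg_blur = veg_blur,
                 elev_base = elev_base, elev_slope = elev_slope,
                 elev_noise_sd = elev_noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw the genotype fields of one individual at a transect position
#'
#' With probability `m(x) = mix_amplitude * exp(-|x - mix_center| /
#' mix_scale)` the individual is an unrecombined parental: all nuclear loci
#' and the mitotype are jointly K-type with probability `p(x)` of the first
#' nuclear cline, otherwise jointly E-type.  This is the tension-zone
#' ingredient that injects heterozygote deficit, inter-locus disequilibrium
#' and cytonuclear disequilibrium simultaneously.  Otherwise every allele
#' copy is drawn independently from its locus's tanh cline (Hardy-Weinberg
#' and linkage equilibrium), and an admixed result (carrying both E and K
#' nuclear alleles) gets the K mitotype with probability `mt_asymmetry`
#' instead of its clinal mitotype.
#'
#' @param x transect position (km, relative to the strip centre).
#' @param cfg a [sim_config()].
#' @return list with `k` (named K-allele counts), `mito` (`"E"`/`"K"` or
#'   `NA` if the config has no mito marker) and `parental_draw` (logical).
#' @export
sample_genotype_at <- function(x, cfg) {
  p_of <- function(l) tanh_p(x, cfg$center_per_locus[[l]],
                             cfg$width_per_locus[[l]])
  m <- cfg$mix_amplitude * exp(-abs(x - cfg$mix_center) / cfg$mix_scale)
  parental <- stats::runif(1) < m
  if (parental) {
    k_type <- stats::runif(1) < p_of(cfg$loci[1])
    k <- stats::setNames(rep(if (k_type) 2L else 0L, length(cfg$loci)),
                         cfg$loci)
    mito <- if (is.null(cfg$mito)) NA_character_ else
      if (k_type) "K" else "E"
  } else {
    k <- vapply(cfg$loci,
                function(l) stats::rbinom(1, 2, p_of(l)), integer(1))
    admixed <- any(k > 0) && any(k < 2)
    mito <- if (is.null(cfg$mito)) NA_character_ else {
      if (admixed && stats::runif(1) < cfg$mt_asymmetry) "K"
      else if (stats::runif(1) < p_of(cfg$mito)) "K" else "E"
    }
  }
  list(k = k, mito = mito, parental_draw = parental)
}

#' Simulate a hybrid-zone genotype dataset
#'
#' Individuals are placed uniformly on the strip, genotypes drawn with
#' [sample_genotype_at()], habitat covariates derived from transect
#' position, and planar coordinates rotated to the configured heading and
#' inverted to latitude/longitude.  Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_dataset()] whose `individuals` table also carries
#'   the hidden truth columns `true_x` (transect position, km) and
#'   `parental_draw`.
#' @export
simulate_zone <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n
    x <- stats::runif(n, -cfg$strip[1] / 2, cfg$strip[1] / 2)
    y <- stats::runif(n, -cfg$strip[2] / 2, cfg$strip[2] / 2)
    draws <- lapply(x, sample_genotype_at, cfg = cfg)
    kmat <- do.call(rbind, lapply(draws, function(d) d$k))
    mito <- vapply(draws, function(d) d$mito, character(1))
    parental <- vapply(draws, function(d) d$parental_draw, logical(1))
    # planar frame: cline axis unit vector (sin th, cos th), perp (cos, -sin)
    th <- .deg2rad(cfg$heading_true)
    east <- x * sin(th) + y * cos(th)
    north <- x * cos(th) - y * sin(th)
    ll <- latlon_from_planar(east, north, cfg$origin[1], cfg$origin[2])
    p_mwp <- stats::plogis((x - cfg$veg_boundary) / cfg$veg_blur)
    vegetation <- ifelse(stats::runif(n) < p_mwp, "MWP", "MMW")
    elevation <- cfg$elev_base + cfg$elev_slope * x +
      stats::rnorm(n, 0, cfg$elev_noise_sd)
    n_k <- rowSums(kmat)
    phenotype <- ifelse(n_k == 0, "eschscholtzii",
                        ifelse(n_k == 2 * length(cfg$loci), "klauberi",
                               "hybrid"))
    ind <- data.frame(id = sprintf("sim%04d", seq_len(n)),
                      lat = ll[, "lat"], lon = ll[, "lon"],
                      elevation = elevation, vegetation = vegetation,
                      phenotype = phenotype,
                      external_class = NA_character_, mito = mito,
                      stringsAsFactors = FALSE)
    for (l in cfg$loci) ind[[paste0("k_", l)]] <- as.integer(kmat[, l])
    ind$true_x <- x
    ind$parental_draw <- parental
    loci <- data.frame(
      name = c(cfg$loci, cfg$mito),
      ploidy = c(rep(2L, length(cfg$loci)), if (!is.null(cfg$mito)) 1L),
      role = c(rep("nuclear", length(cfg$loci)),
               if (!is.null(cfg$mito)) "mitochondrial"),
      stringsAsFactors = FALSE)
    genotype_dataset(loci, ind,
                     provenance = sprintf("simulate_zone(seed=%d)",
                                          cfg$seed))
  })
}
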