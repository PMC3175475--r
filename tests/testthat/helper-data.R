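# Small in-code fixtures shared across tests.

make_loci <- function(nuclear = c("A", "B", "C"), mito = "MT") {
  data.frame(name = c(nuclear, mito),
             ploidy = c(rep(2L, length(nuclear)), if (!is.null(mito)) 1L),
             role = c(rep("nuclear", length(nuclear)),
                      if (!is.null(mito)) "mitochondrial"),
             stringsAsFactors = FALSE)
}

make_dataset <- function(k, mito = NULL, lat = NULL, lon = NULL,
                         elevation = NULL, vegetation = NULL,
                         phenotype = NULL, nuclear = NULL) {
  k <- as.matrix(k)
  n <- nrow(k)
  nuclear <- nuclear %||% LETTERS[seq_len(ncol(k))]
  colnames(k) <- nuclear
  ind <- data.frame(id = sprintf("i%03d", seq_len(n)),
                    lat = lat %||% rep(33, n),
                    lon = lon %||% rep(-116, n),
                    elevation = elevation %||% rep(1400, n),
                    vegetation = vegetation %||% rep("MMW", n),
                    phenotype = phenotype %||% rep("hybrid", n),
                    external_class = NA_character_,
                    mito = if (is.null(mito)) NA_character_ else mito,
                    stringsAsFactors = FALSE)
  for (l in nuclear) ind[[paste0("k_", l)]] <- k[, l]
  genotype_dataset(make_loci(nuclear,
                             if (is.null(mito)) NULL else "MT"), ind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Binomial observations drawn from an exact tanh cline (HWE).
obs_from_cline <- function(n_ind, center, width, seed,
                           span = c(-1.75, 1.75), ploidy = 2) {
  set.seed(seed)
  x <- runif(n_ind, span[1], span[2])
  p <- (1 + tanh(2 * (x - center) / width)) / 2
  data.frame(position = x, k = rbinom(n_ind, ploidy, p),
             n = ploidy)
}
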