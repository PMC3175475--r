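# Internal helpers shared across modules.

# Mean earth radius (km), IUGG value; adequate for study areas of a few km.
.R_EARTH <- 6371.0088

.deg2rad <- function(x) x * pi / 180

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Binomial log-likelihood with the 0*log(0) := 0 convention and the
# binomial coefficient omitted (parameter-free, so irrelevant to ML).
binom_ll <- function(k, n, p) {
  t1 <- ifelse(k > 0, k * log(p), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log(1 - p), 0)
  sum(t1 + t2)
}

# Equirectangular local planar projection around (lat0, lon0), in km.
planar_from_latlon <- function(lat, lon, lat0, lon0) {
  east <- .R_EARTH * cos(.deg2rad(lat0)) * .deg2rad(lon - lon0)
  north <- .R_EARTH * .deg2rad(lat - lat0)
  cbind(east = east, north = north)
}

latlon_from_planar <- function(east, north, lat0, lon0) {
  lat <- lat0 + north / .R_EARTH * 180 / pi
  lon <- lon0 + east / (.R_EARTH * cos(.deg2rad(lat0))) * 180 / pi
  cbind(lat = lat, lon = lon)
}

# Run expr with the RNG seeded, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
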