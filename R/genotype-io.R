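#' Construct a genotype dataset
#'
#' Bundles a locus table and an individual table into the container used by
#' every analysis in the package.  Nuclear diploid genotypes at diagnostic
#' markers are stored as counts of "K" (klauberi-type) alleles (0, 1, 2 or
#' `NA`); the single haploid mitochondrial marker is stored as `"E"`, `"K"`
#' or `NA`.
#'
#' @param loci data.frame with columns `name`, `ploidy` (1 or 2) and `role`
#'   (`"nuclear"` or `"mitochondrial"`).
#' @param individuals data.frame with columns `id`, `lat`, `lon`,
#'   `elevation`, `vegetation`, `phenotype`, `external_class`, `mito`, and
#'   one `k_<locus>` column per nuclear locus.
#' @param provenance free-text metadata string.
#' @param elevation_range plausible elevation range in metres; values
#'   outside it raise an error.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(loci, individuals, provenance = "",
                             elevation_range = c(0, 5000)) {
  stopifnot(is.data.frame(loci), is.data.frame(individuals))
  loci$name <- as.character(loci$name)
  if (anyDuplicated(loci$name))
    stop("locus names must be unique")
  if (!all(loci$role %in% c("nuclear", "mitochondrial")))
    stop("locus role must be 'nuclear' or 'mitochondrial'")
  bad <- (loci$role == "mitochondrial" & loci$ploidy != 1) |
    (loci$role == "nuclear" & loci$ploidy != 2)
  if (any(bad))
    stop("mitochondrial loci must have ploidy 1, nuclear loci ploidy 2")
  if (sum(loci$role == "nuclear") < 1)
    stop("at least one nuclear locus required")
  if (sum(loci$role == "mitochondrial") > 1)
    stop("at most one mitochondrial locus allowed")
  if (anyDuplicated(individuals$id))
    stop("duplicate individual id: ",
         paste(unique(individuals$id[duplicated(individuals$id)]),
               collapse = ", "))
  nuc <- loci$name[loci$role == "nuclear"]
  kcols <- paste0("k_", nuc)
  missing_cols <- setdiff(kcols, names(individuals))
  if (length(missing_cols))
    stop("individuals table lacks genotype column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cc in kcols) {
    v <- individuals[[cc]]
    if (!all(is.na(v) | v %in% 0:2))
      stop("K-allele counts must be 0, 1, 2 or NA (column ", cc, ")")
  }
  if (any(loci$role == "mitochondrial")) {
    if (!all(is.na(individuals$mito) | individuals$mito %in% c("E", "K")))
      stop("mito haplotypes must be 'E', 'K' or NA")
  }
  ev <- individuals$elevation
  if (any(!is.na(ev) & (ev < elevation_range[1] | ev > elevation_range[2])))
    stop("elevation outside plausible range [", elevation_range[1], ", ",
         elevation_range[2], "] m")
  structure(list(loci = loci, individuals = individuals,
                 provenance = provenance),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  nuc <- nuclear_loci(x)
  mt <- mito_locus(x)
  cat("Genotype dataset: ", nrow(x$individuals), " individuals, ",
      length(nuc), " nuclear loci (", paste(nuc, collapse = ", "), ")",
      if (length(mt)) paste0(" + ", mt, " (mtDNA)"), "\n", sep = "")
  if (nzchar(x$provenance)) cat("Provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Names of the nuclear loci of a dataset
#' @param x a `genotype_dataset`.
#' @return character vector.
#' @export
nuclear_loci <- function(x) x$loci$name[x$loci$role == "nuclear"]

#' Name of the mitochondrial locus (length 0 if absent)
#' @param x a `genotype_dataset`.
#' @return character vector of length 0 or 1.
#' @export
mito_locus <- function(x) x$loci$name[x$loci$role == "mitochondrial"]

#' Matrix of K-allele counts at nuclear loci
#' @param x a `genotype_dataset`.
#' @param loci optional subset of nuclear locus names.
#' @return integer matrix, individuals by loci.
#' @export
k_counts <- function(x, loci = NULL) {
  loci <- loci %||% nuclear_loci(x)
  m <- as.matrix(x$individuals[paste0("k_", loci)])
  colnames(m) <- loci
  rownames(m) <- x$individuals$id
  m
}

#' Default column-mapping schema for the individual table
#'
#' The on-disk layout is one row per individual with two allele columns per
#' nuclear locus (suffix `_1`, `_2`) and a single haplotype column for the
#' mitochondrial marker.  Alleles are coded `E`/`K`; `-9` marks missing
#' data.  Adapt the returned list (or a JSON file with the same structure)
#' when reading tables with other column names.
#'
#' @param nuclear character vector of nuclear locus names.
#' @param mito mitochondrial locus name, or `NULL` for none.
#' @return A schema list understood by [read_genotypes()].
#' @export
default_schema <- function(nuclear = c("CXCR4", "SLC8A3", "RAG1"),
                           mito = "ND4") {
  loci <- lapply(nuclear, function(l) paste0(l, c("_1", "_2")))
  names(loci) <- nuclear
  list(id = "id", lat = "latitude", lon = "longitude",
       elevation = "elevation", vegetation = "vegetation",
       phenotype = "phenotype", external_class = "external_class",
       mito = mito, mito_locus = mito %||% character(0), loci = loci)
}

.recode_allele <- function(a) {
  a <- toupper(trimws(as.character(a)))
  a[a %in% c("-9", "NA", "")] <- NA
  a
}

#' Read a per-individual genotype/covariate table
#'
#' Reads a tab-separated table (header required, `.` decimal point) with one
#' row per individual, collapses each pair of nuclear allele columns to a
#' K-allele count, and validates the result.  Any allele coded `-9`, or any
#' allele code other than `E`/`K` (case-insensitive), makes that locus
#' missing for that individual; unexpected codes are additionally reported
#' with a warning, mirroring the exclusion of unassignable haplotypes.
#'
#' @param path path to the TSV file.
#' @param schema column-mapping list as returned by [default_schema()], or
#'   the path to a JSON file encoding the same structure.
#' @param provenance free-text metadata attached to the dataset.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, schema = default_schema(),
                           provenance = path) {
  if (is.character(schema) && length(schema) == 1)
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", dec = ".",
                           stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""))
  mandatory <- c(schema$id, schema$lat, schema$lon, schema$elevation,
                 schema$vegetation, schema$phenotype,
                 unlist(schema$loci, use.names = FALSE))
  if (!is.null(schema$mito) && length(schema$mito))
    mandatory <- c(mandatory, schema$mito)
  absent <- setdiff(mandatory, names(tab))
  if (length(absent))
    stop("input table lacks mandatory column(s): ",
         paste(absent, collapse = ", "))
  id <- as.character(tab[[schema$id]])
  if (anyDuplicated(id))
    stop("duplicate individual id: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  num_or_die <- function(col, what) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- is.na(v) & !is.na(tab[[col]]) & tab[[col]] != -9
    if (what %in% c("latitude", "longitude") && any(is.na(v) | bad))
      stop("non-numeric or missing ", what, " for individual(s): ",
           paste(id[is.na(v) | bad], collapse = ", "))
    v[tab[[col]] == -9] <- NA
    v
  }
  lat <- num_or_die(schema$lat, "latitude")
  lon <- num_or_die(schema$lon, "longitude")
  elevation <- num_or_die(schema$elevation, "elevation")
  lab <- function(col, allowed) {
    v <- as.character(tab[[col]])
    v[v %in% c("-9", "")] <- NA
    if (!is.null(allowed)) v[!is.na(v) & !(v %in% allowed)] <- NA
    v
  }
  vegetation <- lab(schema$vegetation, c("MMW", "MWP"))
  phenotype <- lab(schema$phenotype,
                   c("eschscholtzii", "klauberi", "hybrid"))
  external_class <- if (!is.null(schema$external_class) &&
                        schema$external_class %in% names(tab))
    lab(schema$external_class, NULL) else rep(NA_character_, nrow(tab))
  loci_names <- names(schema$loci)
  kc <- matrix(NA_integer_, nrow(tab), length(loci_names),
               dimnames = list(NULL, loci_names))
  odd <- character(0)
  for (l in loci_names) {
    a1 <- .recode_allele(tab[[schema$loci[[l]][1]]])
    a2 <- .recode_allele(tab[[schema$loci[[l]][2]]])
    strange <- c(a1[!is.na(a1) & !(a1 %in% c("E", "K"))],
                 a2[!is.na(a2) & !(a2 %in% c("E", "K"))])
    if (length(strange)) odd <- c(odd, paste0(l, ":", unique(strange)))
    ok <- !is.na(a1) & !is.na(a2) & a1 %in% c("E", "K") & a2 %in% c("E", "K")
    kc[ok, l] <- (a1[ok] == "K") + (a2[ok] == "K")
  }
  if (length(odd))
    warning("unassignable allele code(s) coerced to missing: ",
            paste(unique(odd), collapse = ", "))
  mito <- if (!is.null(schema$mito) && length(schema$mito)) {
    m <- .recode_allele(tab[[schema$mito]])
    m[!is.na(m) & !(m %in% c("E", "K"))] <- NA
    m
  } else rep(NA_character_, nrow(tab))
  ind <- data.frame(id = id, lat = lat, lon = lon, elevation = elevation,
                    vegetation = vegetation, phenotype = phenotype,
                    external_class = external_class, mito = mito,
                    stringsAsFactors = FALSE)
  for (l in loci_names) ind[[paste0("k_", l)]] <- kc[, l]
  mt_name <- if (!is.null(schema$mito) && length(schema$mito))
    schema$mito else NULL
  loci <- data.frame(
    name = c(loci_names, mt_name),
    ploidy = c(rep(2L, length(loci_names)), if (!is.null(mt_name)) 1L),
    role = c(rep("nuclear", length(loci_names)),
             if (!is.null(mt_name)) "mitochondrial"),
    stringsAsFactors = FALSE)
  genotype_dataset(loci, ind, provenance = provenance)
}

#' Write a genotype dataset as a TSV table
#'
#' Inverse of [read_genotypes()] under the default schema: K-allele counts
#' are expanded back to allele pairs (`0 -> E/E`, `1 -> E/K`, `2 -> K/K`),
#' missing values are written as `-9`.
#'
#' @param x a `genotype_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  ind <- x$individuals
  out <- data.frame(id = ind$id, latitude = ind$lat, longitude = ind$lon,
                    elevation = ifelse(is.na(ind$elevation), -9,
                                       ind$elevation),
                    vegetation = ifelse(is.na(ind$vegetation), "-9",
                                        ind$vegetation),
                    phenotype = ifelse(is.na(ind$phenotype), "-9",
                                       ind$phenotype),
                    external_class = ifelse(is.na(ind$external_class), "-9",
                                            ind$external_class),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (l in nuclear_loci(x)) {
    k <- ind[[paste0("k_", l)]]
    out[[paste0(l, "_1")]] <- ifelse(is.na(k), "-9",
                                     ifelse(k >= 1, "K", "E"))
    out[[paste0(l, "_2")]] <- ifelse(is.na(k), "-9",
                                     ifelse(k == 2, "K", "E"))
  }
  mt <- mito_locus(x)
  if (length(mt))
    out[[mt]] <- ifelse(is.na(ind$mito), "-9", ind$mito)
  .write_tsv(out, path)
  invisible(path)
}

# Full-precision TSV writer: doubles are written with %.17g so that a
# read-back reproduces them bit for bit.
.write_tsv <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]]))
      fmt[[j]] <- ifelse(is.na(fmt[[j]]), "NA", sprintf("%.17g", fmt[[j]]))
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write a result record set to disk
#'
#' @param results a non-empty data.frame (rows are records) or a non-empty
#'   named list (JSON only).
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if ((is.data.frame(results) && nrow(results) == 0) ||
      (!is.data.frame(results) && length(results) == 0))
    stop("refusing to write an empty result set")
  if (format == "tsv") {
    if (!is.data.frame(results))
      results <- as.data.frame(results, stringsAsFactors = FALSE)
    .write_tsv(results, path)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
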