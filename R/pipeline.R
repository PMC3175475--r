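#' Run the full hybrid-zone analysis end to end
#'
#' Orchestrates the complete pipeline on either an input genotype table or
#' a simulated dataset: transect orientation, per-locus and shared tanh
#' cline fits, coincidence/concordance likelihood-ratio tests, Barton's
#' concordance fits, the sliding-window disequilibrium scan, hybrid
#' classification, and the habitat analyses.  Every stage's result is
#' written to `out_dir` together with a machine-readable manifest; a stage
#' failure aborts with the stage name while preserving completed outputs.
#' The run is a pure function of its inputs and `seed`.
#'
#' @param input path to a genotype TSV (read with `schema`), or `NULL`.
#' @param sim a [sim_config()], or `NULL`.  Exactly one of `input`/`sim`
#'   must be given.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (overrides `sim$seed` when simulating).
#' @param heading `"fit"` to estimate the transect heading, or a fixed
#'   compass heading in degrees.
#' @param grid heading grid step (degrees) when fitting the orientation.
#' @param window,step,min_n sliding-window parameters (km, km, count).
#' @param thresholds `"printed"` or `"formula"` threshold mode.
#' @param q_source `"hybrid-index"` or `"column"`.
#' @param covariates habitat covariates to test.
#' @param schema column-mapping schema for `input`.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_all <- function(input = NULL, sim = NULL, out_dir, seed = 1L,
                    heading = "fit", grid = 1,
                    window = 0.2, step = 0.1, min_n = 5,
                    thresholds = c("printed", "formula"),
                    q_source = c("hybrid-index", "column"),
                    covariates = c("vegetation", "elevation"),
                    schema = default_schema()) {
  thresholds <- match.arg(thresholds)
  q_source <- match.arg(q_source)
  if (is.null(input) == is.null(sim))
    stop("give exactly one of 'input' or 'sim'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(obj, fname, format) {
    path <- file.path(out_dir, fname)
    write_results(obj, path, format)
    files <<- c(files, fname)
    path
  }

  dataset <- stage("load", {
    if (!is.null(sim)) {
      sim$seed <- as.integer(seed)
      simulate_zone(sim)
    } else read_genotypes(input, schema)
  })

  orient <- stage("orientation", {
    if (identical(heading, "fit")) fit_orientation(dataset, grid = grid)
    else NULL
  })
  use_heading <- if (is.null(orient)) as.numeric(heading)
                 else orient$heading
  stage("orientation", emit(list(
    heading = use_heading,
    fitted = !is.null(orient),
    support = if (!is.null(orient)) as.list(orient$support),
    loglik = if (!is.null(orient)) orient$loglik,
    directions_agree = if (!is.null(orient)) orient$directions_agree),
    "orientation.json", "json"))

  projected <- stage("projection",
                     project_positions(dataset, use_heading))

  nuc <- nuclear_loci(dataset)
  mt <- mito_locus(dataset)
  fits_tab <- stage("cline_fits", {
    sets <- c(as.list(dataset$loci$name),
              list(nuc), list(dataset$loci$name))
    names(sets) <- c(dataset$loci$name, "all_nuclear", "all_loci")
    rows <- lapply(names(sets), function(nm) {
      f <- fit_cline(projected, loci = sets[[nm]], profile = FALSE)
      data.frame(locus = nm, center = coef(f)[["center"]],
                 center_lo = f$support["center", "lower"],
                 center_hi = f$support["center", "upper"],
                 width = coef(f)[["width"]],
                 width_lo = f$support["width", "lower"],
                 width_hi = f$support["width", "upper"],
                 loglik = f$loglik, n_obs = f$nobs,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    emit(tab, "cline_fits.tsv", "tsv")
    tab
  })

  coincidence <- stage("coincidence", {
    tests <- lapply(c(center = "center", width = "width"),
                    function(s) {
                      t <- fit_shared_and_test(projected, s)
                      list(G = t$G, df = t$df, p = t$p,
                           shared_mle = unname(t$shared_fit$coefficients))
                    })
    off <- if (length(mt)) {
      c_mt <- fits_tab$center[fits_tab$locus == mt]
      c_nuc <- fits_tab$center[fits_tab$locus == "all_nuclear"]
      c_mt - c_nuc
    } else NULL
    out <- c(tests, list(mt_nuclear_center_offset_km = off))
    emit(out, "coincidence.json", "json")
    out
  })

  concord <- stage("concordance", {
    tab <- do.call(rbind, lapply(dataset$loci$name, function(l) {
      f <- fit_concordance(dataset, l)
      data.frame(locus = l, alpha = f$alpha, beta = f$beta,
                 G = f$G, df = f$df, p = f$p, stringsAsFactors = FALSE)
    }))
    emit(tab, "concordance.tsv", "tsv")
    tab
  })

  ld <- stage("ld_scan", {
    tab <- ld_scan(projected, window = window, step = step,
                   min_n = min_n)
    emit(as.data.frame(tab), "ld_windows.tsv", "tsv")
    tab
  })

  classes <- stage("classification", {
    tab <- suppressMessages(
      classify_dataset(dataset, q_source = q_source, mode = thresholds))
    emit(tab, "classification.tsv", "tsv")
    tab
  })

  habitat <- stage("habitat", {
    assoc <- habitat_association_test(classes$class_q,
                                      dataset$individuals$vegetation)
    lrts <- lapply(stats::setNames(covariates, covariates), function(cv)
      suppressWarnings({
        f <- fit_habitat_cline(projected, cv)
        list(G = f$G, df = f$df, p = f$p,
             effect = unname(f$habitat[3]))
      }))
    elev <- elevation_summary(dataset)
    out <- list(association = list(statistic = assoc$statistic,
                                   df = assoc$df, p = assoc$p),
                lrt = lrts,
                elevation = c(list(per_class = elev$summary),
                              list(F = elev$F, p = elev$p)))
    emit(out, "habitat.json", "json")
    out
  })

  manifest <- list(
    config = list(input = input, simulated = !is.null(sim),
                  seed = as.integer(seed), heading = heading,
                  window = window, step = step, min_n = min_n,
                  thresholds = thresholds, q_source = q_source),
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(dataset = dataset, orientation = orient,
                 projected = projected, cline_fits = fits_tab,
                 coincidence = coincidence, concordance = concord,
                 ld = ld, classes = classes, habitat = habitat,
                 manifest = manifest))
}
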