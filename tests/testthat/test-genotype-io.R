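test_that("allele pairs collapse to K counts and -9 codes go missing", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("id", "latitude", "longitude", "elevation", "vegetation",
            "phenotype", "external_class",
            "CXCR4_1", "CXCR4_2", "SLC8A3_1", "SLC8A3_2",
            "RAG1_1", "RAG1_2", "ND4"), collapse = "\t"),
    "s1\t33.3\t-116.9\t1400\tMMW\thybrid\t-9\tE\tK\te\tk\tE\tK\tK",
    "s2\t33.3\t-116.9\t1400\tMWP\tklauberi\t-9\tK\tK\t-9\t-9\tK\tK\tK"),
    tf)
  d <- read_genotypes(tf)
  expect_equal(unname(k_counts(d)[1, ]), c(1, 1, 1))
  expect_equal(d$individuals$mito, c("K", "K"))
  expect_true(is.na(k_counts(d)[2, "SLC8A3"]))
  expect_equal(unname(k_counts(d)[2, c("CXCR4", "RAG1")]), c(2, 2))
})

test_that("unassignable allele codes are coerced to missing with a warning", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("id", "latitude", "longitude", "elevation", "vegetation",
            "phenotype", "CXCR4_1", "CXCR4_2", "SLC8A3_1", "SLC8A3_2",
            "RAG1_1", "RAG1_2", "ND4"), collapse = "\t"),
    "s1\t33.3\t-116.9\t1400\tMMW\thybrid\tE\tK\tX\tK\tE\tE\tE"),
    tf)
  expect_warning(d <- read_genotypes(tf), "unassignable")
  expect_true(is.na(k_counts(d)[1, "SLC8A3"]))
  expect_equal(unname(k_counts(d)[1, "CXCR4"]), 1)
})

test_that("schema and row-level errors name the offender", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlatitude\tfoo", "s1\t33\t1"), tf)
  expect_error(read_genotypes(tf), "longitude")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("id", "latitude", "longitude", "elevation", "vegetation",
                 "phenotype", "CXCR4_1", "CXCR4_2", "SLC8A3_1",
                 "SLC8A3_2", "RAG1_1", "RAG1_2", "ND4"), collapse = "\t")
  writeLines(c(hdr,
               "s1\tnorth\t-116.9\t1400\tMMW\thybrid\tE\tE\tE\tE\tE\tE\tE"),
             tf2)
  expect_error(read_genotypes(tf2), "s1")
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  row <- "s1\t33.3\t-116.9\t1400\tMMW\thybrid\tE\tE\tE\tE\tE\tE\tE"
  writeLines(c(hdr, row, row), tf3)
  expect_error(read_genotypes(tf3), "duplicate")
})

test_that("write/read round-trips synthetic datasets exactly", {
  for (seed in 1:3) {
    d <- simulate_zone(sim_config(n = 60, seed = seed))
    tf <- withr::local_tempfile(fileext = ".tsv")
    write_genotypes(d, tf)
    d2 <- read_genotypes(tf,
                         default_schema(nuclear = nuclear_loci(d),
                                        mito = mito_locus(d)))
    expect_identical(k_counts(d2), k_counts(d))
    expect_identical(d2$individuals$mito, d$individuals$mito)
    expect_identical(d2$individuals$vegetation, d$individuals$vegetation)
    expect_equal(d2$individuals$lat, d$individuals$lat, tolerance = 0)
    expect_equal(d2$individuals$elevation, d$individuals$elevation,
                 tolerance = 0)
  }
})

test_that("result tables round-trip and empty results are refused", {
  fits <- data.frame(locus = c("A", "MT"), center = c(-0.11201, -0.2),
                     width = c(pi / 4, 0.718), n = c(300L, 335L))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_results(fits, tf, "tsv")
  back <- read_results(tf)
  expect_identical(back$locus, fits$locus)
  expect_identical(back$n, fits$n)
  expect_identical(back$center, fits$center)
  expect_identical(back$width, fits$width)
  expect_error(write_results(fits[0, ], tf, "tsv"), "empty")
  ld <- data.frame(center = c(0.1, 0.2), D_between = c(0.01, 0.15))
  write_results(ld, tf, "tsv")
  expect_equal(nrow(read_results(tf)), 2)
})

test_that("dataset invariants are enforced", {
  expect_error(make_dataset(cbind(c(0, 3))), "0, 1, 2")
  expect_error(make_dataset(cbind(0), elevation = 9000), "elevation")
  loci <- make_loci()
  loci$ploidy[1] <- 1L
  ind <- make_dataset(cbind(A = 0, B = 0, C = 0), mito = "E")$individuals
  expect_error(genotype_dataset(loci, ind), "ploidy")
})
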