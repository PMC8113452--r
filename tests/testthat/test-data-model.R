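test_that("variant and sample table invariants are enforced", {
  expect_error(variant_table("1", 0L, "v1", "A", "G"), "positions")
  expect_error(variant_table("1", c(10L, 20L), c("v1", "v1"),
                             c("A", "C"), c("G", "T")), "duplicate")
  expect_error(variant_table("1", 10L, "v1", "A", "G", impq = 1.2),
               "\\[0, 1\\]")
  v <- variant_table("1", 10L, "v1", "A", "G", impq = NA)
  expect_false(v$is_imputed)

  expect_error(
    sample_table("S1", "case", "male", 50, 22, "smoker",
                 0.5, 0.5, 0.5, 0.5),
    "sum to 1")
  expect_error(
    sample_table(c("S1", "S1"), "case", "male", 50, 22, "smoker",
                 0.9, 0.05, 0.03, 0.02),
    "duplicate")
  # controlled vocabulary is case-insensitive
  s <- sample_table("S1", "Case", "MALE", 50, 22, "Non Smoker",
                    0.9, 0.05, 0.03, 0.02)
  expect_identical(s$status, "case")
  expect_identical(s$smoking, "non-smoker")
  expect_error(
    sample_table("S1", "patient", "male", 50, 22, "smoker",
                 0.9, 0.05, 0.03, 0.02),
    "status")
})

test_that("dosage_dataset validates dimensions and range", {
  s <- sample_table(c("S1", "S2"), c("case", "control"),
                    c("male", "female"), c(50, 60), c(22, 25),
                    c("smoker", "non-smoker"), 0.9, 0.05, 0.03, 0.02)
  v <- variant_table("1", c(10L, 20L), c("v1", "v2"), c("A", "C"),
                     c("G", "T"))
  expect_error(dosage_dataset(s, v, matrix(0, 3, 2)), "3 x 2")
  expect_error(dosage_dataset(s, v, matrix(3, 2, 2)), "\\[0, 2\\]")
  ds <- dosage_dataset(s, v, matrix(c(0, 1, 2, NA), 2, 2))
  expect_equal(dim(ds), c(2L, 2L))
  expect_identical(colnames(ds$dosages), c("v1", "v2"))
})

test_that("VCF dosages are read with GT fallback and multiallelic skip", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(path)
  warns <- capture_warnings(got <- read_vcf_dosages(path))
  expect_length(warns, 2)              # the two multiallelic records
  expect_match(warns[1], "multiallelic")
  expect_equal(nrow(got$variants), 8)  # 10 records - 2 multiallelic
  expect_identical(got$sample_ids, c("S1", "S2"))
  # direct DS copy
  expect_equal(unname(got$dosages[, "rs1"]), c(0.5, 1.5))
  # GT fallback when DS absent: 0/1 -> 1, 1/1 -> 2
  expect_equal(unname(got$dosages[, "rs2"]), c(1, 2))
  # missing genotype
  expect_true(is.na(got$dosages["S1", "rs9"]))
  # imputation quality from INFO; absent -> genotyped
  expect_equal(got$variants$impq[got$variants$vid == "rs5"], 0.29)
  expect_true(is.na(got$variants$impq[got$variants$vid == "rs8"]))
  expect_false(got$variants$is_imputed[got$variants$vid == "rs8"])

  expect_error(read_vcf_dosages(file.path(tempdir(), "nope.vcf")),
               "not found")
  expect_error(
    suppressWarnings(read_vcf_dosages(path, multiallelic = "error")),
    "multiallelic")
})

test_that("covariate files parse and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_covariates(path, n = 173)
  s <- read_covariates(path)
  expect_equal(nrow(s), 173)
  expect_s3_class(s, "sample_table")
  expect_identical(s$sid[1], "P1")

  # ancestry rows not summing to one are named in the error
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sid,status,sex,age,bmi,smoking,eas,sas,eur,afr",
               "S1,case,male,54,21.2,smoker,0.92,0.07,0.01,0.00",
               "S2,control,female,60,24,non-smoker,0.5,0.5,0.5,0.5"),
             bad)
  expect_error(read_covariates(bad), "S2")

  noage <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sid,status,sex,bmi,smoking,eas,sas,eur,afr",
               "S1,case,male,21.2,smoker,0.92,0.07,0.01,0.00"), noage)
  expect_error(read_covariates(noage), "age")
})

test_that("joining restricts to the sample intersection in VCF order", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_covariates(path, n = 4)
  samples <- read_covariates(path)
  v <- variant_table("1", c(10L, 20L), c("v1", "v2"), c("A", "C"),
                     c("G", "T"))
  dos <- matrix(1, 5, 2)
  order5 <- c("P3", "P1", "P4", "P2", "P9")  # P9 lacks covariates
  expect_message(ds <- join_dataset(v, dos, samples, order5), "dropped")
  expect_equal(nrow(ds$samples), 4)
  expect_identical(ds$samples$sid, c("P3", "P1", "P4", "P2"))
  expect_error(join_dataset(v, dos, samples, c("X1", "X2", "X3", "X4",
                                               "X5")),
               "no samples shared")
})

test_that("result tables round-trip losslessly and schemas are checked", {
  rows <- data.frame(
    vid = c("a", "b", "c"), chrom = "1", pos = c(1L, 2L, 3L),
    ref = "A", alt = "G", maf = c(0.123456789012345, 0.3, NA),
    beta = c(1 / 3, -2.5, 0.1), se = 0.25, z = c(4 / 3, -10, 0.4),
    p = c(0.18, 1e-23, 0.69), or_ = exp(c(1 / 3, -2.5, 0.1)),
    n = 100L, converged = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(rows, path, "assoc")
  back <- read_result_table(path, "assoc")
  expect_equal(back$beta, rows$beta, tolerance = 0)
  expect_equal(back$maf, rows$maf, tolerance = 0)
  expect_equal(back$p, rows$p, tolerance = 0)

  # empty row set -> header-only file
  write_result_table(rows[0, ], path, "assoc")
  expect_equal(length(readLines(path)), 1L)

  expect_error(write_result_table(rows, path, "mystery"),
               "unknown result schema")
  expect_error(write_result_table(rows[, -6], path, "assoc"), "maf")

  # model schema mirrors the published risk-table headings
  expect_true(all(c("gene", "ref", "maf", "estimate") %in%
                    polygdp:::result_schemas()$model))
})
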