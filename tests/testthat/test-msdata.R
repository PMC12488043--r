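test_that("native PSM tables round-trip exactly", {
  psms <- make_psms(c("PEPTIDEK", "ELVISLIVESK", "DECOYSEQR"),
                    run_id = c("r1", "r1", "r2"),
                    rt = c(100.5, 200.25, 300.125),
                    q_value = c(1e-4, 2e-3, 0.5),
                    is_decoy = c(FALSE, FALSE, TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, f)
  back <- read_psm_table(f)
  expect_equal(back, psms)
})

test_that("an empty PSM file with a header yields an empty table", {
  psms <- make_psms("PEPTIDEK")[0, ]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, f)
  back <- read_psm_table(f)
  expect_equal(nrow(back), 0L)
  expect_setequal(colnames(back), colnames(psms))
})

test_that("missing columns and bad numerics are reported precisely", {
  psms <- make_psms("PEPTIDEK")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, f)
  lines <- readLines(f)
  # drop the is_decoy column
  keep <- setdiff(seq_along(strsplit(lines[1], "\t")[[1]]),
                  which(strsplit(lines[1], "\t")[[1]] == "is_decoy"))
  mangled <- vapply(strsplit(lines, "\t"), function(x)
    paste(x[keep], collapse = "\t"), character(1))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(mangled, f2)
  expect_error(read_psm_table(f2), "is_decoy")
  # corrupt one numeric field
  bad <- make_psms(c("AK", "BK"))
  bad$mono_mass <- c("1500.1", "oops")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_psm_table(f3), "mono_mass.*row.*2")
})

test_that("ms1_tsv reading assigns 0-based scan indices in RT order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scan_id\trt_seconds\tmz\tintensity",
               "sA\t10\t500.1\t100", "sA\t10\t600.2\t50",
               "sB\t20\t500.1\t80"), f)
  run <- read_ms1(f, "ms1_tsv")
  expect_equal(run$scan_rt, c(10, 20))
  expect_setequal(unique(run$peaks$scan_index), c(0L, 1L))
  expect_equal(run$peaks$scan_index[run$peaks$intensity == 80], 1L)
})

test_that("MS1 runs round-trip through the ms1_tsv format", {
  # a broad trace keeps every scan populated: the long format only
  # represents scans that hold at least one peak
  run <- planted_run(data.frame(mass = 1200, charge = 2, rt = 50,
                                amp = 1e5),
                     gradient = 100, peak_width = 40)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ms1_tsv(run, f)
  back <- read_ms1(f, "ms1_tsv", run_id = run$run_id,
                   gradient_length = run$gradient_length)
  o1 <- order(run$peaks$mz, run$peaks$scan_index)
  o2 <- order(back$peaks$mz, back$peaks$scan_index)
  expect_equal(back$peaks[o2, ], run$peaks[o1, ], ignore_attr = TRUE)
  expect_equal(back$scan_rt, run$scan_rt)
})

test_that("degenerate MS1 inputs raise format errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scan_id\trt_seconds\tmz\tintensity",
               "sA\t20\t500\t1", "sB\t10\t500\t1"), f)
  expect_error(read_ms1(f, "ms1_tsv"), "increasing")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scan_id\tms_level\trt_seconds\tmz\tintensity",
               "sA\t2\t10\t500\t1"), f2)
  expect_error(read_ms1(f2, "ms1_tsv"), "empty run")
})

test_that("the donor cutoff follows the one-fifth rule with a cap", {
  expect_identical(donor_threshold(0.01), 0.002)
  expect_identical(donor_threshold(0.025), 0.005)
  expect_identical(donor_threshold(0.05), 0.01)
  expect_identical(donor_threshold(0.2), 0.01)   # capped
  expect_identical(donor_threshold(0.2, donor_cap = 0.05), 0.04)
})

test_that("donor construction keeps the argmax PSM and unions charges", {
  psms <- make_psms(c("PEPK", "PEPK"), run_id = "rA",
                    charge = c(2L, 3L), score = c(10, 20),
                    rt = c(100, 101))
  donors <- build_donor_set(psms, 0.05)
  expect_equal(nrow(donors), 1L)
  expect_equal(donors$score, 20)
  expect_equal(donors$charge, 3L)
  expect_equal(donors$observed_charges, "2;3")
})

test_that("donor selection equals a brute-force q-value filter and never
           consults the decoy label", {
  set.seed(11)
  n <- 1000
  psms <- make_psms(sprintf("PEP%04dK", sample.int(400, n, TRUE)),
                    run_id = sample(c("r1", "r2"), n, TRUE),
                    score = runif(n, 0, 100),
                    q_value = runif(n),
                    is_decoy = runif(n) < 0.3)
  psms$scan_id <- sprintf("s%04d", seq_len(n))
  donors <- build_donor_set(psms, 0.01)  # cutoff 0.002
  keep <- psms[psms$q_value <= 0.002, ]
  expect_equal(nrow(donors),
               nrow(unique(keep[c("peptide", "run_id")])))
  flipped <- psms
  flipped$is_decoy <- !flipped$is_decoy
  donors2 <- build_donor_set(flipped, 0.01)
  key <- function(d) sort(paste(d$peptide, d$origin_run_id))
  expect_identical(key(donors), key(donors2))
})

test_that("propagation tables write deterministically and round-trip", {
  acc <- data.frame(acceptor_run_id = "r2", peptide = "PEPK",
                    stem = "PEPK", mono_mass = 1234.5678,
                    origin_run_id = "r1", anchor_kind = "predicted",
                    is_decoy = FALSE, charge = 2L, apex_rt = 123.456,
                    intensity = 1e5, pep = 0.001, q_value = 0.005,
                    stringsAsFactors = FALSE)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_pip_table(acc, f1)
  write_pip_table(acc, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_pip_table(f1)
  expect_equal(back, acc)
  write_pip_table(acc[0, ], f1)
  expect_equal(length(readLines(f1)), 1L)  # header only
  expect_equal(nrow(read_pip_table(f1)), 0L)
})
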