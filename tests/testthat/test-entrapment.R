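# digestion oracle built from a cleavage-site regex, independent of the
# package's positional implementation
regex_digest <- function(s, min_len, max_missed) {
  frags <- strsplit(gsub("(?<=[KR])(?!P)", "\r", s, perl = TRUE),
                    "\r", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_along(frags))
    for (m in 0:max_missed) {
      if (i + m > length(frags)) break
      pep <- paste(frags[i:(i + m)], collapse = "")
      if (nchar(pep) >= min_len) out <- c(out, pep)
    }
  unique(out)
}

test_that("tryptic digestion cleaves after K/R except before P", {
  expect_setequal(tryptic_digest("ACKDERFG", min_len = 1, max_missed = 0),
                  c("ACK", "DER", "FG"))
  expect_setequal(tryptic_digest("ACKPDE", min_len = 1, max_missed = 0),
                  "ACKPDE")
  expect_error(tryptic_digest("ACZ"), "invalid residue")
})

test_that("digestion equals the regex oracle on random sequences", {
  set.seed(30)
  aa <- names(pipecho:::AA_MONO)
  for (i in 1:20) {
    s <- paste(sample(aa, sample(20:120, 1), replace = TRUE,
                      prob = ifelse(aa %in% c("K", "R", "P"), 3, 1)),
               collapse = "")
    ml <- sample(c(1, 5, 7), 1)
    mm <- sample(0:2, 1)
    expect_setequal(tryptic_digest(s, ml, mm), regex_digest(s, ml, mm))
  }
})

test_that("entrapment shuffles pin K/R and preserve the residue multiset", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- write_random_fasta(f, n = 8, seed = 41)
  db <- build_entrapment_db(f, seed = 5)
  for (i in seq_len(nrow(db))) {
    o <- strsplit(db$original[i], "")[[1]]
    s <- strsplit(db$shuffled[i], "")[[1]]
    expect_identical(which(s %in% c("K", "R")), which(o %in% c("K", "R")))
    expect_identical(sort(s), sort(o))
    expect_equal(db$offset[i], nchar(db$original[i]))
    expect_identical(substr(db$fused[i], 1, db$offset[i]), db$original[i])
  }
})

test_that("colliding shuffled peptides are removed and half is appended", {
  f <- withr::local_tempfile(fileext = ".fasta")
  # one protein whose shuffle is forced identical: all one residue except
  # pinned K sites -> every shuffled fragment collides with the original
  writeLines(c(">COLL1", "AAAAAAKAAAAAAKAAAAAAK"), f)
  db <- build_entrapment_db(f, seed = 1)
  expect_identical(db$segment, "")  # everything collided, nothing left
  # and a protein with plenty of entropy keeps roughly half
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_random_fasta(f2, n = 5, len = c(150, 250), seed = 42)
  db2 <- build_entrapment_db(f2, seed = 2)
  expect_true(all(nchar(db2$segment) <=
                    ceiling(nchar(db2$shuffled) / 2)))
  expect_true(all(nchar(db2$segment) > 0))
  # no entrapment tryptic peptide occurs in the target digest
  target_peps <- unique(unlist(lapply(db2$original, tryptic_digest,
                                      min_len = 7, max_missed = 2)))
  seg_peps <- unlist(lapply(db2$segment, tryptic_digest, min_len = 7,
                            max_missed = 2))
  expect_length(intersect(seg_peps, target_peps), 0L)
})

test_that("fused FASTA carries the boundary offset and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_random_fasta(f, n = 3, seed = 43)
  db <- build_entrapment_db(f, seed = 3)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_entrapment_fasta(db, out)
  x <- Biostrings::readAAStringSet(out)
  expect_equal(as.character(x), db$fused, ignore_attr = TRUE)
  offs <- as.integer(sub(".*ENTRAP_OFFSET=(\\d+).*", "\\1", names(x)))
  expect_equal(offs, db$offset)
})

test_that("censor selection applies the four criteria then samples 500", {
  set.seed(31)
  n <- 2000
  peps <- sprintf("PEP%04d", seq_len(n))
  run_i <- make_psms(peps, run_id = "pure1",
                     score = runif(n, 40, 60),
                     q_value = ifelse(seq_len(n) <= 1200, 5e-4, 5e-3))
  # duplicate MS2 for peptides 1..200 (fails criterion 4)
  dup <- run_i[1:200, ]
  dup$scan_id <- paste0(dup$scan_id, "b")
  other <- make_psms(peps, run_id = "run2", score = 70)  # all higher
  # peptides 1201..2000 fail criterion 1; 1001..1200 are foreign
  membership <- setNames(ifelse(seq_len(n) <= 1000 | seq_len(n) > 1200,
                                "human", "foreign"), peps)
  psms <- rbind(run_i, dup, other)
  plan <- select_censor_set(psms, "pure1", membership, n_censor = 500,
                            seed = 4)
  expect_equal(nrow(plan), 500L)
  qualifying <- peps[201:1000]  # 800 qualify
  expect_true(all(plan$peptide %in% qualifying))
  expect_false(anyDuplicated(plan$peptide) > 0)
  # explicit single-criterion failures
  expect_false(any(plan$peptide %in% peps[1:200]))      # two spectra
  expect_false(any(plan$peptide %in% peps[1001:1200]))  # foreign
  expect_false(any(plan$peptide %in% peps[1201:2000]))  # q >= 0.001
})

test_that("censoring rewrites exactly the planned spectra", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scan_id\tms_level\trt_seconds\tmz\tintensity",
               "s1\t1\t10\t500.5\t100",
               "s1\t1\t10\t600.5\t50",
               "s2\t2\t11\t234.1\t10",
               "s2\t2\t11\t345.2\t20",
               "s3\t1\t12\t500.5\t90",
               "s4\t2\t13\t456.7\t30"), f)
  out <- withr::local_tempfile(fileext = ".tsv")
  censor_file(f, data.frame(scan_id = "s2"), out)
  got <- readLines(out)
  want <- c("scan_id\tms_level\trt_seconds\tmz\tintensity",
            "s1\t1\t10\t500.5\t100",
            "s1\t1\t10\t600.5\t50",
            "s2\t2\t11\t150\t1",
            "s3\t1\t12\t500.5\t90",
            "s4\t2\t13\t456.7\t30")
  expect_identical(got, want)
  # empty plan: byte-identical copy
  out2 <- withr::local_tempfile(fileext = ".tsv")
  censor_file(f, data.frame(scan_id = character(0)), out2)
  expect_identical(readLines(out2), readLines(f))
  # errors: unknown scan, MS1 scan
  expect_error(censor_file(f, data.frame(scan_id = "nope"), out2),
               "nope")
  expect_error(censor_file(f, data.frame(scan_id = "s3"), out2),
               "not MS2")
})

test_that("the native error threshold is 1% of the gradient", {
  pairs <- data.frame(ms2_rt = c(100, 200, 300),
                      pip_rt = c(110, 260, 400))
  nr <- native_error_rate(pairs, gradient_length = 5400)
  expect_equal(nr$threshold, 54)
  expect_equal(nr$rate, 2 / 3)  # diffs 10, 60, 100
  zero <- data.frame(ms2_rt = c(1, 2), pip_rt = c(1, 2))
  expect_equal(native_error_rate(zero, 5400)$rate, 0)
  expect_error(native_error_rate(pairs[0, ], 5400), "no pairs")
})

test_that("classification removes carryovers and follows membership", {
  membership <- c(HUM1 = "human", YEA1 = "foreign", YEA2 = "foreign",
                  ENT1 = "entrapment")
  pips <- data.frame(peptide = c("HUM1", "YEA1", "YEA2", "ENT1"))
  cls <- classify_pip(pips, membership, foreign_ms2 = "YEA1")
  expect_equal(cls, c("human", "carryover_removed", "foreign",
                      "entrapment"))
  expect_error(classify_pip(data.frame(peptide = "NOPE"), membership),
               "NOPE")
})

test_that("the FDP estimate matches direct substitution and is linear", {
  cls <- c(rep("human", 985), rep("foreign", 5), rep("entrapment", 10))
  est <- estimate_fdp(cls, S = 1.86, native_rate = 0.01)
  expect_equal(est$eFPE, 5)
  expect_equal(est$ePIE, 18.6)
  expect_equal(est$eNPE, 9.85)
  expect_equal(est$eFDP, (5 + 18.6 + 9.85) / 1000)
  clean <- estimate_fdp(rep("human", 100), S = 1.86, native_rate = 0)
  expect_equal(clean$eFDP, 0)
  # doubling every component count leaves the FDP unchanged,
  # doubling only the error counts doubles (approximately) the FDP
  est2 <- estimate_fdp(rep(cls, 2), S = 1.86, native_rate = 0.01)
  expect_equal(est2$eFDP, est$eFDP)
  est3 <- estimate_fdp(c(cls, rep("foreign", 5), rep("entrapment", 10)),
                       S = 1.86, native_rate = 0.01)
  expect_equal(est3$eFPE, 2 * est$eFPE)
  expect_equal(est3$ePIE, 2 * est$ePIE)
})
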