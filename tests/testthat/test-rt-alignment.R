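test_that("anchor pairs take the best-scoring PSM RT of each shared peptide", {
  d <- make_psms(c("P1", "P2", "P2"), run_id = "r1",
                 rt = c(100, 200, 205), score = c(50, 90, 10))
  a <- make_psms(c("P1", "P2", "P3"), run_id = "r2",
                 rt = c(110, 210, 400))
  as <- suppressWarnings(build_anchor_set(d, a))
  expect_equal(as$pairs$donor_rt, c(100, 200))
  expect_equal(as$pairs$acceptor_rt, c(110, 210))
})

test_that("too few shared peptides flags the identity fallback", {
  d <- make_psms("P1", run_id = "r1")
  a <- make_psms("ZZ", run_id = "r2")
  as <- build_anchor_set(d, a)
  expect_equal(nrow(as$pairs), 0L)
  expect_true(as$identity_fallback)
  expect_equal(predict_rt(as, c(5, 50)), c(5, 50))
})

test_that("anchors reproduce an affine warp exactly", {
  set.seed(3)
  rts <- sort(runif(500, 50, 1000))
  peps <- sprintf("P%04d", seq_along(rts))
  d <- make_psms(peps, run_id = "r1", rt = rts)
  a <- make_psms(peps, run_id = "r2", rt = 1.05 * rts + 30)
  as <- build_anchor_set(d, a)
  expect_false(as$identity_fallback)
  expect_equal(as$pairs$acceptor_rt, 1.05 * as$pairs$donor_rt + 30)
  # prediction of any point under a pure affine warp is within the local
  # median-shift error of the true warp
  pred <- predict_rt(as, c(100, 500, 900))
  expect_lt(max(abs(pred - (1.05 * c(100, 500, 900) + 30))), 15)
})

test_that("a constant shift is predicted exactly at any RT", {
  rts <- seq(100, 1000, by = 50)
  d <- make_psms(sprintf("P%02d", seq_along(rts)), run_id = "r1", rt = rts)
  a <- make_psms(sprintf("P%02d", seq_along(rts)), run_id = "r2",
                 rt = rts + 60)
  as <- build_anchor_set(d, a)
  expect_equal(predict_rt(as, c(0, 123.4, 2000)), c(0, 123.4, 2000) + 60)
})

test_that("prediction error stays small under a jittered monotone warp", {
  set.seed(4)
  rts <- sort(runif(200, 0, 1000))
  peps <- sprintf("P%04d", seq_along(rts))
  warp <- function(t) 1.04 * t + 25
  d <- make_psms(peps, run_id = "r1", rt = rts)
  a <- make_psms(peps, run_id = "r2", rt = warp(rts) + rnorm(200, 0, 2))
  as <- build_anchor_set(d, a)
  probe <- runif(200, 50, 950)
  err <- abs(predict_rt(as, probe) - warp(probe))
  expect_lt(median(err), 3)
})

test_that("prediction is monotone when anchor shifts are monotone", {
  rts <- seq(0, 1000, by = 25)
  # shift grows with RT: acceptor = t + t/10
  d <- make_psms(sprintf("P%02d", seq_along(rts)), run_id = "r1", rt = rts)
  a <- make_psms(sprintf("P%02d", seq_along(rts)), run_id = "r2",
                 rt = rts + rts / 10)
  as <- build_anchor_set(d, a)
  probe <- seq(0, 1000, by = 7)
  pred <- predict_rt(as, probe)
  expect_true(all(diff(pred) >= 0))
})

test_that("randomized-anchor eligibility applies mass, RT and stem rules", {
  cfg <- pip_config()
  donor <- list(mono_mass = 1500, rt = 600, stem = "DONORSTEM",
                peptide = "DONORSTEM")
  cands <- data.frame(peptide = c("A", "B", "C"),
                      stem = c("A", "B", "C"),
                      mono_mass = c(1503, 1507, 1512),
                      rt = c(100, 100, 100))
  el <- eligible_random_donors(donor, cands, cfg)
  expect_equal(el$peptide, "B")  # 3 Da too close, 12 Da too far
  same_stem <- data.frame(peptide = "X", stem = "DONORSTEM",
                          mono_mass = 1508, rt = 100)
  expect_equal(nrow(eligible_random_donors(donor, same_stem, cfg)), 0L)
})

test_that("eligibility equals a brute-force filter on random candidates", {
  set.seed(5)
  cfg <- pip_config()
  donor <- list(mono_mass = 2000, rt = 500, stem = "S0", peptide = "S0")
  cands <- data.frame(peptide = sprintf("c%04d", 1:1000),
                      stem = sample(c("S0", sprintf("s%03d", 1:50)),
                                    1000, TRUE),
                      mono_mass = runif(1000, 1980, 2020),
                      rt = runif(1000, 0, 1200))
  el <- eligible_random_donors(donor, cands, cfg)
  dm <- abs(cands$mono_mass - 2000)
  manual <- cands[dm > 5 & dm <= 11 &
                    abs(cands$rt - 500) >= cfg$min_rt_separation &
                    cands$stem != "S0", ]
  expect_equal(el$peptide, manual$peptide)
})

test_that("random anchor draws are uniform across streams and reproducible", {
  cfg <- pip_config(seed = 99)
  donor <- list(peptide = "DON", mono_mass = 1500, rt = 600, stem = "DON")
  elig <- data.frame(peptide = c("a", "b", "c", "d"),
                     stem = c("a", "b", "c", "d"),
                     mono_mass = 1507, rt = c(10, 20, 30, 40))
  anchors <- structure(list(pairs = data.frame(donor_rt = numeric(0),
                                               acceptor_rt = numeric(0)),
                            identity_fallback = TRUE),
                       class = "anchor_set")
  one <- draw_random_anchor(donor, elig[1, , drop = FALSE], anchors,
                            "accR", cfg)
  expect_equal(one$source_peptide, "a")
  draws <- vapply(1:10000, function(i)
    draw_random_anchor(donor, elig, anchors, paste0("acc", i),
                       cfg)$source_peptide, character(1))
  counts <- table(draws)
  expect_true(all(abs(counts - 2500) <= 150))
  again <- vapply(1:50, function(i)
    draw_random_anchor(donor, elig, anchors, paste0("acc", i),
                       cfg)$source_peptide, character(1))
  expect_identical(again, draws[1:50])
})

test_that("randomized RTs are distributed like mapped analyte RTs", {
  set.seed(6)
  cfg <- pip_config(seed = 123)
  rts <- sort(rbeta(300, 2, 2)) * 1000  # non-uniform elution profile
  peps <- sprintf("P%04d", seq_along(rts))
  d <- make_psms(peps, run_id = "r1", rt = rts)
  a <- make_psms(peps, run_id = "r2", rt = rts + 40)
  anchors <- build_anchor_set(d, a, cfg)
  pool <- data.frame(peptide = peps, stem = peps, mono_mass = 1507,
                     rt = rts)
  donor <- list(peptide = "DON", mono_mass = 1500, rt = 500, stem = "DON")
  draws <- vapply(1:1000, function(i)
    draw_random_anchor(donor, pool, anchors, paste0("a", i),
                       cfg)$randomized_rt, numeric(1))
  mapped <- predict_rt(anchors, rts, cfg)
  ks <- suppressWarnings(stats::ks.test(draws, mapped))$statistic
  expect_lt(unname(ks), 0.1)
})
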