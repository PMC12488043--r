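test_that("theoretical envelopes follow the Poisson model", {
  for (mass in c(500, 1000, 3000, 5000)) {
    env <- theoretical_envelope(mass)
    expect_equal(sum(env$relative_abundances), 1, tolerance = 1e-9)
    lam <- 4.88e-4 * mass
    direct <- dpois(0:4, lam) / sum(dpois(0:4, lam))
    expect_equal(env$relative_abundances, direct)
    expect_equal(env$most_abundant_index, which.max(direct) - 1L)
  }
  expect_equal(theoretical_envelope(1000)$most_abundant_index, 0L)
  expect_equal(theoretical_envelope(3000)$most_abundant_index, 1L)
})

test_that("a planted trace is recovered with exact apex and intensity", {
  donor <- list(mono_mass = 1800, observed_charges = "2", stem = "X",
                peptide = "X")
  run <- planted_run(data.frame(mass = 1800, charge = 2, rt = 300,
                                amp = 1e5))
  traces <- find_eligible_traces(run, donor, 2,
                                 list(anchor_rt = 300, half_width = 30))
  expect_length(traces, 1L)
  tr <- traces[[1]]
  expect_equal(tr$apex_rt, 300)  # scan grid hits 300 exactly
  # apex equals the brute-force argmax of summed log intensities
  expect_equal(apex_scan(tr),
               tr$scan_index[which.max(tr$scan_log_sum)])
  # intensity is the summed matched isotopologue intensity at the apex
  i <- which(tr$scan_index == tr$apex_scan_index)
  expect_equal(trace_intensity(tr), sum(tr$iso_intensity[i, ]))
  env <- theoretical_envelope(1800)
  expect_equal(trace_intensity(tr), 1e5 * sum(env$relative_abundances),
               tolerance = 1e-6)
})

test_that("runs without matching peaks yield no traces", {
  donor <- list(mono_mass = 2222, observed_charges = "2")
  run <- planted_run(data.frame(mass = 1800, charge = 2, rt = 300,
                                amp = 1e5))
  expect_length(find_eligible_traces(run, donor, 2,
                                     list(anchor_rt = 300,
                                          half_width = 150)), 0L)
})

test_that("the apex window test is half-open on the high side", {
  run <- planted_run(data.frame(mass = 1500, charge = 2, rt = 300,
                                amp = 1e5))
  donor <- list(mono_mass = 1500, observed_charges = "2")
  inside <- find_eligible_traces(run, donor, 2,
                                 list(anchor_rt = 271, half_width = 30))
  expect_length(inside, 1L)   # 300 in [241, 301)
  outside <- find_eligible_traces(run, donor, 2,
                                  list(anchor_rt = 269, half_width = 30))
  expect_length(outside, 0L)  # 300 not in [239, 299)
  at_edge <- find_eligible_traces(run, donor, 2,
                                  list(anchor_rt = 270, half_width = 30))
  expect_length(at_edge, 0L)  # 300 not in [240, 300)
})

test_that("apex selection matches brute force on random multi-scan traces", {
  set.seed(7)
  for (rep in 1:5) {
    rt <- runif(1, 150, 450)
    run <- planted_run(data.frame(mass = 2000, charge = 2, rt = rt,
                                  amp = 10^runif(1, 4, 6)),
                       peak_width = 20)  # long trace, ~50 valid scans
    donor <- list(mono_mass = 2000, observed_charges = "2")
    tr <- find_eligible_traces(run, donor, 2,
                               list(anchor_rt = rt, half_width = 60))[[1]]
    manual <- vapply(seq_along(tr$scan_index), function(i) {
      v <- tr$iso_intensity[i, ]
      sum(log(v[v > 0]))
    }, numeric(1))
    expect_equal(apex_scan(tr), tr$scan_index[which.max(manual)])
  }
})

test_that("expanding search widens in 30 s steps until a trace is found", {
  run <- planted_run(data.frame(mass = 1600, charge = 2, rt = 340,
                                amp = 1e5))
  donor <- list(mono_mass = 1600, observed_charges = "2", peptide = "X",
                stem = "X")
  hit <- search_with_expansion(run, donor, anchor_rt = 300)
  expect_false(is.null(hit))
  expect_equal(hit$half_width, 60)  # |340 - 300| = 40 needs one expansion
  none <- search_with_expansion(run, donor, anchor_rt = 300 - 200)
  expect_null(none)  # beyond the 150 s maximal half width
})

test_that("the higher combined-score trace wins within a window", {
  set.seed(8)
  # two traces of the same peptide: one intense and clean, one weak
  run <- planted_run(data.frame(mass = c(1600, 1600), charge = c(2, 2),
                                rt = c(280, 320), amp = c(1e5, 2e2)))
  donor <- list(mono_mass = 1600, observed_charges = "2", peptide = "X",
                stem = "X")
  ref_feats <- cbind(mass_error = abs(rnorm(50, 0, 2)),
                     log_intensity = rnorm(50, log(5e4), 1),
                     rt_diff = abs(rnorm(50, 0, 5)),
                     envelope_similarity = runif(50, 0.9, 1),
                     n_valid_scans = sample(5:15, 50, TRUE))
  ref <- reference_population(ref_feats)
  hit <- search_with_expansion(run, donor, anchor_rt = 300,
                               reference = ref)
  # the intense trace scores higher on intensity at similar rt_diff
  expect_equal(hit$trace$apex_rt, 280)
})

test_that("returned traces satisfy eligibility when re-checked", {
  run <- planted_run(data.frame(mass = c(1500, 2500), charge = c(2, 3),
                                rt = c(200, 200), amp = c(1e5, 1e5)))
  cfg <- pip_config()
  for (m in c(1500, 2500)) {
    z <- if (m == 1500) 2 else 3
    donor <- list(mono_mass = m, observed_charges = as.character(z))
    trs <- find_eligible_traces(run, donor, z,
                                list(anchor_rt = 200, half_width = 30),
                                cfg)
    for (tr in trs) {
      expect_gte(min(tr$scan_cos), cfg$min_envelope_cos)
      expect_true(all(diff(tr$scan_index) == 1L))
      expect_true(tr$apex_scan_index >= tr$scan_start &&
                    tr$apex_scan_index < tr$scan_end)
      expect_gte(tr$apex_rt, 200 - 30)
      expect_lt(tr$apex_rt, 200 + 30)
    }
  }
})

test_that("search is independent of charge order and monotone in window", {
  run <- planted_run(data.frame(mass = c(1700, 1700), charge = c(2, 3),
                                rt = c(300, 350), amp = c(5e4, 8e4)))
  d12 <- list(mono_mass = 1700, observed_charges = "2;3", peptide = "X",
              stem = "X")
  d21 <- list(mono_mass = 1700, observed_charges = "3;2", peptide = "X",
              stem = "X")
  h1 <- search_with_expansion(run, d12, anchor_rt = 310)
  h2 <- search_with_expansion(run, d21, anchor_rt = 310)
  expect_equal(h1$charge, h2$charge)
  expect_equal(h1$trace$apex_rt, h2$trace$apex_rt)
  # shrinking the maximal window never adds traces
  wide <- search_with_expansion(run, d12, anchor_rt = 240,
                                config = pip_config(max_half_width = 150))
  narrow <- search_with_expansion(run, d12, anchor_rt = 240,
                                  config = pip_config(max_half_width = 30))
  expect_false(is.null(wide))
  expect_true(is.null(narrow) ||
                narrow$trace$apex_rt == wide$trace$apex_rt)
})
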