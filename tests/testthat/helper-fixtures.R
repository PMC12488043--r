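# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# An MS1 run with exactly the requested analyte traces planted on a
# regular scan grid (no jitter unless ppm_shift given). `analytes` is a
# data frame with columns mass, charge, rt, amp and optionally ppm.
planted_run <- function(analytes, run_id = "runA", gradient = 600,
                        interval = 2, n_iso = 5, peak_width = 6,
                        config = pip_config()) {
  scan_rt <- seq(interval, gradient, by = interval)
  parts <- list()
  for (i in seq_len(nrow(analytes))) {
    a <- analytes[i, ]
    env <- theoretical_envelope(a$mass, config)
    lo <- findInterval(a$rt - 3 * peak_width, scan_rt) + 1L
    hi <- findInterval(a$rt + 3 * peak_width, scan_rt)
    if (hi < lo) next
    idx <- lo:hi
    prof <- a$amp * exp(-(scan_rt[idx] - a$rt)^2 / (2 * peak_width^2))
    ppm <- if ("ppm" %in% names(analytes)) a$ppm else 0
    iso_mz <- (a$mass + (seq_len(n_iso) - 1) * 1.0033548378) / a$charge +
      1.007276466879
    parts[[length(parts) + 1L]] <- data.frame(
      scan_index = rep.int(idx - 1L, n_iso),
      mz = rep(iso_mz * (1 + ppm * 1e-6), each = length(idx)),
      intensity = rep(prof, times = n_iso) *
        rep(env$relative_abundances, each = length(idx)))
  }
  peaks <- if (length(parts)) do.call(rbind, parts)
           else data.frame(scan_index = integer(0), mz = numeric(0),
                           intensity = numeric(0))
  peaks <- peaks[peaks$intensity >= 1, , drop = FALSE]
  ms1_run(run_id, scan_rt, peaks, gradient_length = gradient)
}

# a minimal native-format PSM frame
make_psms <- function(peptide, run_id = "runA", scan_id = NULL,
                      mono_mass = 1500, charge = 2L, rt = 300,
                      score = 80, pep = 0.001, q_value = 5e-4,
                      is_decoy = FALSE, stem = NULL) {
  n <- max(lengths(list(peptide, run_id, rt, score, charge, q_value)))
  if (is.null(scan_id)) scan_id <- sprintf("s%04d", seq_len(n))
  data.frame(run_id = rep_len(run_id, n),
             scan_id = rep_len(scan_id, n),
             peptide = rep_len(peptide, n),
             stem = rep_len(if (is.null(stem)) peptide else stem, n),
             mono_mass = rep_len(mono_mass, n),
             charge = rep_len(as.integer(charge), n),
             rt = rep_len(rt, n),
             score = rep_len(score, n),
             pep = rep_len(pep, n),
             q_value = rep_len(q_value, n),
             is_decoy = rep_len(is_decoy, n),
             proteins = rep_len(paste0("P_", peptide), n),
             stringsAsFactors = FALSE)
}

# random candidate lists for competition/FDR oracle tests
random_candidates <- function(n, seed) {
  set.seed(seed)
  data.frame(
    donor_key = sprintf("pep%04d\rrunX", seq_len(n)),
    peptide = sprintf("pep%04d", sample.int(n)),
    acceptor_run_id = "runY",
    anchor_kind = sample(c("predicted", "randomized"), n, replace = TRUE),
    is_decoy = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.3, .7)),
    pep = round(runif(n), 3),  # rounding forces some ties
    combined_score = round(runif(n), 3),
    stringsAsFactors = FALSE)
}

# brute-force recount of the hybrid FDR estimate at every rank
brute_force_curve <- function(sorted) {
  n <- nrow(sorted)
  out <- data.frame(fdr_hat = numeric(n), fdr_adj = numeric(n))
  for (k in seq_len(n)) {
    top <- sorted[seq_len(k), ]
    T_p <- sum(top$anchor_kind == "predicted" & !top$is_decoy)
    T_r <- sum(top$anchor_kind == "randomized" & !top$is_decoy)
    D_p <- sum(top$anchor_kind == "predicted" & top$is_decoy)
    D_r <- sum(top$anchor_kind == "randomized" & top$is_decoy)
    num <- T_r + max(0, D_p - D_r)
    out$fdr_hat[k] <- if (T_p == 0) Inf else num / T_p
    out$fdr_adj[k] <- if (T_p == 0) Inf else (1 + num) / T_p
  }
  out
}

# small synthetic candidate table with separable correct/incorrect
# populations for rescoring tests
separable_candidates <- function(n_correct = 200, n_wrong = 100,
                                 n_random = 150, seed = 1) {
  set.seed(seed)
  mk <- function(n, kind, good, decoy = FALSE, prefix) {
    if (n == 0L) return(NULL)
    data.frame(
      donor_key = sprintf("%s%04d\rrun1", prefix, seq_len(n)),
      peptide = sprintf("%s%04d", prefix, seq_len(n)),
      acceptor_run_id = "run2",
      anchor_kind = kind, is_decoy = decoy,
      mass_error = if (good) abs(rnorm(n, 0, 2)) else runif(n, 4, 10),
      log_intensity = if (good) rnorm(n, 14, 1) else rnorm(n, 11, 1),
      rt_diff = if (good) abs(rnorm(n, 0, 3)) else runif(n, 10, 120),
      envelope_similarity = if (good) runif(n, 0.95, 1)
                            else runif(n, 0.7, 0.9),
      n_valid_scans = if (good) sample(8:15, n, TRUE)
                      else sample(1:4, n, TRUE),
      truth_correct = good,
      stringsAsFactors = FALSE)
  }
  cand <- rbind(mk(n_correct, "predicted", TRUE, prefix = "ok"),
                mk(n_wrong, "predicted", FALSE, prefix = "bad"),
                mk(n_random, "randomized", FALSE, prefix = "rnd"))
  ref <- reference_population(cand[cand$truth_correct,
                                   c("mass_error", "log_intensity",
                                     "rt_diff", "envelope_similarity",
                                     "n_valid_scans")])
  cal <- pipecho:::calibrate_features(as.matrix(
    cand[, c("mass_error", "log_intensity", "rt_diff",
             "envelope_similarity", "n_valid_scans")]), ref)
  colnames(cal) <- paste0("cal_", colnames(cal))
  cand <- cbind(cand, cal)
  cand$combined_score <- pipecho:::combined_score_matrix(
    cal[, paste0("cal_", c("mass_error", "log_intensity", "rt_diff",
                           "envelope_similarity", "n_valid_scans"))])
  cand
}

# small deterministic synthetic proteome written as FASTA
write_random_fasta <- function(path, n = 10, len = c(80, 200), seed = 1,
                               prefix = "SYNPROT") {
  set.seed(seed)
  aa <- names(pipecho:::AA_MONO)
  seqs <- vapply(seq_len(n), function(i) {
    L <- sample(len[1]:len[2], 1)
    paste(sample(aa, L, replace = TRUE, prob = ifelse(aa %in% c("K", "R"),
                                                      2, 1)),
          collapse = "")
  }, character(1))
  lines <- unlist(lapply(seq_len(n), function(i)
    c(sprintf(">%s%03d synthetic", prefix, i), seqs[i])))
  writeLines(lines, path)
  invisible(seqs)
}
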