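# Synthetic multi-run LC-MS experiments with ground truth. The generator
# embodies the two symmetry assumptions the error estimate rests on: an
# incorrect donor identity is equally likely to carry a target or a decoy
# peptide, and an incorrect peak match is equally likely at the predicted
# as at the randomized RT (neither anchor enjoys an advantage at a wrong
# location, because wrong-location signal is placed independently of both).

#' Simulation configuration
#'
#' Defaults describe a short-gradient, four-run DDA experiment at desk
#' scale: 2,000 analytes on a 1,200 s gradient sampled every 2 s, 90%
#' per-run analyte presence, 60% MS2 detection, mild affine RT warps with
#' 2 s jitter, 3 ppm mass jitter, 6 s Gaussian elution peaks, 400 noise
#' traces per run, and 10% + 10% contamination of the PSM list with
#' incorrect target donors and decoy donors (the 1:1 target:decoy split
#' realises the symmetry assumption).
#'
#' @param n_runs,n_analytes Experiment size.
#' @param gradient_length Gradient length, seconds.
#' @param scan_interval MS1 scan spacing, seconds.
#' @param presence_prob Probability an analyte elutes in a given run.
#' @param detection_prob Probability a present analyte is MS2-detected.
#' @param frac_incorrect_donors,frac_decoy_donors Contaminant PSMs as a
#'   fraction of the correct PSM count: target PSMs whose claimed peptide
#'   points at a different or absent analyte, and decoy PSMs.
#' @param warp_slope_range,warp_offset_range Per-run affine RT warp
#'   parameter ranges.
#' @param rt_jitter_sd Per-(analyte, run) RT jitter, seconds.
#' @param mass_jitter_ppm Systematic per-(analyte, run) mass error scale.
#' @param peak_width Gaussian elution peak standard deviation, seconds.
#' @param n_noise_traces Noise peak traces per run (random mass and RT).
#' @param amp_meanlog,amp_sdlog Log-normal apex intensity parameters.
#' @param min_peak_intensity Peaks below this intensity are not written.
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_runs = 4L, n_analytes = 2000L,
                       gradient_length = 1200, scan_interval = 2,
                       presence_prob = 0.9, detection_prob = 0.6,
                       frac_incorrect_donors = 0.1,
                       frac_decoy_donors = 0.1,
                       warp_slope_range = c(0.97, 1.03),
                       warp_offset_range = c(-20, 20),
                       rt_jitter_sd = 2, mass_jitter_ppm = 3,
                       peak_width = 6, n_noise_traces = 400L,
                       amp_meanlog = log(1e6), amp_sdlog = 1,
                       min_peak_intensity = 50, seed = 1L) {
  stopifnot(n_runs >= 2, n_analytes >= 1, gradient_length > 0,
            scan_interval > 0, presence_prob >= 0, presence_prob <= 1,
            detection_prob >= 0, detection_prob <= 1,
            frac_incorrect_donors >= 0, frac_decoy_donors >= 0,
            rt_jitter_sd >= 0, mass_jitter_ppm >= 0, peak_width > 0,
            n_noise_traces >= 0)
  if (gradient_length / scan_interval < 2)
    stop("sim_config: fewer than 2 scans per run", call. = FALSE)
  cfg <- as.list(environment())
  cfg$n_runs <- as.integer(n_runs)
  cfg$n_analytes <- as.integer(n_analytes)
  cfg$n_noise_traces <- as.integer(n_noise_traces)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# random tryptic-like peptides: body without K/R, C-terminal K or R
random_peptides <- function(n, min_len = 7, max_len = 19) {
  body_aa <- setdiff(names(AA_MONO), c("K", "R"))
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(min_len:max_len, need, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste0(paste(sample(body_aa, L - 1, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1)), character(1))
    out <- unique(c(out, seqs))
  }
  out[seq_len(n)]
}

with_preserved_rng <- function(code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Simulate a complete multi-run LC-MS experiment
#'
#' Generates MS1 runs, a target-decoy PSM report and ground truth. Each
#' analyte receives a base RT uniform over the gradient, per-run RTs
#' through an affine warp plus jitter, and a Gaussian elution profile
#' whose isotopologue peaks follow the averagine-Poisson envelope at the
#' analyte's mass. Noise traces (same peak model, random mass and RT) are
#' added per run. MS2 detections of present analytes are sampled at the
#' detection probability; contaminant PSMs come in two flavours with
#' identical q-value distributions: incorrect target donors, whose
#' claimed peptide points at a different (mass within a few ppm of a real
#' analyte) or absent analyte, and decoy donors.
#'
#' @param config A [sim_config].
#' @return List with `runs` (list of [ms1_run]), `psms` (native PSM
#'   frame), `truth` (analyte table, presence/true-RT matrices, donor
#'   correctness), and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_rng({
    set.seed(config$seed)
    simulate_experiment_impl(config)
  })
}

simulate_experiment_impl <- function(cfg) {
  n <- cfg$n_analytes
  run_ids <- sprintf("run%02d", seq_len(cfg$n_runs))
  n_iso <- 5L

  peptides <- random_peptides(n + 2L)  # extras guard against collisions
  peptides <- peptides[seq_len(n)]
  mono_mass <- peptide_mono_mass(peptides)
  charge <- sample(2:3, n, replace = TRUE)
  amp <- stats::rlnorm(n, cfg$amp_meanlog, cfg$amp_sdlog)
  base_rt <- stats::runif(n, 0.03, 0.97) * cfg$gradient_length

  slope <- stats::runif(cfg$n_runs, cfg$warp_slope_range[1],
                        cfg$warp_slope_range[2])
  offset <- stats::runif(cfg$n_runs, cfg$warp_offset_range[1],
                         cfg$warp_offset_range[2])

  present <- matrix(stats::runif(n * cfg$n_runs) < cfg$presence_prob,
                    n, cfg$n_runs, dimnames = list(NULL, run_ids))
  true_rt <- matrix(NA_real_, n, cfg$n_runs,
                    dimnames = list(NULL, run_ids))
  for (r in seq_len(cfg$n_runs)) {
    rt <- slope[r] * base_rt + offset[r] +
      stats::rnorm(n, 0, cfg$rt_jitter_sd)
    rt <- pmin(pmax(rt, 3 * cfg$peak_width),
               cfg$gradient_length - 3 * cfg$peak_width)
    true_rt[, r] <- ifelse(present[, r], rt, NA_real_)
  }

  scan_rt <- seq(cfg$scan_interval, cfg$gradient_length,
                 by = cfg$scan_interval)

  # Gaussian elution profiles with Poisson-averagine envelopes for a set
  # of emitters (analytes and noise traces), fully vectorised
  emit_all <- function(mass, z, rt, a) {
    lo <- findInterval(rt - 3 * cfg$peak_width, scan_rt) + 1L
    hi <- pmin(findInterval(rt + 3 * cfg$peak_width, scan_rt),
               length(scan_rt))
    keep <- hi >= lo
    mass <- mass[keep]; z <- z[keep]; rt <- rt[keep]; a <- a[keep]
    lo <- lo[keep]; hi <- hi[keep]
    ns <- hi - lo + 1L
    e_of <- rep.int(seq_along(ns), ns)              # emitter per scan-row
    idx <- sequence(ns) + rep.int(lo - 1L, ns)      # scan index (1-based)
    prof <- a[e_of] * exp(-(scan_rt[idx] - rt[e_of])^2 /
                            (2 * cfg$peak_width^2))
    lam <- 4.88e-4 * mass
    ab <- vapply(seq_len(n_iso) - 1L, function(k) stats::dpois(k, lam),
                 numeric(length(mass)))             # emitters x iso
    if (length(mass) == 1L) ab <- matrix(ab, 1L)
    ab <- ab / rowSums(ab)
    sys_ppm <- stats::rnorm(length(mass), 0, cfg$mass_jitter_ppm)
    n_rows <- length(idx)
    iso_k <- rep(seq_len(n_iso) - 1L, each = n_rows)
    e_all <- rep.int(e_of, n_iso)
    idx_all <- rep.int(idx, n_iso)
    mz0 <- (mass[e_all] + iso_k * ISO_SPACING) / z[e_all] + PROTON_MASS
    jit <- sys_ppm[e_all] +
      stats::rnorm(n_rows * n_iso, 0, cfg$mass_jitter_ppm / 3)
    int <- rep.int(prof, n_iso) * ab[cbind(e_all, iso_k + 1L)]
    ok <- int >= cfg$min_peak_intensity
    data.frame(scan_index = idx_all[ok] - 1L,
               mz = (mz0 * (1 + jit * 1e-6))[ok],
               intensity = int[ok])
  }

  runs <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    which_p <- which(present[, r])
    peaks <- emit_all(mono_mass[which_p], charge[which_p],
                      true_rt[which_p, r], amp[which_p])
    if (cfg$n_noise_traces > 0L) {
      nz_mass <- stats::runif(cfg$n_noise_traces, 600, 4000)
      nz_z <- sample(2:3, cfg$n_noise_traces, replace = TRUE)
      nz_rt <- stats::runif(cfg$n_noise_traces, 3 * cfg$peak_width,
                            cfg$gradient_length - 3 * cfg$peak_width)
      nz_amp <- stats::rlnorm(cfg$n_noise_traces, cfg$amp_meanlog,
                              cfg$amp_sdlog)
      peaks <- rbind(peaks, emit_all(nz_mass, nz_z, nz_rt, nz_amp))
    }
    runs[[r]] <- ms1_run(run_ids[r], scan_rt, peaks,
                         gradient_length = cfg$gradient_length)
  }
  names(runs) <- run_ids

  # correct PSMs
  det <- present & matrix(stats::runif(n * cfg$n_runs) < cfg$detection_prob,
                          n, cfg$n_runs)
  psm_parts <- list()
  for (r in seq_len(cfg$n_runs)) {
    ai <- which(det[, r])
    if (!length(ai)) next
    psm_parts[[length(psm_parts) + 1L]] <- data.frame(
      run_id = run_ids[r],
      scan_id = sprintf("ms2_%s_%05d", run_ids[r], seq_along(ai)),
      peptide = peptides[ai], stem = peptides[ai],
      mono_mass = mono_mass[ai], charge = charge[ai],
      rt = true_rt[ai, r] + stats::rnorm(length(ai), 0, 1.5),
      score = stats::runif(length(ai), 60, 100),
      pep = stats::runif(length(ai), 0, 0.01),
      q_value = stats::runif(length(ai), 0, 0.001),
      is_decoy = FALSE,
      proteins = paste0("PROT_", peptides[ai]),
      stringsAsFactors = FALSE)
  }
  n_correct <- sum(vapply(psm_parts, nrow, integer(1)))

  # contaminant PSMs: incorrect targets and decoys, same q distribution
  n_inc <- round(cfg$frac_incorrect_donors * n_correct)
  n_dec <- round(cfg$frac_decoy_donors * n_correct)
  n_phantom <- n_inc + n_dec
  phantom_status <- character(0)
  if (n_phantom > 0L) {
    ph_pep <- random_peptides(n_phantom + n)  # draw fresh, avoid clashes
    ph_pep <- setdiff(ph_pep, peptides)[seq_len(n_phantom)]
    # half the phantoms sit within a few ppm of a real analyte's mass
    near <- stats::runif(n_phantom) < 0.5
    ph_mass <- ifelse(
      near,
      mono_mass[sample.int(n, n_phantom, replace = TRUE)] *
        (1 + stats::runif(n_phantom, -3, 3) * 1e-6),
      stats::runif(n_phantom, min(mono_mass), max(mono_mass)))
    ph_run <- sample(run_ids, n_phantom, replace = TRUE)
    ph_decoy <- rep(c(FALSE, TRUE), c(n_inc, n_dec))
    psm_parts[[length(psm_parts) + 1L]] <- data.frame(
      run_id = ph_run,
      scan_id = sprintf("ms2_ph_%05d", seq_len(n_phantom)),
      peptide = ph_pep, stem = ph_pep,
      mono_mass = ph_mass,
      charge = sample(2:3, n_phantom, replace = TRUE),
      rt = stats::runif(n_phantom, 3 * cfg$peak_width,
                        cfg$gradient_length - 3 * cfg$peak_width),
      score = stats::runif(n_phantom, 55, 95),
      pep = stats::runif(n_phantom, 0, 0.02),
      q_value = stats::runif(n_phantom, 0, 0.001),
      is_decoy = ph_decoy,
      proteins = paste0("PHANTOM_", ph_pep),
      stringsAsFactors = FALSE)
    phantom_status <- stats::setNames(rep("incorrect", n_phantom), ph_pep)
  }
  psms <- do.call(rbind, psm_parts)
  rownames(psms) <- NULL

  truth <- list(
    analytes = data.frame(peptide = peptides, mono_mass = mono_mass,
                          charge = charge, base_rt = base_rt, amp = amp,
                          stringsAsFactors = FALSE),
    present = present, true_rt = true_rt,
    donor_status = c(stats::setNames(rep("correct", n), peptides),
                     phantom_status),
    gradient_length = cfg$gradient_length)

  list(runs = runs, psms = psms, truth = truth, config = cfg)
}

#' True false-discovery proportion of accepted propagations
#'
#' A propagation is incorrect when its donor identity was wrong (phantom
#' or decoy peptide) or when the matched trace is not the donor analyte's
#' true trace in the acceptor run: the analyte must be present there and
#' the apex RT within 1% of the gradient length of its true RT.
#'
#' @param accepted Accepted propagations (`peptide`, `acceptor_run_id`,
#'   `apex_rt`).
#' @param truth Ground truth from [simulate_experiment].
#' @return Fraction incorrect; 0 for an empty set.
#' @export
true_fdp <- function(accepted, truth) {
  if (nrow(accepted) == 0L) return(0)
  status <- truth$donor_status[accepted$peptide]
  if (anyNA(status))
    stop("true_fdp: unknown peptide(s): ",
         paste(utils::head(accepted$peptide[is.na(status)], 3),
               collapse = ", "), call. = FALSE)
  idx <- match(accepted$peptide, truth$analytes$peptide)
  tol <- 0.01 * truth$gradient_length
  incorrect <- status != "correct"
  ok_rows <- which(!incorrect)
  for (i in ok_rows) {
    a <- idx[i]; r <- accepted$acceptor_run_id[i]
    tr <- truth$true_rt[a, r]
    if (is.na(tr) || abs(accepted$apex_rt[i] - tr) > tol)
      incorrect[i] <- TRUE
  }
  mean(incorrect)
}
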