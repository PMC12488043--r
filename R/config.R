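# Tunable parameters for the propagation pipeline. All RT values are in
# seconds, all mass tolerances in ppm unless stated otherwise.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the propagation pipeline in one
#' validated list. Defaults are the package's documented operating point;
#' any subset can be overridden.
#'
#' @param pip_fdr Target FDR among reported propagated identifications
#'   (alpha). Default 0.01.
#' @param donor_cap Global cap on the donor peptide q-value cutoff. The
#'   effective donor cutoff is `min(pip_fdr / 5, donor_cap)`. Default 0.01.
#' @param ppm_tolerance Peak matching tolerance in parts per million.
#' @param min_envelope_cos Minimum cosine similarity between observed and
#'   theoretical isotopic envelope intensities for a scan to be valid.
#' @param max_isotopologues Number of isotopologues of the theoretical
#'   envelope that are modelled (monoisotopic peak included).
#' @param initial_half_width Initial RT search-window half width, seconds.
#' @param max_half_width Maximal RT search-window half width, seconds.
#' @param expansion_step Window growth per expansion round, seconds.
#' @param gap_tolerance Number of consecutive invalid scans tolerated inside
#'   a peak trace (0 = traces are maximal runs of valid scans).
#' @param knn_anchors Number of nearest RT anchors used by the local
#'   alignment estimate.
#' @param min_anchors Minimum number of anchor pairs required before the
#'   alignment falls back to the identity mapping.
#' @param min_mass_gap,max_mass_gap Mass distance bounds (Da, exclusive low /
#'   inclusive high) for a peptide to serve as a randomized-RT anchor source.
#' @param min_rt_separation Minimum RT distance (seconds) between a donor and
#'   its randomized anchor source in the donor run. `NULL` means
#'   `2 * max_half_width`, which guarantees that the randomized window can
#'   never overlap the predicted one.
#' @param min_reference Minimum per-run size of the calibration reference
#'   population; below it calibration pools across runs.
#' @param max_reference Maximum number of MS2-anchored reference traces
#'   computed per run (a deterministic subsample keeps cost bounded).
#' @param min_for_ml Minimum number of candidates for semisupervised
#'   rescoring; below it the fallback `pep = 1 - combined_score` is used.
#' @param ml_rounds Rounds of semisupervised training.
#' @param ml_folds Number of cross-validation folds (split by donor peptide).
#' @param ml_top_frac Fraction of top-ordered candidates whose predicted-RT
#'   members serve as positive training examples.
#' @param xgb_nrounds,xgb_max_depth,xgb_eta Gradient-boosted tree
#'   hyperparameters for the rescoring classifier.
#' @param n_censor Number of peptides censored per run by the entrapment
#'   protocol's censoring step.
#' @param seed Global seed from which all per-(donor, acceptor-run) random
#'   streams are derived.
#' @return A named list of class `pip_config`.
#' @export
pip_config <- function(pip_fdr = 0.01,
                       donor_cap = 0.01,
                       ppm_tolerance = 10,
                       min_envelope_cos = 0.7,
                       max_isotopologues = 5,
                       initial_half_width = 30,
                       max_half_width = 150,
                       expansion_step = 30,
                       gap_tolerance = 0,
                       knn_anchors = 10,
                       min_anchors = 10,
                       min_mass_gap = 5,
                       max_mass_gap = 11,
                       min_rt_separation = NULL,
                       min_reference = 20,
                       max_reference = 300,
                       min_for_ml = 100,
                       ml_rounds = 5,
                       ml_folds = 3,
                       ml_top_frac = 0.25,
                       xgb_nrounds = 30,
                       xgb_max_depth = 3,
                       xgb_eta = 0.3,
                       n_censor = 500,
                       seed = 1L) {
  stopifnot(pip_fdr > 0, pip_fdr <= 1,
            donor_cap > 0, donor_cap <= 1,
            ppm_tolerance > 0,
            min_envelope_cos >= 0, min_envelope_cos <= 1,
            max_isotopologues >= 1,
            initial_half_width > 0,
            max_half_width >= initial_half_width,
            expansion_step > 0,
            gap_tolerance >= 0,
            knn_anchors >= 1, min_anchors >= 1,
            min_mass_gap >= 0, max_mass_gap > min_mass_gap,
            min_reference >= 1, min_for_ml >= 1,
            ml_rounds >= 1, ml_folds >= 2,
            ml_top_frac > 0, ml_top_frac <= 1,
            n_censor >= 1)
  if (is.null(min_rt_separation)) min_rt_separation <- 2 * max_half_width
  cfg <- list(
    pip_fdr = pip_fdr, donor_cap = donor_cap,
    ppm_tolerance = ppm_tolerance, min_envelope_cos = min_envelope_cos,
    max_isotopologues = as.integer(max_isotopologues),
    initial_half_width = initial_half_width,
    max_half_width = max_half_width, expansion_step = expansion_step,
    gap_tolerance = as.integer(gap_tolerance),
    knn_anchors = as.integer(knn_anchors),
    min_anchors = as.integer(min_anchors),
    min_mass_gap = min_mass_gap, max_mass_gap = max_mass_gap,
    min_rt_separation = min_rt_separation,
    min_reference = as.integer(min_reference),
    max_reference = as.integer(max_reference),
    min_for_ml = as.integer(min_for_ml),
    ml_rounds = as.integer(ml_rounds), ml_folds = as.integer(ml_folds),
    ml_top_frac = ml_top_frac,
    xgb_nrounds = as.integer(xgb_nrounds),
    xgb_max_depth = as.integer(xgb_max_depth), xgb_eta = xgb_eta,
    n_censor = as.integer(n_censor),
    seed = as.integer(seed))
  class(cfg) <- "pip_config"
  cfg
}

#' Donor peptide q-value cutoff for a requested propagation FDR
#'
#' The donor set is restricted to peptides discovered at a database-search
#' FDR of one fifth of the requested propagation FDR, capped at a global
#' ceiling (default 0.01). Requesting a 1% propagation FDR therefore
#' yields a donor q-value cutoff of 0.002, 2.5% yields 0.005, and 5%
#' yields 0.01.
#'
#' @param pip_fdr Requested propagation FDR (0 < pip_fdr <= 1).
#' @param donor_cap Global donor q-value ceiling.
#' @return The donor peptide q-value cutoff.
#' @export
donor_threshold <- function(pip_fdr, donor_cap = 0.01) {
  stopifnot(is.numeric(pip_fdr), length(pip_fdr) == 1L,
            pip_fdr > 0, pip_fdr <= 1)
  min(pip_fdr / 5, donor_cap)
}

# Physical constants (monoisotopic)
PROTON_MASS <- 1.007276466879
ISO_SPACING <- 1.0033548378  # average mass gap between isotopologues, Da

# Monoisotopic residue masses, Da
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_MASS <- 18.0105646863

#' Monoisotopic peptide mass
#'
#' @param sequence Character vector of peptide sequences over the 20-letter
#'   amino-acid alphabet.
#' @return Numeric vector of monoisotopic masses in Da.
#' @export
peptide_mono_mass <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(aa, names(AA_MONO))
    if (length(bad))
      stop("invalid residue(s): ", paste(unique(bad), collapse = ", "))
    sum(AA_MONO[aa]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

# Deterministic 31-bit string hash for per-object RNG streams.
str_hash31 <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Draw deterministically from a stream derived from (seed, key) without
# disturbing the caller's RNG state.
stream_draw <- function(seed, key, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.numeric(seed) + str_hash31(key)) %% 2147483647)
  sample.int(n, 1L)
}
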