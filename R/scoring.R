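# Match features, empirical calibration against MS2-anchored traces, the
# geometric-mean combined score, and iterative semisupervised PEP
# assignment with gradient-boosted trees.

FEATURE_NAMES <- c("mass_error", "log_intensity", "rt_diff",
                   "envelope_similarity", "n_valid_scans")
# which tail counts as "extreme" during calibration
FEATURE_DIRECTION <- c(mass_error = "high", log_intensity = "low",
                       rt_diff = "high", envelope_similarity = "low",
                       n_valid_scans = "low")

#' Raw match features for a candidate trace
#'
#' * `mass_error`: absolute difference between the observed most-abundant
#'   isotopologue's neutral mass and the theoretical one, in ppm.
#' * `log_intensity`: natural log of the summed apex isotopologue
#'   intensity.
#' * `rt_diff`: absolute apex-RT minus anchor-RT, seconds.
#' * `envelope_similarity`: cosine between observed and theoretical
#'   isotopologue intensities at the apex.
#' * `n_valid_scans`: number of valid scans in the trace.
#'
#' @param trace A `peak_trace`.
#' @param anchor_rt Anchor RT in seconds.
#' @return One-row data frame with the five features.
#' @export
compute_features <- function(trace, anchor_rt) {
  stopifnot(inherits(trace, "peak_trace"))
  env <- trace$envelope
  obs_neutral <- (trace$mz_obs - PROTON_MASS) * trace$charge -
    env$most_abundant_index * ISO_SPACING
  data.frame(
    mass_error = abs(obs_neutral - trace$mono_mass) / trace$mono_mass * 1e6,
    log_intensity = log(trace$intensity),
    rt_diff = abs(trace$apex_rt - anchor_rt),
    envelope_similarity = trace$envelope_cos,
    n_valid_scans = as.numeric(trace$n_valid_scans))
}

# Same features from the compiled core's trace matrix (hot path).
# Returns a matrix with one column per feature.
features_from_matrix <- function(m, anchor_rt, mono_mass, charge,
                                 config = pip_config(), envelope = NULL) {
  if (is.null(envelope)) envelope <- theoretical_envelope(mono_mass, config)
  obs_neutral <- (m[, "mz_obs"] - PROTON_MASS) * charge -
    envelope$most_abundant_index * ISO_SPACING
  out <- cbind(
    mass_error = abs(obs_neutral - mono_mass) / mono_mass * 1e6,
    log_intensity = log(m[, "intensity"]),
    rt_diff = abs(m[, "apex_rt"] - anchor_rt),
    envelope_similarity = m[, "envelope_cos"],
    n_valid_scans = m[, "n_valid_scans"])
  rownames(out) <- NULL
  out
}

#' Calibration reference population
#'
#' Wraps the feature vectors of traces unambiguously associated with
#' MS2-detected peptides (of one acceptor run, or pooled) for use as an
#' empirical null in [calibrate_feature].
#'
#' @param features Data frame or matrix with the columns named in
#'   `FEATURE_NAMES`.
#' @return Object of class `pip_reference` holding one sorted vector per
#'   feature.
#' @export
reference_population <- function(features) {
  stopifnot(all(FEATURE_NAMES %in% colnames(features)),
            nrow(features) >= 1L)
  structure(lapply(stats::setNames(FEATURE_NAMES, FEATURE_NAMES),
                   function(f) sort(features[, f])),
            n = nrow(features), class = "pip_reference")
}

#' Calibrate one feature value against a reference population
#'
#' Returns the proportion of reference values at least as extreme as the
#' observed one, floored at `1/(n + 1)` so the result is strictly
#' positive. For `direction = "high"` larger values are more extreme; for
#' `"low"`, smaller.
#'
#' @param value Numeric vector of observed feature values.
#' @param reference Numeric vector of reference values (non-empty).
#' @param direction `"high"` or `"low"`.
#' @return Calibrated probabilities in `(0, 1]`.
#' @export
calibrate_feature <- function(value, reference, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (length(reference) == 0L)
    stop("empty calibration reference", call. = FALSE)
  calibrate_sorted(value, sort(reference), direction == "high")
}

# hot path: reference already sorted, no arg checking
calibrate_sorted <- function(value, sorted_ref, high) {
  n <- length(sorted_ref)
  cnt <- if (high) {
    n - findInterval(value, sorted_ref, left.open = TRUE)  # #{r >= v}
  } else {
    findInterval(value, sorted_ref)                        # #{r <= v}
  }
  pmax(cnt / n, 1 / (n + 1))
}

# Calibrate a full feature matrix; returns a matrix with one column per
# feature, values in (0, 1].
calibrate_features <- function(features, reference) {
  stopifnot(inherits(reference, "pip_reference"))
  out <- matrix(0, nrow(features), length(FEATURE_NAMES),
                dimnames = list(NULL, FEATURE_NAMES))
  for (f in FEATURE_NAMES)
    out[, f] <- calibrate_sorted(features[, f], reference[[f]],
                                 FEATURE_DIRECTION[[f]] == "high")
  out
}

#' Combined match score
#'
#' Geometric mean of the calibrated feature scores.
#'
#' @param calibrated Numeric vector of calibrated probabilities in
#'   `(0, 1]`.
#' @return The geometric mean, in `(0, 1]`.
#' @export
combined_score <- function(calibrated) {
  if (any(calibrated <= 0))
    stop("calibrated scores must be > 0", call. = FALSE)
  exp(mean(log(calibrated)))
}

combined_score_matrix <- function(cal) {
  if (any(cal <= 0)) stop("calibrated scores must be > 0", call. = FALSE)
  exp(rowMeans(log(cal)))
}

ml_feature_matrix <- function(candidates) {
  as.matrix(candidates[, c(FEATURE_NAMES,
                           paste0("cal_", FEATURE_NAMES),
                           "combined_score")])
}

#' Semisupervised PEP assignment
#'
#' Percolator-style iterative rescoring. Candidates are split into
#' `config$ml_folds` cross-validation folds by donor peptide (all of a
#' donor's candidates share a fold). In each of `config$ml_rounds` rounds,
#' positive training examples are the non-decoy predicted-RT candidates
#' among the top `config$ml_top_frac` of all candidates by the current
#' ordering (round 1: combined score descending; later rounds: previous
#' PEP ascending); negatives are all randomized-RT candidates. A
#' gradient-boosted tree classifier is trained on the other folds and
#' scores the held-out fold; the posterior error probability is then an
#' isotonic fit of the incorrect-label indicator (randomized = 1) against
#' the held-out classifier score.
#'
#' With fewer than `config$min_for_ml` candidates, or no randomized-RT
#' candidates to learn from, the fallback `pep = 1 - combined_score` is
#' used.
#'
#' @param candidates Candidate data frame (needs the raw and calibrated
#'   feature columns, `combined_score`, `donor_key`, `anchor_kind`,
#'   `is_decoy`).
#' @param config A [pip_config].
#' @return `candidates` with a `pep` column; fold assignment and per-round
#'   train/score bookkeeping are attached as attribute `ml_diagnostics`.
#' @export
assign_pep <- function(candidates, config = pip_config()) {
  n <- nrow(candidates)
  neg <- candidates$anchor_kind == "randomized"
  if (n < config$min_for_ml || !any(neg) || all(neg)) {
    candidates$pep <- 1 - candidates$combined_score
    attr(candidates, "ml_diagnostics") <- list(used_ml = FALSE)
    return(candidates)
  }
  keys <- unique(candidates$donor_key)
  perm <- order(str_hash31(paste0(keys, "\rfold\r", config$seed)), keys)
  folds_of_keys <- integer(length(keys))
  folds_of_keys[perm] <- rep_len(seq_len(config$ml_folds), length(keys))
  fold_of_key <- stats::setNames(folds_of_keys, keys)
  fold <- unname(fold_of_key[candidates$donor_key])
  X <- ml_feature_matrix(candidates)
  score <- candidates$combined_score
  pep <- NULL
  rounds_log <- vector("list", config$ml_rounds)
  for (round in seq_len(config$ml_rounds)) {
    # ties in pep are broken by the fold-independent combined score, so
    # tied candidates from different cross-validation folds interleave
    ord <- if (round == 1L) order(-score, candidates$donor_key)
           else order(pep, -candidates$combined_score,
                      candidates$donor_key)
    top <- ord[seq_len(ceiling(config$ml_top_frac * n))]
    pos <- intersect(top, which(candidates$anchor_kind == "predicted" &
                                  !candidates$is_decoy))
    neg_idx <- which(neg)
    raw <- numeric(n)
    trained <- vector("list", config$ml_folds)
    for (f in seq_len(config$ml_folds)) {
      train <- c(pos[fold[pos] != f], neg_idx[fold[neg_idx] != f])
      if (!any(fold[neg_idx] != f) || !any(fold[pos] != f)) {
        candidates$pep <- 1 - candidates$combined_score
        attr(candidates, "ml_diagnostics") <- list(used_ml = FALSE)
        warning("a training partition lacked positive or negative ",
                "examples; PEP fallback used", call. = FALSE)
        return(candidates)
      }
      y <- as.numeric(seq_len(n) %in% pos)[train]
      bst <- xgboost::xgboost(
        x = X[train, , drop = FALSE], y = factor(y, levels = c(0, 1)),
        nrounds = config$xgb_nrounds,
        max_depth = config$xgb_max_depth,
        learning_rate = config$xgb_eta,
        objective = "binary:logistic",
        nthreads = 1, seed = config$seed, verbosity = 0)
      test <- which(fold == f)
      raw[test] <- predict(bst, X[test, , drop = FALSE])
      trained[[f]] <- list(train_folds = sort(unique(fold[train])),
                           scored_fold = f)
    }
    # fold models score on different scales; standardise each fold's
    # held-out logit scores against its own negatives so the pooled
    # ordering interleaves folds instead of stacking one fold on top
    lg <- stats::qlogis(pmin(pmax(raw, 1e-7), 1 - 1e-7))
    for (f in seq_len(config$ml_folds)) {
      test <- which(fold == f)
      ref <- lg[test[neg[test]]]
      if (length(ref) < 5L) ref <- lg[test]
      s <- stats::sd(ref)
      if (!is.finite(s) || s < 1e-9) s <- 1
      raw[test] <- (lg[test] - stats::median(ref)) / s
    }
    pep <- isotonic_pep(raw, as.numeric(neg))
    score <- raw
    rounds_log[[round]] <- trained
  }
  candidates$pep <- pep
  attr(candidates, "ml_diagnostics") <-
    list(used_ml = TRUE, fold = fold, rounds = rounds_log)
  candidates
}

# Monotone (non-increasing in score) calibration of the incorrect-label
# indicator: isotonic regression of y on -score.
isotonic_pep <- function(score, y) {
  o <- order(-score, y)
  fit <- stats::isoreg(x = seq_along(score), y = y[o])$yf
  # average fitted values over tied scores so equal scores get equal peps
  s_sorted <- score[o]
  grp <- cumsum(!duplicated(s_sorted))
  fit <- stats::ave(fit, grp)
  pep <- numeric(length(score))
  pep[o] <- pmin(1, pmax(0, fit))
  pep
}
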