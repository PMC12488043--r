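# The two-proteome protocol for estimating the realized false-discovery
# proportion (FDP) of a propagation tool: MS2 censoring to measure the
# native peak-matching error rate, classification of propagations in pure
# (single-species) runs, and the three-component estimate
#   eFDP = (eFPE + ePIE + eNPE) / |propagations|,
# where eFPE counts foreign-species propagations directly, ePIE scales the
# entrapment count by the database ratio S, and eNPE applies the censored
# native error rate to the species-correct propagations.

#' Select peptides to censor in one run
#'
#' Filters the run's detections by the four protocol criteria — peptide
#' q-value below `q_max`, membership in the `"human"` (target-species)
#' proteome only, a higher-scoring detection of the same peptide in some
#' other run, and exactly one MS2 spectrum in this run — then samples
#' `n_censor` of them uniformly without replacement (all, with a warning,
#' if fewer qualify).
#'
#' @param psms PSM data frame covering all runs.
#' @param run_id The run to censor.
#' @param membership Named character vector mapping peptides to
#'   `"human"`, `"foreign"` or `"entrapment"`.
#' @param n_censor Number of peptides to censor.
#' @param q_max Detection confidence cutoff (default 0.001, i.e. 0.1%).
#' @param seed RNG seed for the sampling.
#' @return Object of class `censor_plan`: data frame `peptide`,
#'   `scan_id` with attributes `run_id` and `n_requested`.
#' @export
select_censor_set <- function(psms, run_id, membership, n_censor = 500,
                              q_max = 0.001, seed = 1L) {
  in_run <- psms[psms$run_id == run_id & !psms$is_decoy, , drop = FALSE]
  n_in_run <- table(in_run$peptide)
  other <- psms[psms$run_id != run_id & !psms$is_decoy, , drop = FALSE]
  best_other <- tapply(other$score, other$peptide, max)
  memb <- membership[in_run$peptide]
  qualifies <- in_run$q_value < q_max &
    !is.na(memb) & memb == "human" &
    n_in_run[in_run$peptide] == 1L &
    in_run$peptide %in% names(best_other) &
    best_other[in_run$peptide] > in_run$score
  pool <- in_run[which(qualifies), c("peptide", "scan_id"), drop = FALSE]
  if (nrow(pool) == 0L) {
    warning("no peptides qualify for censoring in ", run_id,
            call. = FALSE)
    plan <- pool
  } else if (nrow(pool) <= n_censor) {
    if (nrow(pool) < n_censor)
      warning("only ", nrow(pool), " qualifying peptides (< ", n_censor,
              ") in ", run_id, call. = FALSE)
    plan <- pool
  } else {
    idx <- with_preserved_rng({
      set.seed(seed)
      sample.int(nrow(pool), n_censor)
    })
    plan <- pool[sort(idx), , drop = FALSE]
  }
  rownames(plan) <- NULL
  attr(plan, "run_id") <- run_id
  attr(plan, "n_requested") <- n_censor
  class(plan) <- c("censor_plan", class(plan))
  plan
}

#' Censor MS2 spectra in a data file
#'
#' Replaces the peak list of every planned MS2 spectrum with a single
#' peak at 150 m/z; all other content, including every MS1 spectrum, is
#' untouched. For the native long-format spectra TSV (columns
#' `scan_id, ms_level, rt_seconds, mz, intensity`) the edit is textual,
#' so the un-censored lines are byte-identical to the input. The mzML
#' path (via `mzR`) rewrites the file with the planned spectra replaced;
#' scan ids are matched against the spectrum acquisition numbers.
#'
#' @param spectra_path Input file.
#' @param plan A `censor_plan` (or data frame with `scan_id`).
#' @param out_path Output file.
#' @param format `"spectra_tsv"` or `"mzml"`.
#' @export
censor_file <- function(spectra_path, plan, out_path,
                        format = c("spectra_tsv", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(spectra_path))
    stop("no such file: ", spectra_path, call. = FALSE)
  targets <- unique(as.character(plan$scan_id))
  if (format == "spectra_tsv") {
    lines <- readLines(spectra_path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    req <- c("scan_id", "ms_level", "rt_seconds", "mz", "intensity")
    require_columns(header, req, "spectra_tsv")
    ci <- match(req, header)
    fields <- strsplit(lines[-1], "\t", fixed = TRUE)
    scan_of <- vapply(fields, `[`, character(1), ci[1])
    missing <- setdiff(targets, scan_of)
    if (length(missing))
      stop("censor plan names scan(s) absent from file: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    lvl_of <- vapply(fields, `[`, character(1), ci[2])
    bad <- targets[!targets %in% scan_of[lvl_of == "2"]]
    if (length(bad))
      stop("planned scan(s) are not MS2 spectra: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    out <- character(0)
    i <- 1L
    n <- length(fields)
    body <- lines[-1]
    while (i <= n) {
      s <- scan_of[i]
      j <- i
      while (j < n && scan_of[j + 1L] == s) j <- j + 1L
      if (s %in% targets) {
        f <- fields[[i]]
        f[ci[4]] <- "150"
        f[ci[5]] <- "1"
        out <- c(out, paste(f, collapse = "\t"))
      } else {
        out <- c(out, body[i:j])
      }
      i <- j + 1L
    }
    writeLines(c(lines[1], out), out_path)
    return(invisible(out_path))
  }
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("censoring mzML requires the 'mzR' package", call. = FALSE)
  fh <- mzR::openMSfile(spectra_path)
  hd <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  mzR::close(fh)
  acq <- as.character(hd$acquisitionNum)
  hit <- match(targets, acq)
  if (anyNA(hit))
    stop("censor plan names scan(s) absent from file: ",
         paste(utils::head(targets[is.na(hit)], 5), collapse = ", "),
         call. = FALSE)
  if (any(hd$msLevel[hit] != 2L))
    stop("planned scan(s) are not MS2 spectra", call. = FALSE)
  for (i in hit) {
    pk[[i]] <- matrix(c(150, 1), nrow = 1,
                      dimnames = list(NULL, c("mz", "intensity")))
    hd$peaksCount[i] <- 1L
  }
  mzR::writeMSData(pk, out_path, header = hd)
  invisible(out_path)
}

#' Native peak-matching error rate from censoring pairs
#'
#' A pair (original-analysis apex RT, censored-analysis propagation RT)
#' of the same peptide and run counts as a native peak error when the
#' absolute RT difference exceeds 1% of the gradient length (54 s for a
#' 90-minute gradient).
#'
#' @param pairs Data frame with columns `ms2_rt` and `pip_rt`, seconds,
#'   pooled across runs.
#' @param gradient_length Gradient length, seconds.
#' @return List with `rate`, `n_errors`, `n_pairs` and `threshold`.
#' @export
native_error_rate <- function(pairs, gradient_length) {
  stopifnot(gradient_length > 0)
  if (nrow(pairs) == 0L)
    stop("native_error_rate: no pairs", call. = FALSE)
  threshold <- 0.01 * gradient_length
  err <- abs(pairs$ms2_rt - pairs$pip_rt) > threshold
  list(rate = mean(err), n_errors = sum(err), n_pairs = nrow(pairs),
       threshold = threshold)
}

#' Classify propagations in pure runs
#'
#' Foreign-species propagations whose peptide was itself MS2-detected in
#' a pure run are flagged `carryover_removed` (genuine analyte carried
#' over by the LC system, not a propagation error); all others take their
#' database membership.
#'
#' @param pips Data frame with a `peptide` column (propagations reported
#'   in pure runs).
#' @param membership Named character vector mapping peptides to
#'   `"human"`, `"foreign"` or `"entrapment"` (ambiguous peptides must be
#'   excluded beforehand).
#' @param foreign_ms2 Character vector of foreign peptides MS2-detected
#'   in pure runs.
#' @return Character vector per row: `human`, `foreign`, `entrapment` or
#'   `carryover_removed`.
#' @export
classify_pip <- function(pips, membership, foreign_ms2 = character(0)) {
  m <- membership[pips$peptide]
  if (anyNA(m))
    stop("classify_pip: peptide(s) absent from membership: ",
         paste(utils::head(pips$peptide[is.na(m)], 3), collapse = ", "),
         call. = FALSE)
  cls <- unname(m)
  cls[cls == "foreign" & pips$peptide %in% foreign_ms2] <-
    "carryover_removed"
  cls
}

#' Three-component FDP estimate
#'
#' From the classified propagations of the pure runs (carryovers already
#' removed): `eFPE` is the foreign count, `ePIE` the entrapment count
#' scaled by the database ratio `S`, and `eNPE` the human count times the
#' censoring-derived native error rate. `eFDP` is their sum over the
#' number of propagations.
#'
#' @param classes Character vector from [classify_pip];
#'   `carryover_removed` entries are dropped here.
#' @param S Database scaling factor (> 1); see
#'   [entrapment_scale_factor].
#' @param native_rate Native peak-matching error rate in `[0, 1]`; see
#'   [native_error_rate].
#' @return Object of class `fdp_estimate`: list with `n_pips`, the
#'   component counts `eFPE`, `ePIE`, `eNPE`, `eFDP`, and the
#'   per-component FDP fractions `fdp_foreign`, `fdp_identification`,
#'   `fdp_native`.
#' @export
estimate_fdp <- function(classes, S, native_rate) {
  stopifnot(S > 1, native_rate >= 0, native_rate <= 1)
  classes <- classes[classes != "carryover_removed"]
  n <- length(classes)
  if (n == 0L) stop("estimate_fdp: no propagations", call. = FALSE)
  n_h <- sum(classes == "human")
  n_f <- sum(classes == "foreign")
  n_e <- sum(classes == "entrapment")
  eFPE <- n_f
  ePIE <- n_e * S
  eNPE <- n_h * native_rate
  out <- list(n_pips = n, eFPE = eFPE, ePIE = ePIE, eNPE = eNPE,
              S = S, native_rate = native_rate,
              eFDP = (eFPE + ePIE + eNPE) / n,
              fdp_foreign = eFPE / n,
              fdp_identification = ePIE / n,
              fdp_native = eNPE / n)
  class(out) <- "fdp_estimate"
  out
}

#' @export
print.fdp_estimate <- function(x, ...) {
  cat("<fdp_estimate> n =", x$n_pips, "\n")
  cat(sprintf("  eFPE %.1f  ePIE %.1f (S = %.3f)  eNPE %.1f (rate %.4f)\n",
              x$eFPE, x$ePIE, x$S, x$eNPE, x$native_rate))
  cat(sprintf("  eFDP = %.4f (foreign %.4f, identification %.4f, native %.4f)\n",
              x$eFDP, x$fdp_foreign, x$fdp_identification, x$fdp_native))
  invisible(x)
}

#' Simulate a two-proteome propagation study with a known error mix
#'
#' Generates the inputs of the FDP protocol with planted ground truth:
#' each propagation into the pure runs is correct-human, a native peak
#' error (human identity, wrong peak), a foreign peak-matching error, or
#' a peptide-identification error. Identification errors hit the
#' entrapment segment with probability `1/S` and are otherwise labelled
#' human, mirroring the database proportions. Censoring pairs with the
#' same native error rate and a set of carryover foreign detections are
#' generated alongside.
#'
#' @param n_pips Number of propagations into pure runs.
#' @param p_native Native peak-matching error probability.
#' @param p_foreign Foreign peak-matching error probability.
#' @param p_ident Peptide-identification error probability.
#' @param S Database scaling factor.
#' @param n_pairs Number of censoring comparison pairs.
#' @param n_carryover Foreign propagations explained by carryover (their
#'   peptides appear in `foreign_ms2`).
#' @param gradient_length Gradient length, seconds.
#' @param seed RNG seed.
#' @return List with `pips` (peptide, truth flag), `membership`,
#'   `foreign_ms2`, `pairs` (`ms2_rt`, `pip_rt`), `gradient_length`, `S`
#'   and `true_fdp` (fraction of incorrect propagations after carryover
#'   removal).
#' @export
simulate_entrapment_study <- function(n_pips = 5000, p_native = 0.01,
                                      p_foreign = 0.006, p_ident = 0.02,
                                      S = 1.86, n_pairs = 4000,
                                      n_carryover = 20,
                                      gradient_length = 5400, seed = 1L) {
  stopifnot(p_native + p_foreign + p_ident < 1, S > 1)
  with_preserved_rng({
    set.seed(seed)
    kind <- sample(c("correct", "native_err", "foreign_err", "ident_err"),
                   n_pips, replace = TRUE,
                   prob = c(1 - p_native - p_foreign - p_ident,
                            p_native, p_foreign, p_ident))
    # identification errors land in the entrapment segment w.p. 1/S
    ident_entrap <- kind == "ident_err" & stats::runif(n_pips) < 1 / S
    label <- ifelse(kind == "foreign_err", "foreign",
                    ifelse(ident_entrap, "entrapment", "human"))
    peptide <- sprintf("PEP%06d", seq_len(n_pips))
    correct <- kind == "correct"
    # carryover: genuine foreign analytes, detected and propagated
    co_pep <- sprintf("CARRY%04d", seq_len(n_carryover))
    pips <- data.frame(
      peptide = c(peptide, co_pep),
      truth = c(ifelse(correct, "correct", "incorrect"),
                rep("carryover", n_carryover)),
      stringsAsFactors = FALSE)
    membership <- c(stats::setNames(label, peptide),
                    stats::setNames(rep("foreign", n_carryover), co_pep))
    thr <- 0.01 * gradient_length
    is_err <- stats::runif(n_pairs) < p_native
    diff <- ifelse(is_err, stats::runif(n_pairs, thr, 5 * thr),
                   stats::runif(n_pairs, 0, thr))
    ms2_rt <- stats::runif(n_pairs, 0, gradient_length)
    pairs <- data.frame(ms2_rt = ms2_rt,
                        pip_rt = ms2_rt + sample(c(-1, 1), n_pairs,
                                                 replace = TRUE) * diff)
    list(pips = pips, membership = membership, foreign_ms2 = co_pep,
         pairs = pairs, gradient_length = gradient_length, S = S,
         true_fdp = mean(!correct))
  })
}
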