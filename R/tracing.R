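# Isotopic envelopes, peak-trace discovery in an RT window, apex selection
# and the expanding-window search. The per-scan matching work is done in
# compiled code (src/traces.cpp); this file owns the model and the window
# logic.

#' Theoretical isotopic envelope for a peptide mass
#'
#' Averagine-style Poisson model: the relative abundance of isotopologue
#' `i` is `Poisson(i; lambda)` with `lambda = 4.88e-4 * mono_mass`,
#' truncated at `config$max_isotopologues` isotopologues and renormalised.
#'
#' @param mono_mass Monoisotopic mass in Da (> 0).
#' @param config A [pip_config].
#' @return List of class `isotopic_envelope` with `relative_abundances`
#'   (sums to 1) and `most_abundant_index` (0-based; ties resolve to the
#'   lowest index).
#' @export
theoretical_envelope <- function(mono_mass, config = pip_config()) {
  stopifnot(mono_mass > 0)
  lambda <- 4.88e-4 * mono_mass
  k <- seq_len(config$max_isotopologues) - 1L
  ab <- stats::dpois(k, lambda)
  ab <- ab / sum(ab)
  structure(list(relative_abundances = ab,
                 most_abundant_index = which.max(ab) - 1L),
            class = "isotopic_envelope")
}

# m/z of each modelled isotopologue at a given charge
isotopologue_mz <- function(mono_mass, charge, n_iso) {
  (mono_mass + (seq_len(n_iso) - 1L) * ISO_SPACING) / charge + PROTON_MASS
}

# All traces for (mono_mass, charge) in a run, as the compiled core's
# matrix. No window filtering. Internal hot path.
find_traces_matrix <- function(run, mono_mass, charge,
                               config = pip_config(), detail = FALSE) {
  env <- theoretical_envelope(mono_mass, config)
  res <- find_traces_cpp(run$peaks$mz, run$peaks$intensity,
                         run$peaks$scan_index, run$scan_rt,
                         isotopologue_mz(mono_mass, charge,
                                         config$max_isotopologues),
                         env$relative_abundances,
                         env$most_abundant_index,
                         config$ppm_tolerance, config$min_envelope_cos,
                         config$gap_tolerance, detail)
  res$envelope <- env
  res
}

trace_object <- function(run, charge, mono_mass, row, det, envelope) {
  structure(list(
    run_id = run$run_id, charge = as.integer(charge),
    mono_mass = mono_mass,
    scan_start = as.integer(row[["start_scan"]]),
    scan_end = as.integer(row[["end_scan_excl"]]),  # half-open
    scan_index = as.integer(det$scans),
    scan_rt = as.numeric(det$rt),
    scan_log_sum = as.numeric(det$log_sum),
    scan_cos = as.numeric(det$cos),
    iso_intensity = det$iso,
    apex_scan_index = as.integer(row[["apex_scan"]]),
    apex_rt = as.numeric(row[["apex_rt"]]),
    intensity = as.numeric(row[["intensity"]]),
    envelope_cos = as.numeric(row[["envelope_cos"]]),
    mz_obs = as.numeric(row[["mz_obs"]]),
    n_valid_scans = as.integer(row[["n_valid_scans"]]),
    envelope = envelope), class = "peak_trace")
}

#' @export
print.peak_trace <- function(x, ...) {
  cat("<peak_trace> run ", x$run_id, " z=", x$charge,
      " scans [", x$scan_start, ",", x$scan_end, ") apex ",
      x$apex_scan_index, " @ ", round(x$apex_rt, 2), " s, intensity ",
      signif(x$intensity, 4), "\n", sep = "")
  invisible(x)
}

#' Find eligible peak traces in an RT window
#'
#' A scan is valid for a donor peptide at a charge if it contains a peak
#' within `config$ppm_tolerance` of the theoretical most abundant
#' isotopologue m/z and the cosine between the observed matched
#' isotopologue intensities and the theoretical envelope is at least
#' `config$min_envelope_cos`. Maximal runs of consecutive valid scans
#' form traces; a trace is eligible when its apex RT lies inside the
#' half-open window `[anchor - half_width, anchor + half_width)`.
#'
#' @param run An [ms1_run].
#' @param donor Donor row (needs `mono_mass`).
#' @param charge Charge state to search.
#' @param window List with `anchor_rt` and `half_width` (seconds).
#' @param config A [pip_config].
#' @return List of `peak_trace` objects (possibly empty).
#' @export
find_eligible_traces <- function(run, donor, charge, window,
                                 config = pip_config()) {
  res <- find_traces_matrix(run, donor$mono_mass, charge, config,
                            detail = TRUE)
  m <- res$traces
  if (nrow(m) == 0L) return(list())
  keep <- which(m[, "apex_rt"] >= window$anchor_rt - window$half_width &
                  m[, "apex_rt"] < window$anchor_rt + window$half_width)
  lapply(keep, function(i)
    trace_object(run, charge, donor$mono_mass, m[i, ], res$detail[[i]],
                 res$envelope))
}

#' Apex scan of a peak trace
#'
#' The member scan with the maximal sum of log-intensities over matched
#' isotopologue peaks; ties resolve to the lowest scan index.
#'
#' @param trace A `peak_trace`.
#' @return The apex scan index (0-based).
#' @export
apex_scan <- function(trace) {
  stopifnot(inherits(trace, "peak_trace"), length(trace$scan_index) >= 1L)
  trace$scan_index[which.max(trace$scan_log_sum)]
}

#' Trace intensity summary
#'
#' Sum of the matched isotopologue peak intensities at the apex scan.
#'
#' @param trace A `peak_trace`.
#' @return Summed apex intensity (arbitrary units).
#' @export
trace_intensity <- function(trace) {
  stopifnot(inherits(trace, "peak_trace"))
  i <- which(trace$scan_index == trace$apex_scan_index)
  sum(trace$iso_intensity[i, ])
}

# Window filter + best-trace pick on the matrix representation; used by
# both the public expanding search and the pipeline. `scorer` maps the
# eligible sub-matrix (+ anchor) to one score per row, higher better.
pick_best_trace <- function(m, anchor_rt, half_width, scorer) {
  keep <- which(m[, "apex_rt"] >= anchor_rt - half_width &
                  m[, "apex_rt"] < anchor_rt + half_width)
  if (length(keep) == 0L) return(NULL)
  sub <- m[keep, , drop = FALSE]
  sc <- scorer(sub, anchor_rt)
  # deterministic tie-break: higher intensity, then earlier scan
  o <- order(-sc, -sub[, "intensity"], sub[, "apex_scan"])[1L]
  list(row = sub[o, ], score = sc[o])
}

#' Expanding-window trace search
#'
#' Searches all observed charges of a donor peptide around an anchor RT.
#' Starting from `config$initial_half_width`, the half width grows by
#' `config$expansion_step` seconds until at least one eligible trace is
#' found (the highest combined-score trace at that width is returned) or
#' `config$max_half_width` is exceeded.
#'
#' @param run An [ms1_run].
#' @param donor Donor row (needs `mono_mass`, `observed_charges`).
#' @param anchor_rt Anchor RT in seconds (predicted or randomized).
#' @param config A [pip_config].
#' @param reference Optional calibration reference (see
#'   [reference_population]) used for combined-score ranking when several
#'   traces fall inside one window; without it traces are ranked by
#'   envelope cosine.
#' @return `NULL` if nothing is found, else a list with `trace` (a
#'   `peak_trace`), `charge` and `half_width`.
#' @export
search_with_expansion <- function(run, donor, anchor_rt,
                                  config = pip_config(),
                                  reference = NULL) {
  charges <- parse_charges(donor$observed_charges)
  per_charge <- lapply(charges, function(z)
    find_traces_matrix(run, donor$mono_mass, z, config, detail = TRUE))
  names(per_charge) <- as.character(charges)
  hit <- search_expansion_core(per_charge, charges, donor, anchor_rt,
                               config, reference)
  if (is.null(hit)) return(NULL)
  res <- per_charge[[as.character(hit$charge)]]
  i <- hit$index
  list(trace = trace_object(run, hit$charge, donor$mono_mass,
                            res$traces[i, ], res$detail[[i]],
                            res$envelope),
       charge = hit$charge, half_width = hit$half_width)
}

# Expansion over precomputed per-charge trace matrices. Returns charge,
# row index and half width of the winning trace, or NULL.
search_expansion_core <- function(per_charge, charges, donor, anchor_rt,
                                  config, reference) {
  widths <- seq(config$initial_half_width, config$max_half_width,
                by = config$expansion_step)
  scorer <- make_trace_scorer(donor, reference, config)
  for (hw in widths) {
    best <- NULL
    for (ci in seq_along(charges)) {
      m <- per_charge[[ci]]$traces
      if (nrow(m) == 0L) next
      keep <- which(m[, "apex_rt"] >= anchor_rt - hw &
                      m[, "apex_rt"] < anchor_rt + hw)
      if (length(keep) == 0L) next
      sc <- scorer(m[keep, , drop = FALSE], anchor_rt, charges[ci])
      for (j in seq_along(keep)) {
        cand <- list(charge = charges[ci], index = keep[j],
                     half_width = hw, score = sc[j],
                     intensity = m[keep[j], "intensity"],
                     apex = m[keep[j], "apex_scan"])
        if (is.null(best) || cand$score > best$score ||
            (cand$score == best$score &&
             (cand$intensity > best$intensity ||
              (cand$intensity == best$intensity && cand$apex < best$apex))))
          best <- cand
      }
    }
    if (!is.null(best))
      return(best[c("charge", "index", "half_width", "score")])
  }
  NULL
}

parse_charges <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  sort(unique(as.integer(strsplit(as.character(x), ";", fixed = TRUE)[[1]])))
}

# Scorer factory: with a calibration reference, rank by the calibrated
# geometric-mean combined score; without one, by envelope cosine.
make_trace_scorer <- function(donor, reference, config) {
  if (is.null(reference)) {
    return(function(sub, anchor_rt, charge = NULL)
      sub[, "envelope_cos"])
  }
  function(sub, anchor_rt, charge) {
    f <- features_from_matrix(sub, anchor_rt, donor$mono_mass, charge,
                              config)
    combined_score_matrix(calibrate_features(f, reference))
  }
}
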