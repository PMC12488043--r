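# End-to-end propagation: donor set -> RT alignment -> trace search at
# predicted and randomized anchors -> calibration and combined score ->
# semisupervised PEP -> pair competition -> run-by-run FDR control.

# grow-able column store for candidate rows
new_collector <- function(n0 = 1024L) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$cap <- n0
  env$cols <- list()
  env
}

collector_add <- function(env, row) {
  if (env$n == 0L && length(env$cols) == 0L) {
    env$cols <- lapply(row, function(v) {
      out <- vector(typeof(v), env$cap)
      out
    })
    names(env$cols) <- names(row)
  }
  if (env$n >= env$cap) {
    env$cap <- env$cap * 2L
    env$cols <- lapply(env$cols, function(col) {
      length(col) <- env$cap
      col
    })
  }
  env$n <- env$n + 1L
  for (nm in names(row)) env$cols[[nm]][env$n] <- row[[nm]]
  invisible(env)
}

collector_df <- function(env) {
  if (env$n == 0L) return(NULL)
  as.data.frame(lapply(env$cols, function(col) col[seq_len(env$n)]),
                stringsAsFactors = FALSE)
}

# Unambiguous MS2-anchored traces of one run: for every target donor of
# the run, search its own MS2 RT window; exactly one eligible trace makes
# the peptide unambiguous. Returns the peptide table (for randomized
# anchor sourcing) and the feature frame (calibration reference).
run_ms2_traces <- function(run, run_donors, config, cache) {
  n <- nrow(run_donors)
  feats <- vector("list", n)
  unamb <- logical(n)
  pep <- run_donors$peptide; mass <- run_donors$mono_mass
  z <- run_donors$charge; rt <- run_donors$rt
  for (i in seq_len(n)) {
    m <- cached_traces(cache, run, pep[i], mass[i], z[i], config)
    if (nrow(m) == 0L) next
    keep <- which(m[, "apex_rt"] >= rt[i] - config$initial_half_width &
                    m[, "apex_rt"] < rt[i] + config$initial_half_width)
    if (length(keep) != 1L) next
    unamb[i] <- TRUE
    feats[[i]] <- features_from_matrix(m[keep, , drop = FALSE], rt[i],
                                       mass[i], z[i], config)
  }
  list(peptides = run_donors[unamb, c("peptide", "stem", "mono_mass",
                                      "rt"), drop = FALSE],
       features = if (any(unamb)) do.call(rbind, feats[unamb]) else NULL)
}

cached_traces <- function(cache, run, peptide, mono_mass, charge, config) {
  key <- paste(run$run_id, peptide, charge, sep = "\r")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- find_traces_matrix(run, mono_mass, charge, config)$traces
  cache[[key]] <- m
  m
}

# deterministic subsample keeping calibration cost bounded
cap_reference <- function(features, max_n) {
  if (is.null(features) || nrow(features) <= max_n) return(features)
  idx <- round(seq(1, nrow(features), length.out = max_n))
  features[idx, , drop = FALSE]
}

#' Propagate peptide identities across runs with FDR control
#'
#' Runs the full pipeline on a set of MS1 runs and a target-decoy PSM
#' report: donor selection at one fifth of `alpha` (see
#' [donor_threshold]), per-run-pair local RT alignment, expanding-window
#' trace search anchored at the predicted RT and at a randomized RT drawn
#' from a mass-mismatched peptide of the donor run, empirical feature
#' calibration against MS2-anchored traces, semisupervised PEP
#' assignment, predicted-vs-randomized pair competition, and run-by-run
#' acceptance at FDR `alpha`.
#'
#' A peptide is only propagated into runs with no MS2 detection of that
#' peptide; when several origin runs offer the same peptide, the
#' highest-scoring donor is used.
#'
#' @param runs List of [ms1_run] objects.
#' @param psms PSM data frame ([read_psm_table]).
#' @param alpha Target propagation FDR.
#' @param config A [pip_config]; its `pip_fdr` is overridden by `alpha`.
#' @return Object of class `pip_result`: list with `accepted` (data frame
#'   of reported propagations), `candidates`, `survivors`, `summary` (per
#'   acceptor run), `donor_cutoff`, `unopposed_fraction` and `config`.
#' @export
propagate <- function(runs, psms, alpha = 0.01, config = pip_config()) {
  stopifnot(length(runs) >= 2L, nrow(psms) > 0L)
  config$pip_fdr <- alpha
  run_ids <- vapply(runs, function(r) r$run_id, character(1))
  if (anyDuplicated(run_ids)) stop("duplicate run_id", call. = FALSE)
  names(runs) <- run_ids

  donors <- build_donor_set(psms, alpha, config$donor_cap)
  cutoff <- attr(donors, "donor_cutoff")
  if (nrow(donors) == 0L) stop("empty donor set", call. = FALSE)
  donors <- donors[donors$origin_run_id %in% run_ids, , drop = FALSE]

  detected <- lapply(run_ids, function(r)
    unique(psms$peptide[psms$run_id == r]))
  names(detected) <- run_ids
  anchor_psms <- lapply(run_ids, function(r)
    psms[psms$run_id == r & !psms$is_decoy & psms$q_value <= cutoff, ,
         drop = FALSE])
  names(anchor_psms) <- run_ids

  cache <- new.env(parent = emptyenv())

  # per-run unambiguous MS2 traces: calibration reference + randomized
  # anchor source pool
  ms2info <- lapply(run_ids, function(r) {
    rd <- donors[donors$origin_run_id == r & !donors$is_decoy, ,
                 drop = FALSE]
    run_ms2_traces(runs[[r]], rd, config, cache)
  })
  names(ms2info) <- run_ids
  pooled_feats <- do.call(rbind, Filter(Negate(is.null),
                                        lapply(ms2info, `[[`, "features")))
  if (is.null(pooled_feats) || nrow(pooled_feats) == 0L)
    stop("no calibration reference: no unambiguous MS2-anchored traces",
         call. = FALSE)
  pooled_ref <- reference_population(cap_reference(pooled_feats,
                                                   config$max_reference))
  refs <- lapply(run_ids, function(r) {
    f <- ms2info[[r]]$features
    if (is.null(f) || nrow(f) < config$min_reference) pooled_ref
    else reference_population(cap_reference(f, config$max_reference))
  })
  names(refs) <- run_ids

  # pairwise RT alignments (donor run -> acceptor run)
  aligns <- list()
  for (o in run_ids) for (a in run_ids) {
    if (o == a) next
    aligns[[paste(o, a, sep = "\r")]] <-
      suppressWarnings(build_anchor_set(anchor_psms[[o]],
                                        anchor_psms[[a]], config))
  }

  col <- new_collector(4096L)
  n_unopposed <- 0L
  n_pairs <- 0L

  # randomized-anchor source pools as plain vectors (hot loop)
  pools <- lapply(ms2info, function(x) list(
    peptide = x$peptides$peptide, stem = x$peptides$stem,
    mass = x$peptides$mono_mass, rt = x$peptides$rt))

  for (a in run_ids) {
    run_a <- runs[[a]]
    ref_a <- refs[[a]]
    cand_donors <- donors[donors$origin_run_id != a &
                            !(donors$peptide %in% detected[[a]]), ,
                          drop = FALSE]
    if (nrow(cand_donors) == 0L) next
    # one donor per peptide: the highest-scoring origin
    o1 <- order(cand_donors$peptide, -cand_donors$score,
                cand_donors$origin_run_id)
    cand_donors <- cand_donors[o1, , drop = FALSE]
    cand_donors <- cand_donors[!duplicated(cand_donors$peptide), ,
                               drop = FALSE]
    cd_pep <- cand_donors$peptide; cd_stem <- cand_donors$stem
    cd_mass <- cand_donors$mono_mass; cd_rt <- cand_donors$rt
    cd_decoy <- cand_donors$is_decoy
    cd_origin <- cand_donors$origin_run_id
    cd_charges <- cand_donors$observed_charges
    for (i in seq_len(nrow(cand_donors))) {
      d <- list(peptide = cd_pep[i], stem = cd_stem[i],
                mono_mass = cd_mass[i], rt = cd_rt[i],
                is_decoy = cd_decoy[i], origin_run_id = cd_origin[i])
      amap <- aligns[[paste(d$origin_run_id, a, sep = "\r")]]
      charges <- parse_charges(cd_charges[i])
      envelope <- theoretical_envelope(d$mono_mass, config)
      per_charge <- lapply(charges, function(z)
        list(traces = cached_traces(cache, run_a, d$peptide, d$mono_mass,
                                    z, config)))
      anchors_to_try <- list(
        predicted = predict_rt(amap, d$rt, config))
      pool <- pools[[d$origin_run_id]]
      dm <- abs(pool$mass - d$mono_mass)
      elig <- which(dm > config$min_mass_gap & dm <= config$max_mass_gap &
                      abs(pool$rt - d$rt) >= config$min_rt_separation &
                      pool$stem != d$stem)
      n_pairs <- n_pairs + 1L
      if (length(elig) > 0L) {
        j <- elig[stream_draw(config$seed,
                              paste(d$peptide, a, sep = "\r"),
                              length(elig))]
        anchors_to_try$randomized <- predict_rt(amap, pool$rt[j], config)
      } else {
        n_unopposed <- n_unopposed + 1L
      }
      for (kind in names(anchors_to_try)) {
        anchor_rt <- anchors_to_try[[kind]]
        scorer0 <- function(sub, anc, z) {
          f <- features_from_matrix(sub, anc, d$mono_mass, z, config,
                                    envelope)
          combined_score_matrix(calibrate_features(f, ref_a))
        }
        hit <- search_expansion_core_scored(per_charge, charges, anchor_rt,
                                            config, scorer0)
        if (is.null(hit)) next
        m <- per_charge[[hit$charge_i]]$traces[hit$index, , drop = FALSE]
        f <- features_from_matrix(m, anchor_rt, d$mono_mass,
                                  charges[hit$charge_i], config, envelope)
        cal <- calibrate_features(f, ref_a)
        collector_add(col, list(
          donor_key = paste(d$peptide, d$origin_run_id, sep = "\r"),
          peptide = d$peptide, stem = d$stem, mono_mass = d$mono_mass,
          is_decoy = d$is_decoy, origin_run_id = d$origin_run_id,
          acceptor_run_id = a, anchor_kind = kind,
          anchor_rt = anchor_rt, charge = charges[hit$charge_i],
          apex_scan = as.integer(m[1, "apex_scan"]),
          apex_rt = m[1, "apex_rt"], intensity = m[1, "intensity"],
          mass_error = f[1, "mass_error"],
          log_intensity = f[1, "log_intensity"],
          rt_diff = f[1, "rt_diff"],
          envelope_similarity = f[1, "envelope_similarity"],
          n_valid_scans = f[1, "n_valid_scans"],
          cal_mass_error = cal[1, "mass_error"],
          cal_log_intensity = cal[1, "log_intensity"],
          cal_rt_diff = cal[1, "rt_diff"],
          cal_envelope_similarity = cal[1, "envelope_similarity"],
          cal_n_valid_scans = cal[1, "n_valid_scans"],
          combined_score = combined_score(cal[1, ])))
      }
    }
  }

  candidates <- collector_df(col)
  if (is.null(candidates))
    stop("no propagation candidates found", call. = FALSE)
  candidates <- assign_pep(candidates, config)
  survivors <- pair_competition(candidates)

  accepted_list <- list()
  summary_rows <- list()
  for (a in run_ids) {
    sa <- survivors[survivors$acceptor_run_id == a, , drop = FALSE]
    if (nrow(sa) == 0L) next
    curve <- estimate_fdr_curve(sa)
    acc <- accept_at_level(curve, alpha)
    k <- attr(acc, "k_alpha")
    summary_rows[[a]] <- data.frame(
      run_id = a, n_candidates = nrow(sa), k_alpha = k,
      T_p = if (k > 0) curve$T_p[k] else 0L,
      T_r = if (k > 0) curve$T_r[k] else 0L,
      D_p = if (k > 0) curve$D_p[k] else 0L,
      D_r = if (k > 0) curve$D_r[k] else 0L,
      n_accepted = nrow(acc))
    accepted_list[[a]] <- acc
  }
  accepted <- if (length(accepted_list))
    do.call(rbind, accepted_list) else survivors[0, , drop = FALSE]
  rownames(accepted) <- NULL

  res <- list(accepted = accepted, candidates = candidates,
              survivors = survivors,
              summary = if (length(summary_rows))
                do.call(rbind, summary_rows) else NULL,
              donor_cutoff = cutoff, alpha = alpha,
              unopposed_fraction = if (n_pairs) n_unopposed / n_pairs
                                   else NA_real_,
              config = config)
  class(res) <- "pip_result"
  res
}

# expansion loop where the scorer also needs the charge; mirrors
# search_expansion_core but indexes charges positionally
search_expansion_core_scored <- function(per_charge, charges, anchor_rt,
                                         config, scorer) {
  widths <- seq(config$initial_half_width, config$max_half_width,
                by = config$expansion_step)
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
        cand <- list(charge_i = ci, index = keep[j], half_width = hw,
                     score = sc[j], intensity = m[keep[j], "intensity"],
                     apex = m[keep[j], "apex_scan"])
        if (is.null(best) || cand$score > best$score ||
            (cand$score == best$score &&
             (cand$intensity > best$intensity ||
              (cand$intensity == best$intensity && cand$apex < best$apex))))
          best <- cand
      }
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

#' @export
print.pip_result <- function(x, ...) {
  cat("<pip_result> alpha =", x$alpha,
      " donor q-value cutoff =", x$donor_cutoff, "\n")
  cat("  candidates:", nrow(x$candidates),
      " survivors:", nrow(x$survivors),
      " accepted:", nrow(x$accepted), "\n")
  cat("  unopposed donor fraction:",
      round(x$unopposed_fraction, 3), "\n")
  if (!is.null(x$summary)) {
    cat("  per-run acceptance:\n")
    print(x$summary, row.names = FALSE)
  }
  invisible(x)
}

#' Accepted propagations in the output table layout
#'
#' @param result A `pip_result`.
#' @return Data frame with the columns of [write_pip_table], sorted by
#'   (acceptor run, pep).
#' @export
pip_result_table <- function(result) {
  stopifnot(inherits(result, "pip_result"))
  acc <- result$accepted
  out <- data.frame(
    acceptor_run_id = acc$acceptor_run_id, peptide = acc$peptide,
    stem = acc$stem, mono_mass = acc$mono_mass,
    origin_run_id = acc$origin_run_id, anchor_kind = acc$anchor_kind,
    is_decoy = acc$is_decoy, charge = acc$charge, apex_rt = acc$apex_rt,
    intensity = acc$intensity, pep = acc$pep, q_value = acc$q_value,
    stringsAsFactors = FALSE)
  out[order(out$acceptor_run_id, out$pep, out$peptide), , drop = FALSE]
}
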