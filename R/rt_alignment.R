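# Retention-time alignment between a donor and an acceptor run, and the
# randomized-RT anchors that model peak-matching errors. The alignment is a
# local k-nearest-neighbour median shift over peptides MS2-detected in both
# runs; no global warping model is fitted.

#' Build the RT anchor set between two runs
#'
#' One anchor pair per peptide sequence MS2-detected in both runs, taking
#' the best-scoring PSM's RT on each side. With fewer than
#' `config$min_anchors` shared peptides the alignment degrades to the
#' identity mapping and the returned object carries a fallback flag.
#'
#' @param donor_run_psms,acceptor_run_psms Target PSMs of the two runs
#'   (data frames with at least `peptide`, `rt`, `score`).
#' @param config A [pip_config].
#' @return An object of class `anchor_set`: list with `pairs` (data frame
#'   `donor_rt`, `acceptor_rt` sorted by `donor_rt`) and
#'   `identity_fallback` flag.
#' @export
build_anchor_set <- function(donor_run_psms, acceptor_run_psms,
                             config = pip_config()) {
  best_rt <- function(psms) {
    if (nrow(psms) == 0L)
      return(stats::setNames(numeric(0), character(0)))
    o <- order(psms$peptide, -psms$score, psms$rt)
    psms <- psms[o, , drop = FALSE]
    first <- !duplicated(psms$peptide)
    stats::setNames(psms$rt[first], psms$peptide[first])
  }
  d <- best_rt(donor_run_psms)
  a <- best_rt(acceptor_run_psms)
  shared <- intersect(names(d), names(a))
  pairs <- data.frame(donor_rt = unname(d[shared]),
                      acceptor_rt = unname(a[shared]))
  pairs <- pairs[order(pairs$donor_rt), , drop = FALSE]
  rownames(pairs) <- NULL
  fallback <- nrow(pairs) < config$min_anchors
  if (fallback && nrow(pairs) > 0L)
    warning("only ", nrow(pairs), " shared peptides (< ",
            config$min_anchors, "); falling back to identity RT mapping",
            call. = FALSE)
  structure(list(pairs = pairs, identity_fallback = fallback),
            class = "anchor_set")
}

#' Map a donor-run RT onto the acceptor run
#'
#' Local estimate: the `k = config$knn_anchors` anchors nearest in donor
#' RT are selected and the median of their acceptor-minus-donor shifts is
#' added to `donor_rt`. In identity fallback the input is returned
#' unchanged. Vectorised over `donor_rt`.
#'
#' @param anchors An `anchor_set`.
#' @param donor_rt Numeric vector of donor-run RTs, seconds.
#' @param config A [pip_config].
#' @return Predicted acceptor-run RTs, seconds.
#' @export
predict_rt <- function(anchors, donor_rt, config = pip_config()) {
  stopifnot(inherits(anchors, "anchor_set"))
  if (anchors$identity_fallback || nrow(anchors$pairs) == 0L)
    return(donor_rt)
  ad <- anchors$pairs$donor_rt
  shift <- anchors$pairs$acceptor_rt - ad
  donor_rt + knn_median_shift_cpp(ad, shift, config$knn_anchors, donor_rt)
}

#' Peptides eligible to source a randomized-RT anchor
#'
#' A randomized anchor for a donor peptide is drawn from MS2-detected
#' peptides of the donor's origin run that (a) have an unambiguously
#' associated peak trace (flag supplied by the caller), (b) lie more than
#' `min_mass_gap` and at most `max_mass_gap` Da from the donor mass,
#' (c) elute at least `config$min_rt_separation` seconds away, and
#' (d) have a different stem sequence.
#'
#' @param donor One donor row (list or single-row data frame with
#'   `mono_mass`, `rt`, `stem`).
#' @param candidates Data frame of MS2-detected peptides of the donor run
#'   with unambiguous traces (columns `peptide`, `stem`, `mono_mass`,
#'   `rt`).
#' @param config A [pip_config].
#' @return The subset of `candidates` that passes all rules.
#' @export
eligible_random_donors <- function(donor, candidates,
                                   config = pip_config()) {
  if (nrow(candidates) == 0L) return(candidates)
  dm <- abs(candidates$mono_mass - donor$mono_mass)
  dt <- abs(candidates$rt - donor$rt)
  keep <- dm > config$min_mass_gap & dm <= config$max_mass_gap &
    dt >= config$min_rt_separation & candidates$stem != donor$stem
  candidates[keep, , drop = FALSE]
}

#' Draw a randomized-RT anchor
#'
#' Chooses one eligible peptide uniformly at random and maps its donor-run
#' RT onto the acceptor scale with the same local alignment used for the
#' predicted anchor. The draw is taken from a deterministic stream derived
#' from `(config$seed, donor peptide, acceptor run)`, so results are
#' reproducible and independent of iteration order.
#'
#' @param donor One donor row (needs `peptide`).
#' @param eligible Non-empty result of [eligible_random_donors].
#' @param anchors The donor-to-acceptor `anchor_set`.
#' @param acceptor_run_id Acceptor run identifier (stream key component).
#' @param config A [pip_config].
#' @return List with `source_peptide` and `randomized_rt` (seconds).
#' @export
draw_random_anchor <- function(donor, eligible, anchors, acceptor_run_id,
                               config = pip_config()) {
  if (nrow(eligible) == 0L)
    stop("draw_random_anchor: empty eligible set", call. = FALSE)
  i <- stream_draw(config$seed,
                   paste(donor$peptide, acceptor_run_id, sep = "\r"),
                   nrow(eligible))
  list(source_peptide = eligible$peptide[i],
       randomized_rt = predict_rt(anchors, eligible$rt[i], config))
}
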