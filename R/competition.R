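# Predicted-vs-randomized pair competition, the hybrid FDR estimate, and
# run-by-run acceptance with the +1-adjusted threshold rule.
#
# For a run's candidate list sorted by PEP (best first), let T^p_k / T^r_k
# be the numbers of target-peptide candidates with a predicted / randomized
# RT anchor among the top k, and D^p_k / D^r_k the analogous decoy counts.
# T^r_k estimates the peak-matching errors among the top k and
# max(0, D^p_k - D^r_k) the peptide-identification errors, giving
#   fdr_hat(k) = (T^r_k + max(0, D^p_k - D^r_k)) / T^p_k.
# Acceptance adds +1 to the numerator and takes the largest k still at or
# below alpha; the predicted-RT target candidates among those top k are
# reported.

#' Pair competition between predicted- and randomized-RT matches
#'
#' Within each (donor peptide, acceptor run) group holding both a
#' predicted-RT and a randomized-RT candidate, the higher-PEP member is
#' removed; PEP ties remove the predicted-RT member, so a tie counts as a
#' win for the randomized anchor and inflates the error estimate rather
#' than deflating it. Unopposed candidates survive unchanged.
#'
#' @param candidates Candidate data frame with `donor_key`,
#'   `acceptor_run_id`, `anchor_kind`, `pep`.
#' @return The surviving subset, original order preserved.
#' @export
pair_competition <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  grp <- paste(candidates$donor_key, candidates$acceptor_run_id,
               sep = "\r")
  pred <- candidates$anchor_kind == "predicted"
  # groups have at most one candidate of each kind
  pep_pred <- stats::setNames(candidates$pep[pred], grp[pred])
  pep_rand <- stats::setNames(candidates$pep[!pred], grp[!pred])
  drop <- logical(nrow(candidates))
  both <- intersect(names(pep_pred), names(pep_rand))
  if (length(both)) {
    pred_loses <- pep_pred[both] >= pep_rand[both]  # tie -> predicted out
    drop[pred] <- grp[pred] %in% both[pred_loses]
    drop[!pred] <- grp[!pred] %in% both[!pred_loses]
  }
  candidates[!drop, , drop = FALSE]
}

# Deterministic candidate order within one run: PEP ascending, ties by
# combined score descending, then donor peptide lexicographic.
order_run_candidates <- function(candidates) {
  order(candidates$pep, -candidates$combined_score, candidates$peptide)
}

#' Hybrid FDR estimate along one run's sorted candidate list
#'
#' @param survivors One acceptor run's candidates after
#'   [pair_competition] (needs `pep`, `combined_score`, `peptide`,
#'   `anchor_kind`, `is_decoy`).
#' @return Object of class `fdr_curve`: the candidates in sorted order
#'   with cumulative counts `T_p, T_r, D_p, D_r`, the raw estimate
#'   `fdr_hat` (`Inf` where `T_p = 0`), the +1-adjusted estimate
#'   `fdr_adj`, and monotone `q_value`s (see [assign_qvalues]).
#' @export
estimate_fdr_curve <- function(survivors) {
  o <- order_run_candidates(survivors)
  s <- survivors[o, , drop = FALSE]
  pred <- s$anchor_kind == "predicted"
  T_p <- cumsum(pred & !s$is_decoy)
  T_r <- cumsum(!pred & !s$is_decoy)
  D_p <- cumsum(pred & s$is_decoy)
  D_r <- cumsum(!pred & s$is_decoy)
  num <- T_r + pmax(0, D_p - D_r)
  fdr_hat <- ifelse(T_p == 0, Inf, num / T_p)
  fdr_adj <- ifelse(T_p == 0, Inf, (1 + num) / T_p)
  q <- rev(cummin(rev(fdr_adj)))
  s$T_p <- T_p; s$T_r <- T_r; s$D_p <- D_p; s$D_r <- D_r
  s$fdr_hat <- fdr_hat
  s$fdr_adj <- fdr_adj
  s$q_value <- q
  class(s) <- c("fdr_curve", class(s))
  s
}

#' Monotone q-values from the +1-adjusted estimate
#'
#' `q(k) = min over k' >= k` of the adjusted estimate, so thresholding
#' the q-values at alpha reproduces [accept_at_level].
#'
#' @param fdr_adj Numeric vector of +1-adjusted estimates along the
#'   sorted list.
#' @return Non-decreasing q-values.
#' @export
assign_qvalues <- function(fdr_adj) {
  rev(cummin(rev(fdr_adj)))
}

#' Accept one run's propagations at FDR level alpha
#'
#' Finds the maximal rank `k` whose +1-adjusted estimate is at or below
#' `alpha` and reports the predicted-RT target candidates among the top
#' `k`. Randomized-RT and decoy candidates are never reported.
#'
#' @param survivors One run's candidates after [pair_competition], or an
#'   `fdr_curve`.
#' @param alpha Target FDR in (0, 1).
#' @return The accepted subset (sorted by PEP), with the curve columns
#'   and attribute `k_alpha`.
#' @export
accept_at_level <- function(survivors, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  curve <- if (inherits(survivors, "fdr_curve")) survivors
           else estimate_fdr_curve(survivors)
  ok <- which(curve$fdr_adj <= alpha)
  k <- if (length(ok)) max(ok) else 0L
  keep <- if (k > 0L)
    which(seq_len(nrow(curve)) <= k & curve$anchor_kind == "predicted" &
            !curve$is_decoy)
  else integer(0)
  out <- curve[keep, , drop = FALSE]
  attr(out, "k_alpha") <- k
  out
}
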