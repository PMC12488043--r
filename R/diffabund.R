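# Spike-in sensitivity analysis: per-analyte observed log2 fold changes
# and the count of spike-species analytes recovered inside the widest
# fold-change window around the expected value that still holds the
# fraction of (truly unchanging) human analytes at or below a target FDP.

#' Construct a quantification matrix
#'
#' @param intensity Numeric matrix, analytes x runs, positive intensities
#'   with `NA` (or 0, converted to `NA`) for missing values; dimnames
#'   required.
#' @param conditions Named character vector: condition label per run.
#' @param species Named character vector: `"human"`, `"spike"` or
#'   `"ambiguous"` per analyte. Ambiguous analytes are excluded from
#'   window scoring.
#' @return Object of class `quant_matrix`.
#' @export
quant_matrix <- function(intensity, conditions, species = NULL) {
  stopifnot(is.matrix(intensity), !is.null(rownames(intensity)),
            !is.null(colnames(intensity)),
            all(colnames(intensity) %in% names(conditions)))
  intensity[!is.na(intensity) & intensity <= 0] <- NA
  if (is.null(species))
    species <- stats::setNames(rep("human", nrow(intensity)),
                               rownames(intensity))
  stopifnot(all(rownames(intensity) %in% names(species)))
  structure(list(intensity = intensity,
                 conditions = conditions[colnames(intensity)],
                 species = species[rownames(intensity)]),
            class = "quant_matrix")
}

#' Median log-ratio normalization across runs
#'
#' Scales every run so that the median log2 ratio of shared analytes to
#' the reference run (the first column) is zero. When species labels are
#' available the medians are computed on human (non-spike) analytes,
#' whose abundances are expected constant.
#'
#' @param qm A [quant_matrix]; a single-run matrix is returned unchanged.
#' @return The normalized `quant_matrix`; per-run scale factors attached
#'   as attribute `scale_factors`.
#' @export
normalize_runs <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (ncol(qm$intensity) == 1L) {
    attr(qm, "scale_factors") <- stats::setNames(1, colnames(qm$intensity))
    return(qm)
  }
  x <- qm$intensity
  use <- if (any(qm$species == "human")) qm$species == "human"
         else rep(TRUE, nrow(x))
  ref <- x[, 1L]
  sf <- vapply(seq_len(ncol(x)), function(j) {
    shared <- use & !is.na(ref) & !is.na(x[, j])
    if (!any(shared))
      stop("no shared analytes between run ", colnames(x)[j],
           " and the reference run", call. = FALSE)
    2^stats::median(log2(x[shared, j]) - log2(ref[shared]))
  }, numeric(1))
  qm$intensity <- sweep(x, 2L, sf, "/")
  attr(qm, "scale_factors") <- stats::setNames(sf, colnames(x))
  qm
}

#' Observed log2 fold changes between two conditions
#'
#' Intensities are log2 transformed, missing and zero values dropped,
#' the remaining values averaged within each condition, and the
#' difference `mean(cond_b) - mean(cond_a)` reported. Analytes lacking an
#' observation in either condition are omitted.
#'
#' @param qm A [quant_matrix].
#' @param cond_a,cond_b Condition labels (fold change is b over a; pass
#'   the lower spike level as `cond_a`).
#' @return Data frame `analyte`, `species`, `o_fc`.
#' @export
fold_changes <- function(qm, cond_a, cond_b) {
  stopifnot(inherits(qm, "quant_matrix"))
  ja <- which(qm$conditions == cond_a)
  jb <- which(qm$conditions == cond_b)
  if (!length(ja) || !length(jb))
    stop("condition without runs: ",
         paste(c(cond_a, cond_b)[c(!length(ja), !length(jb))],
               collapse = ", "), call. = FALSE)
  la <- log2(qm$intensity[, ja, drop = FALSE])
  lb <- log2(qm$intensity[, jb, drop = FALSE])
  ma <- rowMeans(la, na.rm = TRUE)
  mb <- rowMeans(lb, na.rm = TRUE)
  ok <- is.finite(ma) & is.finite(mb)
  data.frame(analyte = rownames(qm$intensity)[ok],
             species = unname(qm$species[ok]),
             o_fc = unname(mb[ok] - ma[ok]),
             stringsAsFactors = FALSE)
}

#' Spike recovery inside an expected-fold-change window at fixed FDP
#'
#' Considers windows `[e_fc - r, e_fc + r]` around the expected spike
#' log2 fold change, with candidate radii the observed distances
#' `|o_fc - e_fc|`. Human analytes falling inside a window are false
#' discoveries (their true fold change is 0). The widest radius whose
#' in-window human fraction is at most `fdp_target` is chosen, and the
#' number of spike analytes inside it is reported.
#'
#' @param records Fold-change records ([fold_changes]); rows with species
#'   `"ambiguous"` are excluded.
#' @param e_fc Expected spike log2 fold change
#'   (`log2(higher spike level / lower spike level)`).
#' @param fdp_target Maximum tolerated human fraction in the window.
#' @return List with `count` (spike analytes in the chosen window),
#'   `radius` (chosen radius; `NA` if no radius qualifies, count 0) and
#'   `fdp` (realized human fraction at the chosen radius).
#' @export
window_sensitivity <- function(records, e_fc, fdp_target = 0.05) {
  stopifnot(fdp_target > 0, fdp_target < 1)
  rec <- records[records$species %in% c("human", "spike"), , drop = FALSE]
  if (nrow(rec) == 0L)
    return(list(count = 0L, radius = NA_real_, fdp = NA_real_))
  d <- abs(rec$o_fc - e_fc)
  human <- rec$species == "human"
  radii <- sort(unique(d))
  best <- NA_real_
  best_fdp <- NA_real_
  for (r in radii) {
    inside <- d <= r
    fdp <- sum(human & inside) / sum(inside)
    if (fdp <= fdp_target) {
      best <- r
      best_fdp <- fdp
    }
  }
  if (is.na(best)) return(list(count = 0L, radius = NA_real_,
                               fdp = NA_real_))
  list(count = sum(!human & d <= best), radius = best, fdp = best_fdp)
}

#' Roll peptide quantities up to proteins
#'
#' Protein intensity per run is the sum of its peptides' intensities
#' present in that run; proteins with no retained peptide are absent.
#' The protein species label is inherited when all peptides agree and is
#' `"ambiguous"` otherwise.
#'
#' @param qm A peptide-level [quant_matrix].
#' @param protein_of Named character vector: protein accession per
#'   peptide (unambiguous for retained peptides).
#' @return A protein-level [quant_matrix].
#' @export
protein_rollup <- function(qm, protein_of) {
  stopifnot(inherits(qm, "quant_matrix"),
            all(rownames(qm$intensity) %in% names(protein_of)))
  prot <- protein_of[rownames(qm$intensity)]
  x <- qm$intensity
  x0 <- x
  x0[is.na(x0)] <- 0
  agg <- rowsum(x0, group = prot)
  any_obs <- rowsum((!is.na(x)) * 1, group = prot) > 0
  agg[!any_obs] <- NA
  sp <- vapply(split(unname(qm$species), prot), function(s)
    if (length(unique(s)) == 1L) s[1] else "ambiguous", character(1))
  quant_matrix(agg, qm$conditions, sp[rownames(agg)])
}
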