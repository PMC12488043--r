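# Domain containers and tabular I/O: PSM reports, MS1 runs, donor sets and
# propagation result tables. The native formats are plain TSV so that every
# fixture can be built in code and diffed by eye.

PSM_COLUMNS <- c("run_id", "scan_id", "peptide", "stem", "mono_mass",
                 "charge", "rt", "score", "pep", "q_value", "is_decoy",
                 "proteins")
PSM_NUMERIC <- c("mono_mass", "charge", "rt", "score", "pep", "q_value")

PIP_COLUMNS <- c("acceptor_run_id", "peptide", "stem", "mono_mass",
                 "origin_run_id", "anchor_kind", "is_decoy", "charge",
                 "apex_rt", "intensity", "pep", "q_value")
PIP_NUMERIC <- c("mono_mass", "charge", "apex_rt", "intensity", "pep",
                 "q_value")

# Deterministic TSV writer: doubles serialized with 17 significant digits so
# that read(write(x)) round-trips exactly and equal inputs give equal bytes.
write_tsv_det <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
    } else if (is.logical(out[[j]])) {
      out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

require_columns <- function(found, needed, what) {
  missing <- setdiff(needed, found)
  if (length(missing))
    stop(what, ": missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

convert_numeric_cols <- function(df, cols, what) {
  for (cl in cols) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
    if (length(bad))
      stop(what, ": unparseable numeric in column '", cl, "' at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    df[[cl]] <- val
  }
  df
}

parse_logical_col <- function(x, col, what) {
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad))
    stop(what, ": unparseable logical in column '", col, "' at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  out
}

#' Read a PSM report
#'
#' Reads one row per peptide-spectrum match from a tabular target-decoy
#' search report. The native dialect expects the columns
#' `run_id, scan_id, peptide, stem, mono_mass, charge, rt, score, pep,
#' q_value, is_decoy, proteins` (tab separated; `rt` in seconds; `q_value`
#' is the peptide-level q-value; `proteins` a `;`-joined accession list).
#' Other report layouts are supported by passing a named character vector
#' mapping native column names to the file's column names. Columns not in
#' the mapping are ignored.
#'
#' @param path Path to a TSV file.
#' @param dialect `"native"` or a named character vector
#'   (`c(native_name = file_name, ...)`).
#' @return A `data.frame` with the native columns, one row per PSM.
#' @export
read_psm_table <- function(path, dialect = "native") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (identical(dialect, "native")) {
    map <- stats::setNames(PSM_COLUMNS, PSM_COLUMNS)
  } else {
    stopifnot(is.character(dialect), !is.null(names(dialect)))
    map <- dialect
    require_columns(names(map), PSM_COLUMNS, "psm dialect")
  }
  require_columns(colnames(raw), unname(map[PSM_COLUMNS]), "psm table")
  df <- stats::setNames(raw[unname(map[PSM_COLUMNS])], PSM_COLUMNS)
  if (nrow(df) == 0L) {
    df <- convert_numeric_cols(df, PSM_NUMERIC, "psm table")
    df$is_decoy <- logical(0)
    return(df)
  }
  df <- convert_numeric_cols(df, PSM_NUMERIC, "psm table")
  df$is_decoy <- parse_logical_col(df$is_decoy, "is_decoy", "psm table")
  df$charge <- as.integer(df$charge)
  bad <- which(df$pep < 0 | df$pep > 1 | df$q_value < 0 | df$q_value > 1 |
                 df$mono_mass <= 0 | df$charge < 1)
  if (length(bad))
    stop("psm table: invalid field values at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Write a PSM table in the native dialect
#'
#' @param psms Data frame with the native PSM columns.
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  require_columns(colnames(psms), PSM_COLUMNS, "psm table")
  write_tsv_det(psms[PSM_COLUMNS], path)
}

#' Construct an MS1 run
#'
#' @param run_id Run identifier, unique within an experiment.
#' @param scan_rt Numeric vector of scan retention times in seconds,
#'   strictly increasing; scan `i` (0-based) elutes at `scan_rt[i + 1]`.
#' @param peaks Data frame with columns `scan_index` (0-based), `mz`,
#'   `intensity`.
#' @param gradient_length Gradient length in seconds (> 0); defaults to the
#'   last scan RT.
#' @return An object of class `ms1_run` with peaks sorted by m/z.
#' @export
ms1_run <- function(run_id, scan_rt, peaks, gradient_length = NULL) {
  stopifnot(is.character(run_id), length(run_id) == 1L)
  if (length(scan_rt) == 0L) stop("empty run: no MS1 scans", call. = FALSE)
  if (any(diff(scan_rt) <= 0))
    stop("scan RTs must be strictly increasing", call. = FALSE)
  stopifnot(all(c("scan_index", "mz", "intensity") %in% colnames(peaks)))
  if (any(peaks$intensity < 0)) stop("negative intensity", call. = FALSE)
  if (nrow(peaks) &&
      (min(peaks$scan_index) < 0 || max(peaks$scan_index) >= length(scan_rt)))
    stop("peak scan_index out of range", call. = FALSE)
  if (is.null(gradient_length)) gradient_length <- max(scan_rt)
  stopifnot(gradient_length > 0)
  o <- order(peaks$mz, peaks$scan_index)
  structure(list(run_id = run_id,
                 scan_rt = as.numeric(scan_rt),
                 peaks = data.frame(scan_index = as.integer(peaks$scan_index[o]),
                                    mz = as.numeric(peaks$mz[o]),
                                    intensity = as.numeric(peaks$intensity[o])),
                 gradient_length = as.numeric(gradient_length)),
            class = "ms1_run")
}

#' @export
print.ms1_run <- function(x, ...) {
  cat("<ms1_run> ", x$run_id, ": ", length(x$scan_rt), " scans, ",
      nrow(x$peaks), " peaks, gradient ", x$gradient_length, " s\n",
      sep = "")
  invisible(x)
}

#' Read MS1 data for one run
#'
#' For `ms1_tsv`, the file is long-format TSV with columns
#' `scan_id, rt_seconds, mz, intensity`; rows of one scan must be
#' contiguous and scans must appear in strictly increasing RT order.
#' For `mzml`, spectra are read through the `mzR` package and only
#' MS-level-1 spectra are ingested (retention times are normalised to
#' seconds). Scan indices are assigned 0-based in RT order.
#'
#' @param path Input file.
#' @param format `"ms1_tsv"` or `"mzml"`.
#' @param run_id Run identifier; default the file base name.
#' @param gradient_length Optional gradient length in seconds.
#' @return An [ms1_run] object.
#' @export
read_ms1 <- function(path, format = c("ms1_tsv", "mzml"), run_id = NULL,
                     gradient_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(run_id))
    run_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "ms1_tsv") {
    raw <- utils::read.delim(path, colClasses = "character",
                             check.names = FALSE)
    require_columns(colnames(raw), c("scan_id", "rt_seconds", "mz",
                                     "intensity"), "ms1_tsv")
    if ("ms_level" %in% colnames(raw))
      raw <- raw[raw$ms_level %in% c("1", "1L"), , drop = FALSE]
    if (nrow(raw) == 0L) stop("empty run: no MS1 spectra in ", path,
                              call. = FALSE)
    raw <- convert_numeric_cols(raw, c("rt_seconds", "mz", "intensity"),
                                "ms1_tsv")
    grp <- rle(raw$scan_id)
    scan_id <- grp$values
    ends <- cumsum(grp$lengths)
    starts <- ends - grp$lengths + 1L
    rt <- raw$rt_seconds[starts]
    if (anyDuplicated(scan_id))
      stop("ms1_tsv: rows of a scan must be contiguous", call. = FALSE)
    if (any(vapply(seq_along(scan_id), function(i)
      any(raw$rt_seconds[starts[i]:ends[i]] != rt[i]), logical(1))))
      stop("ms1_tsv: inconsistent rt within a scan", call. = FALSE)
    if (any(diff(rt) <= 0))
      stop("ms1_tsv: scan RTs not strictly increasing", call. = FALSE)
    scan_index <- rep.int(seq_along(scan_id) - 1L, grp$lengths)
    return(ms1_run(run_id, rt,
                   data.frame(scan_index = scan_index, mz = raw$mz,
                              intensity = raw$intensity),
                   gradient_length))
  }
  # mzML via mzR
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  ms1 <- which(hd$msLevel == 1L)
  if (length(ms1) == 0L)
    stop("empty run: no MS1 spectra in ", path, call. = FALSE)
  rt <- hd$retentionTime[ms1]  # mzR reports seconds
  o <- order(rt)
  ms1 <- ms1[o]; rt <- rt[o]
  pk <- mzR::peaks(fh, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  npk <- vapply(pk, nrow, integer(1))
  peaks <- data.frame(
    scan_index = rep.int(seq_along(ms1) - 1L, npk),
    mz = unlist(lapply(pk, function(m) m[, 1]), use.names = FALSE),
    intensity = unlist(lapply(pk, function(m) m[, 2]), use.names = FALSE))
  ms1_run(run_id, rt, peaks, gradient_length)
}

#' Write an MS1 run as long-format TSV
#'
#' @param run An [ms1_run] object.
#' @param path Output path.
#' @export
write_ms1_tsv <- function(run, path) {
  stopifnot(inherits(run, "ms1_run"))
  o <- order(run$peaks$scan_index, run$peaks$mz)
  df <- data.frame(scan_id = sprintf("scan%06d", run$peaks$scan_index[o]),
                   rt_seconds = run$scan_rt[run$peaks$scan_index[o] + 1L],
                   mz = run$peaks$mz[o],
                   intensity = run$peaks$intensity[o])
  write_tsv_det(df, path)
}

# minimal spectrum header frame accepted by mzR::writeMSData
mzml_header <- function(ms_level, rt, n_peaks, base_mz, base_int,
                        low_mz, high_mz) {
  n <- length(rt)
  data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(ms_level), polarity = 1L,
    peaksCount = as.integer(n_peaks), totIonCurrent = base_int,
    retentionTime = rt, basePeakMZ = base_mz,
    basePeakIntensity = base_int, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = low_mz, highMZ = high_mz,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
}

#' Write an MS1 run as mzML
#'
#' Requires the `mzR` package. Peak lists are written per scan in m/z
#' order; retention times are stored in seconds.
#'
#' @param run An [ms1_run].
#' @param path Output mzML path.
#' @export
write_ms1_mzml <- function(run, path) {
  stopifnot(inherits(run, "ms1_run"))
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the 'mzR' package", call. = FALSE)
  n <- length(run$scan_rt)
  o <- order(run$peaks$scan_index, run$peaks$mz)
  pk <- split.data.frame(
    cbind(mz = run$peaks$mz[o], intensity = run$peaks$intensity[o]),
    factor(run$peaks$scan_index[o], levels = seq_len(n) - 1L))
  pk <- lapply(pk, function(m) {
    if (nrow(m) == 0L)
      m <- matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("mz", "intensity")))
    m
  })
  base_i <- vapply(pk, function(m)
    if (nrow(m)) max(m[, 2]) else 0, numeric(1))
  base_mz <- vapply(pk, function(m)
    if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1))
  hd <- mzml_header(1L, run$scan_rt, vapply(pk, nrow, integer(1)),
                    base_mz, base_i,
                    vapply(pk, function(m) if (nrow(m)) min(m[, 1]) else 0,
                           numeric(1)),
                    vapply(pk, function(m) if (nrow(m)) max(m[, 1]) else 0,
                           numeric(1)))
  mzR::writeMSData(unname(pk), path, header = hd)
  invisible(path)
}

#' Build the donor peptide set from a PSM report
#'
#' Donor eligibility is decided purely by the peptide-level q-value: the
#' cutoff is one fifth of the requested propagation FDR, capped at
#' `donor_cap` (see [donor_threshold]). Target and decoy peptides are
#' retained alike; the target/decoy label is never consulted. One donor is
#' emitted per (peptide sequence, origin run), represented by its
#' highest-scoring PSM, and carries the set of charges of all of that
#' run's PSMs for the peptide.
#'
#' @param psms PSM data frame as returned by [read_psm_table].
#' @param pip_fdr Requested propagation FDR.
#' @param donor_cap Global donor q-value ceiling.
#' @return Data frame with one row per donor: `peptide, stem, mono_mass,
#'   is_decoy, origin_run_id, scan_id, charge, rt, score, pep, q_value,
#'   observed_charges` (`;`-joined), `proteins`.
#' @export
build_donor_set <- function(psms, pip_fdr, donor_cap = 0.01) {
  stopifnot(nrow(psms) > 0)
  cutoff <- donor_threshold(pip_fdr, donor_cap)
  keep <- psms[psms$q_value <= cutoff, , drop = FALSE]
  if (nrow(keep) == 0L) {
    out <- keep[c("peptide", "stem", "mono_mass", "is_decoy", "run_id",
                  "scan_id", "charge", "rt", "score", "pep", "q_value")]
    names(out)[names(out) == "run_id"] <- "origin_run_id"
    out$observed_charges <- character(0)
    out$proteins <- character(0)
    attr(out, "donor_cutoff") <- cutoff
    return(out)
  }
  key <- paste(keep$peptide, keep$run_id, sep = "\r")
  # best PSM per group: maximal score, ties to the lowest scan_id
  o <- order(key, -keep$score, keep$scan_id)
  keep <- keep[o, , drop = FALSE]
  key <- key[o]
  first <- !duplicated(key)
  donors <- keep[first, , drop = FALSE]
  charges <- vapply(split(keep$charge, key),
                    function(z) paste(sort(unique(z)), collapse = ";"),
                    character(1))
  donors$observed_charges <- unname(charges[key[first]])
  out <- data.frame(peptide = donors$peptide, stem = donors$stem,
                    mono_mass = donors$mono_mass, is_decoy = donors$is_decoy,
                    origin_run_id = donors$run_id, scan_id = donors$scan_id,
                    charge = donors$charge, rt = donors$rt,
                    score = donors$score, pep = donors$pep,
                    q_value = donors$q_value,
                    observed_charges = donors$observed_charges,
                    proteins = donors$proteins,
                    stringsAsFactors = FALSE)
  o2 <- order(out$origin_run_id, out$peptide)
  out <- out[o2, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "donor_cutoff") <- cutoff
  out
}

#' Write accepted propagation results
#'
#' Writes a TSV with the documented header; byte output is deterministic
#' for a fixed input. Rows are expected sorted by (acceptor run, pep).
#'
#' @param results Data frame of accepted propagations with the columns
#'   `acceptor_run_id, peptide, stem, mono_mass, origin_run_id,
#'   anchor_kind, is_decoy, charge, apex_rt, intensity, pep, q_value`.
#' @param path Output path.
#' @export
write_pip_table <- function(results, path) {
  require_columns(colnames(results), PIP_COLUMNS, "pip table")
  write_tsv_det(results[PIP_COLUMNS], path)
}

#' Read a propagation result table written by [write_pip_table]
#'
#' @param path Input path.
#' @return Data frame with the documented propagation columns.
#' @export
read_pip_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  require_columns(colnames(raw), PIP_COLUMNS, "pip table")
  df <- raw[PIP_COLUMNS]
  df <- convert_numeric_cols(df, PIP_NUMERIC, "pip table")
  if (nrow(df)) {
    df$is_decoy <- parse_logical_col(df$is_decoy, "is_decoy", "pip table")
    df$charge <- as.integer(df$charge)
  } else df$is_decoy <- logical(0)
  rownames(df) <- NULL
  df
}
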