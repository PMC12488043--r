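# In-silico tryptic digestion and the two-proteome entrapment database:
# shuffled protein sequences (cleavage sites pinned in place) appended to
# the target proteins so that matches to the appended segment expose
# peptide-identification errors.

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when followed by P, and emits all peptides
#' with up to `max_missed` internal missed cleavages and at least
#' `min_len` residues.
#'
#' @param sequence One protein sequence over the 20-letter amino-acid
#'   alphabet.
#' @param min_len Minimum peptide length.
#' @param max_missed Maximum number of missed cleavage sites.
#' @return Character vector of peptides ordered by start position, then
#'   missed-cleavage count; duplicates removed.
#' @export
tryptic_digest <- function(sequence, min_len = 7, max_missed = 2) {
  stopifnot(length(sequence) == 1L, min_len >= 1, max_missed >= 0)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, names(AA_MONO))
  if (length(bad))
    stop("invalid residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  n <- length(aa)
  if (n == 0L) return(character(0))
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  out <- character(0)
  n_frag <- length(starts)
  for (i in seq_len(n_frag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > n_frag) break
      if (ends[j] - starts[i] + 1L >= min_len)
        out <- c(out, substr(sequence, starts[i], ends[j]))
    }
  }
  unique(out)
}

read_fasta_seqs <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Build a two-proteome entrapment database
#'
#' For each target protein, an entrapment sequence is created by shuffling
#' every residue uniformly at random while keeping all K and R residues
#' (the tryptic cleavage sites) in place. Tryptic fragments of the
#' shuffle that are identical to a peptide of the target or of any
#' exclusion proteome (digested at `min_len`/`max_missed`) are deleted
#' from the shuffled sequence. The first `floor(length/2)` residues of
#' the surviving sequence are appended to the original protein; the
#' boundary offset is recorded so downstream classification can assign a
#' peptide to the original or the entrapment segment.
#'
#' @param target_fasta Path to the target proteome FASTA.
#' @param exclusion_fastas Character vector of FASTA paths whose peptides
#'   must not occur in the entrapment segments.
#' @param min_len,max_missed Digestion parameters for the collision sets.
#' @param seed RNG seed for the shuffles.
#' @return Object of class `entrapment_db`: data frame with `accession`,
#'   `original`, `shuffled`, `segment` (the appended half), `fused`,
#'   `offset` (boundary, 0-based position of the first entrapment
#'   residue); the seed is attached as attribute `seed`.
#' @export
build_entrapment_db <- function(target_fasta, exclusion_fastas = character(),
                                min_len = 7, max_missed = 2, seed = 1L) {
  targets <- read_fasta_seqs(target_fasta)
  excl <- unlist(lapply(exclusion_fastas, read_fasta_seqs))
  collision_set <- unique(unlist(c(
    lapply(targets, tryptic_digest, min_len = min_len,
           max_missed = max_missed),
    lapply(excl, tryptic_digest, min_len = min_len,
           max_missed = max_missed))))
  with_preserved_rng({
    set.seed(seed)
    rows <- lapply(seq_along(targets), function(i) {
      orig <- targets[[i]]
      aa <- strsplit(orig, "", fixed = TRUE)[[1]]
      movable <- which(!aa %in% c("K", "R"))
      sh <- aa
      sh[movable] <- aa[sample(movable)]
      shuffled <- paste(sh, collapse = "")
      # basic (fully cleaved) fragments of the shuffle, in positional
      # order; colliding ones are deleted from the sequence
      frag_pos <- tryptic_fragments(shuffled)
      keep <- !(frag_pos %in% collision_set)
      survived <- paste(frag_pos[keep], collapse = "")
      segment <- substr(survived, 1L, floor(nchar(survived) / 2))
      data.frame(accession = names(targets)[i], original = orig,
                 shuffled = shuffled, segment = segment,
                 fused = paste0(orig, segment), offset = nchar(orig),
                 stringsAsFactors = FALSE)
    })
  })
  db <- do.call(rbind, rows)
  attr(db, "seed") <- seed
  class(db) <- c("entrapment_db", class(db))
  db
}

# fully cleaved tryptic fragments in positional order (with duplicates)
tryptic_fragments <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  substring(sequence, bounds[-length(bounds)] + 1L, bounds[-1])
}

#' Write the fused entrapment database as FASTA
#'
#' The description line of each record carries the boundary as
#' `ENTRAP_OFFSET=<n>` (0-based position of the first entrapment
#' residue).
#'
#' @param db An `entrapment_db`.
#' @param path Output FASTA path.
#' @export
write_entrapment_fasta <- function(db, path) {
  stopifnot(inherits(db, "entrapment_db"))
  x <- Biostrings::AAStringSet(db$fused)
  names(x) <- sprintf("%s ENTRAP_OFFSET=%d", db$accession, db$offset)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Entrapment-to-target database scaling factor
#'
#' `S = (unique entrapment peptides + unique target peptides) / unique
#' entrapment peptides`, computed by digesting the original and the
#' entrapment segments of the fused database separately.
#'
#' @param db An `entrapment_db`.
#' @param min_len,max_missed Digestion parameters.
#' @return List with `S`, `n_target_peptides`, `n_entrapment_peptides`.
#' @export
entrapment_scale_factor <- function(db, min_len = 7, max_missed = 2) {
  stopifnot(inherits(db, "entrapment_db"))
  tgt <- unique(unlist(lapply(db$original, tryptic_digest,
                              min_len = min_len, max_missed = max_missed)))
  ent <- unique(unlist(lapply(db$segment[nchar(db$segment) > 0],
                              tryptic_digest, min_len = min_len,
                              max_missed = max_missed)))
  if (length(ent) == 0L)
    stop("no entrapment peptides in database", call. = FALSE)
  list(S = (length(ent) + length(tgt)) / length(ent),
       n_target_peptides = length(tgt),
       n_entrapment_peptides = length(ent))
}
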