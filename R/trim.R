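# PCR primer removal from read ends.
#
# Amplicon reads begin and end in primer sequence: a 5'-end read starts
# with the forward primer, a 3'-end read (reverse-complemented during
# sequencing) starts with the reverse primer; either read may run into the
# reverse complement of the opposite primer at its 3' end.  The search is
# anchored to a terminal window (primer length + `slack` bases) rather
# than a global scan, so template-internal near-matches are never trimmed.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# mismatches between a primer (IUPAC allowed) and an equal-length window
primer_mismatches <- function(primer_chars, window_chars) {
  ok <- mapply(function(p, b) b %in% IUPAC_SETS[[p]], primer_chars,
               window_chars)
  sum(!ok)
}

# best anchored match of any primer at the 5' terminus: returns bases to
# remove (0 if none)
match_end <- function(seq_chars, primers, max_mismatch, slack) {
  L <- length(seq_chars)
  best <- 0L; best_mm <- Inf
  for (pr in primers) {
    pc <- strsplit(pr, "")[[1]]
    pl <- length(pc)
    if (pl > L) next
    for (off in 0:slack) {
      if (off + pl > L) break
      mm <- primer_mismatches(pc, seq_chars[(off + 1):(off + pl)])
      if (mm <= max_mismatch && (mm < best_mm ||
                                 (mm == best_mm && off + pl > best))) {
        best <- off + pl; best_mm <- mm
      }
    }
  }
  best
}

#' Trim PCR primers from read ends
#'
#' Searches for the forward and reverse primers (and their reverse
#' complements) anchored at each read terminus, allowing `max_mismatch`
#' mismatches and up to `slack` bases of offset; matching prefixes and
#' suffixes are removed.  IUPAC degeneracies in the primers match any
#' compatible base.  Reads shorter than `min_retained_length` after
#' trimming are flagged for discard.  Non-matching reads pass through
#' unmodified.
#'
#' @param reads a reads data.frame (see [read_fastq()]).
#' @param primer_f,primer_r forward and reverse primer sequences (IUPAC
#'   degeneracies allowed).
#' @param max_mismatch maximum mismatches tolerated in a primer match
#'   (default 2; must be < primer length).
#' @param min_retained_length reads shorter than this after trimming are
#'   discarded (default 50).
#' @param slack extra terminal offset searched beyond the primer length
#'   (default 3).
#' @return a list with `reads` (trimmed, kept reads) and `report`
#'   (data.frame: `read_id`, `trimmed5`, `trimmed3`, `kept`, `note`).
#' @export
trim_primers <- function(reads, primer_f, primer_r, max_mismatch = 2,
                         min_retained_length = 50, slack = 3) {
  primer_f <- toupper(primer_f); primer_r <- toupper(primer_r)
  if (nchar(primer_f) == 0 || nchar(primer_r) == 0)
    stop("primers must be non-empty")
  if (max_mismatch >= min(nchar(primer_f), nchar(primer_r)))
    stop("max_mismatch must be smaller than the primer length")
  # a read's 5' terminus starts in a primer (forward for 5'-end reads,
  # reverse for 3'-end reads); its 3' terminus ends in a primer reverse
  # complement.  The 3' search runs on the reverse-complemented remainder,
  # where it becomes a 5'-anchored search for the primers themselves.
  p5 <- c(primer_f, primer_r)
  n <- nrow(reads)
  t5 <- integer(n); t3 <- integer(n)
  out_seq <- reads$seq; out_qual <- reads$qual
  for (i in seq_len(n)) {
    sc <- strsplit(reads$seq[i], "")[[1]]
    a <- match_end(sc, p5, max_mismatch, slack)
    rem <- if (a < length(sc))
      paste(sc[(a + 1):length(sc)], collapse = "") else ""
    b <- if (nchar(rem)) match_end(strsplit(revcomp(rem), "")[[1]], p5,
                                   max_mismatch, slack) else 0L
    t5[i] <- a; t3[i] <- b
    if (a > 0 || b > 0) {
      keep_to <- nchar(reads$seq[i]) - b
      out_seq[i] <- substr(reads$seq[i], a + 1, keep_to)
      if (!is.na(reads$qual[i]))
        out_qual[i] <- substr(reads$qual[i], a + 1, keep_to)
    }
  }
  kept <- nchar(out_seq) >= min_retained_length
  note <- ifelse(t5 == 0 & t3 == 0, "no primer found",
                 ifelse(kept, "trimmed", "discarded: too short"))
  report <- data.frame(read_id = reads$id, trimmed5 = t5, trimmed3 = t3,
                       kept = kept, note = note, stringsAsFactors = FALSE)
  trimmed <- reads
  trimmed$seq <- out_seq
  trimmed$qual <- out_qual
  list(reads = trimmed[kept, , drop = FALSE], report = report)
}

#' Sweep primer remnants from OTU consensus ends
#'
#' A read whose primer copy carries too many sequencing errors escapes
#' read-level trimming and can extend its contig with a low-depth primer
#' overhang.  This post-assembly sweep removes primer matches anchored at
#' the consensus ends, with a more permissive mismatch allowance than the
#' read-level pass (the remnant carries the very errors that let it
#' escape), mirroring the classic practice of running the primer/vector
#' cleaner over assembled sequences as well as reads.
#'
#' @param otus OTU set (see [map_reads()]).
#' @inheritParams trim_primers
#' @param max_mismatch mismatches tolerated in a remnant match (default
#'   4; an anchored 20-base match at 4 mismatches is still far beyond
#'   chance).
#' @param min_retained_length consensus sequences shorter than this after
#'   sweeping are left untouched (default 100).
#' @return a list with `otus` (swept data.frame `id`, `consensus`) and
#'   `report` (per-OTU bases removed).
#' @export
sweep_otu_primers <- function(otus, primer_f, primer_r, max_mismatch = 4,
                              min_retained_length = 100, slack = 3) {
  ot <- as_otu_frame(otus)
  res <- trim_primers(new_reads(ot$id, ot$consensus), primer_f, primer_r,
                      max_mismatch = max_mismatch,
                      min_retained_length = min_retained_length,
                      slack = slack)
  swept <- setNames(res$reads$seq, res$reads$id)
  keep <- ot$id %in% names(swept)
  ot$consensus[keep] <- unname(swept[ot$id[keep]])
  list(otus = ot,
       report = data.frame(otu = res$report$read_id,
                           trimmed5 = res$report$trimmed5,
                           trimmed3 = res$report$trimmed3,
                           stringsAsFactors = FALSE))
}
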