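# small shared helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case preserved as
#'   upper case on output for non-ACGT as N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# uppercase + alphabet validation for nucleotide sequences
validate_dna <- function(seqs, what = "sequence", allow_n = TRUE) {
  seqs <- toupper(seqs)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- which(!grepl(pat, seqs))
  if (length(bad))
    stop(sprintf("%s %d contains characters outside {A,C,G,T%s}",
                 what, bad[1], if (allow_n) ",N" else ""))
  seqs
}

# deterministic zero-padded ids
make_ids <- function(prefix, n) {
  if (n == 0) return(character(0))
  sprintf("%s_%0*d", prefix, max(4L, nchar(as.character(n))), seq_len(n))
}

# Phred+33 helpers
qual_to_int <- function(q) as.integer(utf8ToInt(q)) - 33L
int_to_qual <- function(x) intToUtf8(as.integer(x) + 33L)

# normalise heterogeneous OTU inputs to a data.frame(id, consensus),
# sorted by id (the tie-break order used throughout)
as_otu_frame <- function(otus) {
  if (inherits(otus, "olc_assembly")) otus <- otus$otus
  if (inherits(otus, "dbg_assembly"))
    otus <- data.frame(id = otus$contigs$id, consensus = otus$contigs$seq,
                       stringsAsFactors = FALSE)
  if (is.character(otus)) {
    if (is.null(names(otus))) names(otus) <- make_ids("otu", length(otus))
    otus <- data.frame(id = names(otus), consensus = unname(otus),
                       stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(otus), all(c("id", "consensus") %in% names(otus)))
  if (anyDuplicated(otus$id)) stop("duplicate OTU ids")
  otus <- otus[order(otus$id), c("id", "consensus")]
  rownames(otus) <- NULL
  otus$consensus <- validate_dna(otus$consensus, "OTU consensus")
  otus
}
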