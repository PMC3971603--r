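# Nucleotide dereplication, reading-frame identification and peptide
# collapse.
#
# Nucleotide OTUs are dereplicated at 100% identity (byte-identical,
# reverse-complement-identical, or exact containment), the reading frame
# of each survivor is identified by scoring all six conceptual
# translations against a protein reference with local BLOSUM62 alignment
# (with a longest-ORF fallback below the score floor), and identical
# peptides are collapsed into non-redundant peptide OTUs whose per-library
# abundance is the sum over their member nucleotide OTUs.

the <- new.env(parent = emptyenv())

get_blosum62 <- function() {
  if (is.null(the$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the$blosum62 <- e$BLOSUM62
  }
  the$blosum62
}

FRAME_ORDER <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Translate a DNA sequence in a given frame
#'
#' Frames +1/+2/+3 read the forward strand from offsets 0/1/2; -1/-2/-3
#' read the reverse complement.  Trailing partial codons are dropped;
#' stop codons appear as `*`, fuzzy codons (containing N) as `X`.
#'
#' @param seq a DNA string.
#' @param frame one of +1, +2, +3, -1, -2, -3.
#' @return the peptide string.
#' @export
translate_frame <- function(seq, frame) {
  stopifnot(frame %in% FRAME_ORDER)
  s <- if (frame > 0) seq else revcomp(seq)
  off <- abs(frame) - 1L
  usable <- 3L * ((nchar(s) - off) %/% 3L)
  if (usable < 3) return("")
  s <- substr(s, off + 1L, off + usable)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

longest_orf_len <- function(pep) {
  if (nchar(pep) == 0) return(0L)
  max(nchar(strsplit(pep, "*", fixed = TRUE)[[1]]), 0L)
}

#' Identify the reading frame of an OTU
#'
#' Scores all six conceptual translations by best local alignment
#' (BLOSUM62, gap open -11, extend -1) against a protein reference and
#' returns the maximal-scoring frame (ties resolved in the order +1, +2,
#' +3, -1, -2, -3).  When the maximal score falls below `score_floor` (or
#' no reference is supplied) the frame containing the longest open reading
#' frame is used instead.
#'
#' @param otu a DNA string (length >= 3).
#' @param protein_ref amino-acid reference set (`reference_set`,
#'   data.frame `id`/`seq`, named character vector, or NULL).
#' @param score_floor minimum alignment score for the alignment-based call
#'   (default 50).
#' @return a list: `frame`, `score` (NA for the ORF fallback), `peptide`,
#'   `has_internal_stop`.
#' @export
find_frame <- function(otu, protein_ref = NULL, score_floor = 50) {
  if (nchar(otu) < 3) stop("OTU shorter than 3 bases cannot be translated")
  peps <- vapply(FRAME_ORDER, function(f) translate_frame(otu, f), "")
  score <- rep(NA_real_, 6)
  if (!is.null(protein_ref)) {
    refs <- ref_frame(protein_ref)
    if (nrow(refs)) {
      bl <- get_blosum62()
      alpha <- paste(rownames(bl), collapse = "")
      score <- vapply(peps, function(p) {
        if (nchar(p) == 0) return(-Inf)
        as.numeric(max(vapply(refs$seq, function(r)
          cpp_protein_sw_score(p, r, bl, alpha), 0L)))
      }, 0, USE.NAMES = FALSE)
    }
  }
  if (all(is.na(score)) || max(score, na.rm = TRUE) < score_floor) {
    orf <- vapply(peps, longest_orf_len, 0L)
    best <- which.max(orf)  # first maximum follows FRAME_ORDER
    sc <- NA_real_
  } else {
    best <- which.max(score)
    sc <- score[best]
  }
  pep <- peps[best]
  has_stop <- grepl("*", substr(pep, 1, nchar(pep) - 1L), fixed = TRUE)
  list(frame = FRAME_ORDER[best], score = sc, peptide = pep,
       has_internal_stop = has_stop)
}

#' Identify frames for a whole OTU set
#'
#' @param otus OTU set (see [map_reads()]).
#' @inheritParams find_frame
#' @return a data.frame: `id`, `frame`, `score`, `peptide`,
#'   `has_internal_stop`.
#' @export
find_frames <- function(otus, protein_ref = NULL, score_floor = 50) {
  ot <- as_otu_frame(otus)
  rows <- lapply(seq_len(nrow(ot)), function(i) {
    fr <- find_frame(ot$consensus[i], protein_ref, score_floor)
    data.frame(id = ot$id[i], frame = fr$frame, score = fr$score,
               peptide = fr$peptide,
               has_internal_stop = fr$has_internal_stop,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# longest-first 100% identity / containment grouping shared by the
# nucleotide and peptide dereplication steps
derep_groups <- function(ids, seqs, with_revcomp) {
  ord <- order(-nchar(seqs), ids)
  rep_idx <- integer(0)
  assign_to <- integer(length(ids))
  for (i in ord) {
    hit <- 0L
    for (r in rep_idx) {
      if (grepl(seqs[i], seqs[r], fixed = TRUE) ||
          (with_revcomp && grepl(revcomp(seqs[i]), seqs[r],
                                 fixed = TRUE))) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      assign_to[i] <- i
    } else assign_to[i] <- hit
  }
  list(rep_idx = rep_idx, assign_to = assign_to)
}

# sum table rows of each group into its representative row
merge_table_rows <- function(table, assign_to, ids) {
  reps <- unique(assign_to)
  out <- matrix(0L, length(reps), ncol(table),
                dimnames = list(ids[reps], colnames(table)))
  for (g in seq_along(reps)) {
    members <- ids[assign_to == reps[g]]
    members <- intersect(members, rownames(table))
    if (length(members))
      out[g, ] <- as.integer(colSums(table[members, , drop = FALSE]))
  }
  abundance_table(out, unmapped = attr(table, "unmapped"),
                  total = attr(table, "total"))
}

#' Dereplicate nucleotide OTUs at 100% identity
#'
#' OTUs that are byte-identical, identical after reverse complement, or
#' exact substrings of a longer OTU (on either strand) are merged into the
#' longest representative (ties: lexicographically smallest id), and their
#' abundances are summed into it.
#'
#' @param otus OTU set (see [map_reads()]).
#' @param table an `abundance_table` over the OTU ids (optional).
#' @return a list with `otus` (representatives), `table` (merged, or NULL)
#'   and `merges` (data.frame `otu` -> `representative`).
#' @export
dereplicate_nt <- function(otus, table = NULL) {
  ot <- as_otu_frame(otus)
  g <- derep_groups(ot$id, ot$consensus, with_revcomp = TRUE)
  reps <- sort(ot$id[g$rep_idx])
  merges <- data.frame(otu = ot$id, representative = ot$id[g$assign_to],
                       stringsAsFactors = FALSE)
  out_tab <- if (!is.null(table))
    merge_table_rows(table, g$assign_to, ot$id) else NULL
  list(otus = ot[ot$id %in% reps, , drop = FALSE], table = out_tab,
       merges = merges)
}

#' Collapse translated OTUs into non-redundant peptide OTUs
#'
#' Identical peptides (exact equality; containment merged into the longer)
#' are grouped into one peptide OTU whose per-library abundance is the sum
#' of its member nucleotide OTUs' abundances.  OTUs flagged with internal
#' stop codons are excluded by default and reported.
#'
#' @param frames data.frame from [find_frames()] (`id`, `frame`,
#'   `peptide`, `has_internal_stop`).
#' @param table nucleotide `abundance_table` over the OTU ids (optional).
#' @param exclude_internal_stop drop internal-stop OTUs from peptide space
#'   (default TRUE).
#' @return a list with `peptide_otus` (data.frame `id`, `peptide`,
#'   `members`, `frames`), `table` (peptide `abundance_table` or NULL) and
#'   `excluded` (ids of internal-stop OTUs left out).
#' @export
collapse_peptides <- function(frames, table = NULL,
                              exclude_internal_stop = TRUE) {
  stopifnot(all(c("id", "frame", "peptide") %in% names(frames)))
  excluded <- character(0)
  use <- frames
  if (exclude_internal_stop && any(frames$has_internal_stop)) {
    excluded <- frames$id[frames$has_internal_stop]
    use <- frames[!frames$has_internal_stop, , drop = FALSE]
  }
  if (!nrow(use)) {
    warning("no peptide OTUs remain after excluding internal-stop OTUs")
    return(list(peptide_otus = data.frame(id = character(0),
                                          peptide = character(0),
                                          members = character(0),
                                          frames = character(0),
                                          stringsAsFactors = FALSE),
                table = NULL, excluded = excluded))
  }
  g <- derep_groups(use$id, use$peptide, with_revcomp = FALSE)
  reps <- g$rep_idx
  ordg <- reps[order(-nchar(use$peptide[reps]), use$peptide[reps])]
  pep_ids <- make_ids("pep", length(ordg))
  rows <- lapply(seq_along(ordg), function(q) {
    members <- use$id[g$assign_to == ordg[q]]
    data.frame(id = pep_ids[q], peptide = use$peptide[ordg[q]],
               members = paste(sort(members), collapse = ","),
               frames = paste(use$frame[match(sort(members), use$id)],
                              collapse = ","),
               stringsAsFactors = FALSE)
  })
  pep <- do.call(rbind, rows)
  out_tab <- NULL
  if (!is.null(table)) {
    counts <- matrix(0L, nrow(pep), ncol(table),
                     dimnames = list(pep$id, colnames(table)))
    for (q in seq_len(nrow(pep))) {
      members <- intersect(strsplit(pep$members[q], ",")[[1]],
                           rownames(table))
      if (length(members))
        counts[q, ] <- as.integer(colSums(table[members, , drop = FALSE]))
    }
    excl_counts <- if (length(excluded)) {
      ex <- intersect(excluded, rownames(table))
      colSums(table[ex, , drop = FALSE])
    } else rep(0L, ncol(table))
    out_tab <- abundance_table(
      counts, unmapped = attr(table, "unmapped") + excl_counts,
      total = attr(table, "total"))
  }
  list(peptide_otus = pep, table = out_tab, excluded = excluded)
}
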