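# Assembly quality assessment: reference identity screening (a
# BLAST-then-Smith-Waterman style two-stage search), per-OTU sensitivity
# and specificity against ground truth, and compositional profile error.

ref_frame <- function(refs) {
  if (inherits(refs, "community_truth")) refs <- refs$members
  if (is.data.frame(refs)) {
    if (all(c("id", "seq") %in% names(refs)))
      return(data.frame(id = refs$id, seq = refs$seq,
                        stringsAsFactors = FALSE))
    if (all(c("name", "seq") %in% names(refs)))
      return(data.frame(id = refs$name, seq = refs$seq,
                        stringsAsFactors = FALSE))
  }
  if (is.character(refs))
    return(data.frame(id = names(refs) %||% make_ids("ref", length(refs)),
                      seq = unname(refs), stringsAsFactors = FALSE))
  stop("cannot interpret reference set")
}

kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  km <- unique(substring(seq, 1:(L - k + 1), k:L))
  km[!grepl("[^ACGT]", km)]  # ambiguous bases cannot seed
}

# best local-alignment hit of `query` against every (shortlisted)
# reference, on both strands, with coordinates on the forward reference
best_ref_hits <- function(query, refs, k = 8, top = 20,
                          exhaustive = FALSE) {
  refs <- ref_frame(refs)
  qk <- kmer_set(query, k)
  qk_rc <- kmer_set(revcomp(query), k)
  if (!length(qk))
    return(data.frame(ref_id = character(0), identity = numeric(0),
                      score = integer(0), strand = character(0),
                      ref_start = integer(0), ref_end = integer(0)))
  if (exhaustive || nrow(refs) <= top) {
    cand <- seq_len(nrow(refs))
  } else {
    shared <- vapply(refs$seq, function(r) {
      rk <- kmer_set(r, k)
      max(sum(qk %in% rk), sum(qk_rc %in% rk))
    }, 0)
    if (all(shared == 0)) return(best_ref_hits(query, refs, k, top,
                                               exhaustive = TRUE))
    cand <- order(-shared, refs$id)[seq_len(min(top, nrow(refs)))]
    cand <- cand[shared[cand] > 0]
  }
  rows <- lapply(cand, function(i) {
    rlen <- nchar(refs$seq[i])
    fw <- cpp_sw_align(query, refs$seq[i])
    rv <- cpp_sw_align(query, revcomp(refs$seq[i]))
    if (fw$score > rv$score ||
        (fw$score == rv$score && fw$identity >= rv$identity)) {
      data.frame(ref_id = refs$id[i], identity = fw$identity,
                 score = fw$score, strand = "+",
                 ref_start = fw$s_start, ref_end = fw$s_end,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(ref_id = refs$id[i], identity = rv$identity,
                 score = rv$score, strand = "-",
                 ref_start = rlen - rv$s_end, ref_end = rlen - rv$s_start,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(-out$score, -out$identity, out$ref_id), , drop = FALSE]
}

#' Reference identity screen (two-stage local alignment)
#'
#' Short-lists candidate references by shared k-mer count (k = 8, top 20
#' by default), then scores the query against each candidate by exact
#' local alignment on both strands; identity is matches / alignment
#' columns x 100 over the optimal local alignment.  All references
#' attaining the maximum identity are returned.
#'
#' @param query a DNA string.
#' @param refs a reference set (`reference_set`, data.frame with
#'   `id`/`seq`, or named character vector).
#' @param k k-mer size for the short-list (default 8).
#' @param top number of candidates carried into alignment (default 20).
#' @param exhaustive skip the short-list and align against every
#'   reference.
#' @return a list with `ref_ids` (all references attaining the maximal
#'   alignment score), `identity` (identity of that optimal alignment),
#'   and `hits` (per-candidate data.frame, best first).  A query with no
#'   alignable k-mers (e.g. all `N`) yields an empty result with a
#'   warning.
#'
#' @details Candidates are ranked by the optimal local-alignment score,
#'   and the reported identity is computed over that alignment's columns.
#'   Ranking by raw identity would be degenerate: any unrelated reference
#'   sharing a short exact word with the query attains a "100%" local
#'   alignment of a few bases.
#' @export
watered_blast_identity <- function(query, refs, k = 8, top = 20,
                                   exhaustive = FALSE) {
  hits <- best_ref_hits(query, refs, k, top, exhaustive)
  if (!nrow(hits)) {
    warning("query has no alignable sequence (no candidates)")
    return(list(ref_ids = character(0), identity = NA_real_, hits = hits))
  }
  mx <- max(hits$score)
  best <- hits[hits$score == mx, , drop = FALSE]
  list(ref_ids = sort(best$ref_id), identity = max(best$identity),
       hits = hits)
}

#' Per-OTU sensitivity and specificity
#'
#' For each OTU, the target `t` is its nearest reference (best identity by
#' [watered_blast_identity()]; lexicographic tie-break).  Sensitivity is
#' the fraction of `t`'s reads assigned to the OTU; specificity is the
#' fraction of the OTU's reads that are truly from `t`.  Zero-denominator
#' cases yield `NA` with the corresponding `*_defined` flag set to FALSE.
#'
#' @param otus OTU set (see [map_reads()]).
#' @param assignments assignment data.frame from [map_reads()].
#' @param read_sources per-read truth: data.frame `read_id`, `source`
#'   (e.g. `truth$read_sources` from [simulate_reads()]) or a named
#'   character vector.
#' @param refs reference set used to name each OTU's target; defaults to
#'   the truth members when `read_sources` is a `community_truth`.
#' @return a data.frame: `otu`, `nearest_ref`, `nearest_identity`,
#'   `sensitivity`, `specificity`, `sn_defined`, `sp_defined`.
#' @export
otu_sn_sp <- function(otus, assignments, read_sources, refs = NULL) {
  if (inherits(read_sources, "community_truth")) {
    refs <- refs %||% read_sources$members
    read_sources <- read_sources$read_sources
  }
  if (is.data.frame(read_sources))
    read_sources <- setNames(read_sources$source, read_sources$read_id)
  if (is.null(refs)) stop("refs required to name OTU targets")
  ot <- as_otu_frame(otus)
  src_of <- read_sources[assignments$read_id]
  rows <- lapply(seq_len(nrow(ot)), function(i) {
    wb <- watered_blast_identity(ot$consensus[i], refs)
    t <- if (length(wb$ref_ids)) wb$ref_ids[1] else NA_character_
    in_otu <- assignments$otu == ot$id[i]
    n_from_t <- sum(read_sources == t, na.rm = TRUE)
    n_in_otu <- sum(in_otu)
    sn <- if (!is.na(t) && n_from_t > 0)
      sum(in_otu & !is.na(src_of) & src_of == t) / n_from_t else NA_real_
    sp <- if (!is.na(t) && n_in_otu > 0)
      sum(in_otu & !is.na(src_of) & src_of == t) / n_in_otu else NA_real_
    data.frame(otu = ot$id[i], nearest_ref = t,
               nearest_identity = wb$identity,
               sensitivity = sn, specificity = sp,
               sn_defined = !is.na(sn), sp_defined = !is.na(sp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare an estimated profile against community ground truth
#'
#' OTUs are matched to community members by best reference hit (several
#' OTUs may match one member; their abundances are summed).  The
#' compositional error is the total variation distance
#' `0.5 * sum(|p_hat - p|)` between the mapped-read profile and the
#' realized truth profile; `members_recovered` counts members matched by
#' at least one OTU at `recover_identity` percent or better; the unmapped
#' fraction is reported separately.
#'
#' @param table an `abundance_table` of mapped counts.
#' @param otus the OTU set behind the table's rows.
#' @param truth a `community_truth` from [simulate_reads()].
#' @param recover_identity identity threshold for calling a member
#'   recovered (default 97).
#' @return an object of class `profile_comparison`: list with `l1_error`,
#'   `members_recovered`, `unmapped_fraction`, `member_abundance`
#'   (data.frame of estimated vs true proportions) and `otu_match`.
#' @export
compare_profiles <- function(table, otus, truth, recover_identity = 97) {
  stopifnot(inherits(truth, "community_truth"))
  ot <- as_otu_frame(otus)
  members <- truth$members
  # best member hit per OTU (optimal local alignment, both strands)
  best_member <- character(nrow(ot)); names(best_member) <- ot$id
  best_ident <- numeric(nrow(ot))
  recovered_set <- character(0)
  for (i in seq_len(nrow(ot))) {
    wb <- watered_blast_identity(ot$consensus[i], members,
                                 exhaustive = TRUE)
    best_member[i] <- wb$ref_ids[1]
    best_ident[i] <- wb$identity
    if (wb$identity >= recover_identity)
      recovered_set <- union(recovered_set, wb$ref_ids)
  }
  # estimated member profile from mapped reads (pooled over libraries)
  row_tot <- rowSums(table)
  shared <- intersect(ot$id, names(row_tot))
  est_all <- setNames(rep(0, nrow(members)), members$name)
  for (id in shared)
    est_all[best_member[id]] <- est_all[best_member[id]] + row_tot[id]
  p_hat <- if (sum(est_all) > 0) est_all / sum(est_all) else est_all
  # realized truth profile (non-chimeric reads)
  src <- truth$read_sources$source
  src <- src[src %in% members$name]
  p <- tabulate(factor(src, levels = members$name),
                nbins = nrow(members))
  p <- p / sum(p)
  l1 <- 0.5 * sum(abs(p_hat - p))
  recovered <- sort(recovered_set)
  unm <- attr(table, "unmapped"); tot <- attr(table, "total")
  structure(list(
    l1_error = l1,
    members_recovered = length(recovered),
    recovered_members = recovered,
    unmapped_fraction = if (sum(tot) > 0) sum(unm) / sum(tot) else 0,
    member_abundance = data.frame(member = members$name,
                                  estimated = as.numeric(p_hat),
                                  true = p, stringsAsFactors = FALSE),
    otu_match = data.frame(otu = ot$id, member = unname(best_member),
                           identity = best_ident,
                           stringsAsFactors = FALSE)),
    class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf(paste0("Profile comparison: %d member(s) recovered, ",
                     "L1 error %.4f, unmapped fraction %.4f\n"),
              x$members_recovered, x$l1_error, x$unmapped_fraction))
  invisible(x)
}
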