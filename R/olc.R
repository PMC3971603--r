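# Greedy overlap-layout-consensus assembly with exact internal read
# tracking.
#
# Overlaps are gapless dovetail/containment alignments on either strand
# (the simulator's default error model is substitution-only, and the
# companion brute-force oracle used in the tests is offset-based).  Greedy
# merging proceeds in decreasing score order (overlap length x identity);
# a haplotype-conflict guard refuses to merge two contigs whose consensus
# columns disagree with >= 2 reads of support on both sides at more than
# `max_merge_conflicts` positions, which is what keeps near-identical
# community members (e.g. a 96%-identical pair) in separate OTUs while
# still merging sequencing-error variation.

BASE4 <- c("A", "C", "G", "T")

base_codes <- function(seq) {
  m <- match(strsplit(seq, "")[[1]], BASE4)  # N -> NA (no vote)
  m
}

#' Find pairwise read overlaps
#'
#' Detects suffix-prefix (dovetail) and containment overlaps between all
#' read pairs, on either strand, reporting the best qualifying overlap per
#' pair (length >= `min_overlap_len` and identity >= `min_overlap_identity`
#' percent over the overlap columns).  Small inputs are scanned
#' exhaustively over all offsets; large inputs use a k-mer seeded offset
#' shortlist that agrees with the exhaustive scan on qualifying overlaps.
#'
#' @param reads a reads data.frame or character vector of sequences (names
#'   used as ids).
#' @param min_overlap_len minimum overlap length in bases (default 100).
#' @param min_overlap_identity minimum percent identity over the overlap
#'   (default 90).
#' @param method `"auto"` (exhaustive below 300 reads), `"exhaustive"` or
#'   `"seeded"`.
#' @param seed_k,stride k-mer size and probe stride for the seeded scan.
#' @return a data.frame of edges: `a`, `b` (read ids, a < b), `orient`
#'   (`"+"`/`"-"`: strand of b relative to a), `offset` (start of oriented
#'   b in a's coordinates), `length`, `identity`, `score`.
#' @export
find_overlaps <- function(reads, min_overlap_len = 100,
                          min_overlap_identity = 90,
                          method = c("auto", "exhaustive", "seeded"),
                          seed_k = 12, stride = 4) {
  method <- match.arg(method)
  if (is.character(reads))
    reads <- new_reads(names(reads) %||% make_ids("read", length(reads)),
                       reads)
  stopifnot(min_overlap_len >= 1,
            min_overlap_identity > 0, min_overlap_identity <= 100)
  reads <- reads[order(reads$id), , drop = FALSE]
  exhaustive <- switch(method, exhaustive = TRUE, seeded = FALSE,
                       auto = nrow(reads) <= 300)
  ed <- cpp_overlap_edges(reads$seq, as.integer(min_overlap_len),
                          min_overlap_identity, exhaustive,
                          as.integer(seed_k), as.integer(stride))
  data.frame(a = reads$id[ed$a], b = reads$id[ed$b], orient = ed$orient,
             offset = ed$offset, length = ed$length, identity = ed$identity,
             score = ed$length * ed$identity, stringsAsFactors = FALSE)
}

#' Assemble reads by greedy overlap-layout-consensus
#'
#' Computes overlap edges ([find_overlaps()]), merges reads greedily by
#' decreasing score (overlap length x identity; ties broken
#' lexicographically by read id pair), and calls a per-column weighted
#' majority consensus (quality-weighted when qualities are present; ties
#' resolved to the lexicographically smallest base).  Every input read ends
#' up in exactly one OTU's tracked set or in the unassembled list; contigs
#' with fewer than `min_reads_per_otu` reads are dissolved to unassembled.
#' Consensus sequences are reported in canonical orientation (the
#' lexicographically smaller of the two strands).
#'
#' @inheritParams find_overlaps
#' @param min_reads_per_otu contigs with fewer reads are dissolved
#'   (default 2).
#' @param max_merge_conflicts absolute floor on the number of
#'   disagreeing consensus columns tolerated when merging (default 1).
#' @param merge_conflict_rate maximum tolerated fraction of overlap
#'   columns where the two sides' majority calls disagree (default 0.02);
#'   merges above `max(max_merge_conflicts, rate * overlap)` are
#'   rejected.  Sequencing errors disagree at roughly the per-base error
#'   rate, while distinct templates above the overlap-identity threshold
#'   disagree at up to 10%, so the default cleanly separates
#'   near-identical community members from error variation.
#' @return an object of class `olc_assembly`: list with `otus` (data.frame
#'   `id`, `consensus`, `n_reads`), `tracking` (data.frame `read_id`,
#'   `otu_id`, `"unassembled"` for untracked reads), `depth` (per-OTU
#'   per-column read depth), `unassembled` (read ids) and `params`.
#' @export
olc_assemble <- function(reads, min_overlap_len = 100,
                         min_overlap_identity = 90, min_reads_per_otu = 2,
                         max_merge_conflicts = 1,
                         merge_conflict_rate = 0.02,
                         method = c("auto", "exhaustive", "seeded"),
                         seed_k = 12, stride = 4, edges = NULL) {
  method <- match.arg(method)
  if (is.character(reads))
    reads <- new_reads(names(reads) %||% make_ids("read", length(reads)),
                       reads)
  if (anyDuplicated(reads$id)) stop("duplicate read ids")
  reads <- reads[order(reads$id), , drop = FALSE]
  n <- nrow(reads)
  params <- list(min_overlap_len = min_overlap_len,
                 min_overlap_identity = min_overlap_identity,
                 min_reads_per_otu = min_reads_per_otu,
                 max_merge_conflicts = max_merge_conflicts,
                 merge_conflict_rate = merge_conflict_rate)
  if (n == 0)
    return(structure(list(otus = data.frame(id = character(0),
                                            consensus = character(0),
                                            n_reads = integer(0)),
                          tracking = data.frame(read_id = character(0),
                                                otu_id = character(0)),
                          depth = list(), unassembled = character(0),
                          params = params), class = "olc_assembly"))
  if (is.null(edges)) {
    exhaustive <- switch(method, exhaustive = TRUE, seeded = FALSE,
                         auto = n <= 300)
    ed <- cpp_overlap_edges(reads$seq, as.integer(min_overlap_len),
                            min_overlap_identity, exhaustive,
                            as.integer(seed_k), as.integer(stride))
    ea <- ed$a; eb <- ed$b
    score <- ed$length * ed$identity
    orient <- ifelse(ed$orient == "+", 1L, -1L)
    offset <- ed$offset
  } else {
    keep <- edges$length >= min_overlap_len &
      edges$identity >= min_overlap_identity
    edges <- edges[keep, , drop = FALSE]
    ea <- match(edges$a, reads$id); eb <- match(edges$b, reads$id)
    score <- edges$length * edges$identity
    orient <- ifelse(edges$orient == "+", 1L, -1L)
    offset <- edges$offset
  }
  # greedy layout in decreasing score order, read-id pair tie-break
  # (reads are id-sorted, so index order is id order)
  ord <- order(-score, ea, eb)
  lay <- cpp_olc_greedy(reads$seq, as.integer(ea[ord]),
                        as.integer(eb[ord]), as.integer(orient[ord]),
                        as.integer(offset[ord]),
                        as.integer(max_merge_conflicts),
                        merge_conflict_rate)
  lens <- nchar(reads$seq)
  use_qual <- !all(is.na(reads$qual))

  groups <- split(seq_len(n), lay$root)
  groups <- groups[lengths(groups) >= min_reads_per_otu]
  cons <- character(length(groups)); depth <- vector("list", length(groups))
  rd_ids <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    L <- max(lay$delta[g] + lens[g])
    cm <- matrix(0L, 4, L)
    wm <- if (use_qual) matrix(0, 4, L) else NULL
    for (r in g) {
      cd <- base_codes(reads$seq[r])
      if (lay$sigma[r] == 1L) {
        pos <- lay$delta[r] + seq_len(lens[r])
      } else {
        pos <- lay$delta[r] + rev(seq_len(lens[r]))
        cd <- 5L - cd  # complement
      }
      ok <- !is.na(cd)
      ix <- cbind(cd[ok], pos[ok])
      cm[ix] <- cm[ix] + 1L
      if (use_qual) {
        w <- if (is.na(reads$qual[r])) rep(1, lens[r]) else
          pmax(1L, qual_to_int(reads$qual[r]))
        wm[ix] <- wm[ix] + w[ok]
      }
    }
    vm <- if (use_qual) wm else cm
    top <- max.col(t(vm), ties.method = "first")
    covered <- colSums(cm) > 0
    s <- paste(ifelse(covered, BASE4[top], "N"), collapse = "")
    d <- colSums(cm)
    rc <- revcomp(s)
    if (rc < s) { s <- rc; d <- rev(d) }
    cons[i] <- s; depth[[i]] <- as.integer(d)
    rd_ids[[i]] <- reads$id[g]
  }
  ord <- order(-lengths(rd_ids), cons)
  cons <- cons[ord]; depth <- depth[ord]; rd_ids <- rd_ids[ord]
  ids <- make_ids("otu", length(cons))
  tracking <- data.frame(read_id = reads$id, otu_id = "unassembled",
                         stringsAsFactors = FALSE)
  for (i in seq_along(ids))
    tracking$otu_id[match(rd_ids[[i]], tracking$read_id)] <- ids[i]
  unasm <- tracking$read_id[tracking$otu_id == "unassembled"]
  structure(list(
    otus = data.frame(id = ids, consensus = cons,
                      n_reads = lengths(rd_ids), stringsAsFactors = FALSE),
    tracking = tracking,
    depth = setNames(depth, ids),
    tracked_reads = setNames(rd_ids, ids),
    unassembled = unasm,
    params = params), class = "olc_assembly")
}

#' @export
print.olc_assembly <- function(x, ...) {
  cat("OLC assembly:", nrow(x$otus), "OTUs,",
      sum(x$otus$n_reads), "reads tracked,",
      length(x$unassembled), "unassembled\n")
  cat(sprintf("  min overlap %d bp at >= %.0f%% identity\n",
              x$params$min_overlap_len, x$params$min_overlap_identity))
  invisible(x)
}
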