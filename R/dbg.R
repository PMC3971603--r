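# De Bruijn graph assembly over canonical k-mers.
#
# The graph is built on canonical k-mers (a k-mer and its reverse
# complement are one node); traversal works on oriented node states so
# both strands are handled uniformly.  Cleaning follows the usual DBG
# recipe: low-count k-mers dropped, short dead-end tips clipped, simple
# two-path bubbles whose branches align above `bubble_pop_identity` popped
# in favour of the higher-coverage branch.  Read tracking is deliberately
# absent: distilling reads to k-mers forfeits it, and abundance is
# recovered downstream by read mapping.

dbg_unitigs <- function(kmers, counts, k) {
  N <- length(kmers)
  rcs <- revcomp(kmers)
  oriented <- list(kmers, rcs)  # orientation 1 = canonical, 2 = rc
  # successor tables: succ_idx[[o]][[b]][i], succ_or likewise
  succ_idx <- list(vector("list", 4), vector("list", 4))
  succ_or <- list(vector("list", 4), vector("list", 4))
  for (o in 1:2) {
    suffix <- substr(oriented[[o]], 2, k)
    for (b in 1:4) {
      t <- paste0(suffix, BASE4[b])
      trc <- revcomp(t)
      canon <- ifelse(t <= trc, t, trc)
      j <- match(canon, kmers)
      succ_idx[[o]][[b]] <- j
      succ_or[[o]][[b]] <- ifelse(t <= trc, 1L, 2L)
    }
  }
  OD <- matrix(0L, N, 2)
  for (o in 1:2) {
    nn <- 0L
    for (b in 1:4) nn <- nn + !is.na(succ_idx[[o]][[b]])
    OD[, o] <- nn
  }
  flip <- function(o) 3L - o
  indeg <- function(i, o) OD[i, flip(o)]
  the_succ <- function(i, o) {
    for (b in 1:4) {
      j <- succ_idx[[o]][[b]][i]
      if (!is.na(j)) return(c(j, succ_or[[o]][[b]][i]))
    }
    NULL
  }
  visited <- rep(FALSE, N)
  paths <- list(); porient <- list()
  walk <- function(i, o) {
    nodes <- integer(0); ors <- integer(0)
    repeat {
      nodes <- c(nodes, i); ors <- c(ors, o)
      visited[i] <<- TRUE
      if (OD[i, o] != 1L) break
      s <- the_succ(i, o)
      if (visited[s[1]]) break
      if (indeg(s[1], s[2]) != 1L) break
      i <- s[1]; o <- s[2]
    }
    list(nodes, ors)
  }
  for (i in seq_len(N)) {
    if (visited[i]) next
    for (o in 1:2) {
      ind <- indeg(i, o)
      is_start <- ind != 1L
      if (!is_start && ind == 1L) {
        # unique predecessor of (i,o) = reverse of the unique successor
        # of (i, flip(o)); a branching predecessor also starts a unitig
        p <- the_succ(i, flip(o))
        is_start <- OD[p[1], flip(p[2])] != 1L
      }
      if (is_start && !visited[i]) {
        w <- walk(i, o)
        paths[[length(paths) + 1L]] <- w[[1]]
        porient[[length(porient) + 1L]] <- w[[2]]
        break
      }
    }
  }
  for (i in seq_len(N)) {  # leftover cycles
    if (visited[i]) next
    w <- walk(i, 1L)
    paths[[length(paths) + 1L]] <- w[[1]]
    porient[[length(porient) + 1L]] <- w[[2]]
  }
  seqs <- vapply(seq_along(paths), function(p) {
    nodes <- paths[[p]]; ors <- porient[[p]]
    first <- oriented[[ors[1]]][nodes[1]]
    if (length(nodes) == 1) return(first)
    tail_chars <- vapply(2:length(nodes), function(q)
      substr(oriented[[ors[q]]][nodes[q]], k, k), "")
    paste0(first, paste(tail_chars, collapse = ""))
  }, "")
  cov <- vapply(paths, function(nd) mean(counts[nd]), 0)
  # unitig-graph attachment: states at both ends
  ins <- vapply(seq_along(paths), function(p)
    indeg(paths[[p]][1], porient[[p]][1]), 0L)
  outs <- vapply(seq_along(paths), function(p) {
    np <- length(paths[[p]])
    OD[paths[[p]][np], porient[[p]][np]]
  }, 0L)
  pred_state <- vapply(seq_along(paths), function(p) {
    if (ins[p] != 1L) return(NA_integer_)
    s <- the_succ(paths[[p]][1], flip(porient[[p]][1]))
    s[1] * 2L + (s[2] - 1L)
  }, 0L)
  succ_state <- vapply(seq_along(paths), function(p) {
    if (outs[p] != 1L) return(NA_integer_)
    np <- length(paths[[p]])
    s <- the_succ(paths[[p]][np], porient[[p]][np])
    s[1] * 2L + (s[2] - 1L)
  }, 0L)
  list(paths = paths, seqs = seqs, cov = cov, ins = ins, outs = outs,
       pred = pred_state, succ = succ_state)
}

#' Assemble reads with a de Bruijn graph
#'
#' @param reads a reads data.frame or character vector of sequences.
#' @param k k-mer length; the supported sweep range is 10-31 (values
#'   outside it are allowed with a warning).
#' @param min_kmer_count k-mers seen fewer times are dropped (default 2).
#' @param tip_max_len dead-end unitigs shorter than this are clipped
#'   (default `2 * k`).
#' @param bubble_pop_identity two-path bubbles whose branches align at or
#'   above this percent identity are popped, keeping the higher-coverage
#'   branch (default 98).
#' @param min_contig_len minimum emitted contig length (default 100).
#' @return an object of class `dbg_assembly`: list with `contigs`
#'   (data.frame `id`, `seq`, `length`, `mean_kmer_coverage`),
#'   `n_reads_skipped` (reads shorter than k) and `params`.
#' @export
dbg_assemble <- function(reads, k = 31, min_kmer_count = 2,
                         tip_max_len = 2 * k, bubble_pop_identity = 98,
                         min_contig_len = 100) {
  if (is.character(reads))
    reads <- new_reads(names(reads) %||% make_ids("read", length(reads)),
                       reads)
  k <- as.integer(k)
  if (k < 10 || k > 31)
    warning("k = ", k, " is outside the supported sweep range [10, 31]")
  if (k < 2 || k > 31) stop("k must be in [2, 31]")
  if (min_kmer_count < 1) stop("min_kmer_count must be >= 1")
  lens <- nchar(reads$seq)
  if (!any(lens >= k))
    stop("no usable reads: k (", k, ") exceeds the maximum read length (",
         if (length(lens)) max(lens) else 0, ")")
  n_skipped <- sum(lens < k)
  usable <- reads$seq[lens >= k]
  kc <- cpp_count_kmers(usable, k)
  keep <- kc$count >= min_kmer_count
  kmers <- kc$kmer[keep]
  counts <- kc$count[keep]
  params <- list(k = k, min_kmer_count = min_kmer_count,
                 tip_max_len = tip_max_len,
                 bubble_pop_identity = bubble_pop_identity,
                 min_contig_len = min_contig_len)

  empty <- function() structure(
    list(contigs = data.frame(id = character(0), seq = character(0),
                              length = integer(0),
                              mean_kmer_coverage = numeric(0),
                              stringsAsFactors = FALSE),
         n_reads_skipped = n_skipped, params = params),
    class = "dbg_assembly")
  if (length(kmers) == 0) return(empty())

  unitigs_of <- function(kmers, counts)
    dbg_unitigs(kmers, counts, k)

  drop_nodes <- function(kmers, counts, nodes) {
    keep <- setdiff(seq_along(kmers), nodes)
    list(kmers = kmers[keep], counts = counts[keep])
  }

  # iterative cleaning: clip tips, then pop bubbles, until stable
  for (round in 1:10) {
    u <- unitigs_of(kmers, counts)
    ulen <- nchar(u$seqs)
    dead_in <- u$ins == 0L; dead_out <- u$outs == 0L
    tips <- which(xor(dead_in, dead_out) & ulen < tip_max_len)
    if (length(tips)) {
      rm_nodes <- unique(unlist(u$paths[tips]))
      if (length(rm_nodes) == length(kmers)) break
      upd <- drop_nodes(kmers, counts, rm_nodes)
      kmers <- upd$kmers; counts <- upd$counts
      if (length(kmers) == 0) return(empty())
      next
    }
    # simple two-path bubbles: unitigs sharing one predecessor state and
    # one successor state (in either mutual orientation).  Both anchor
    # states are stored pointing away from the unitig, so reversing a
    # branch simply swaps them.
    keyA <- paste(u$pred, u$succ)
    keyB <- paste(u$succ, u$pred)
    canon_key <- ifelse(is.na(u$pred) | is.na(u$succ), NA,
                        pmin(keyA, keyB))
    losers <- integer(0)
    for (kgrp in unique(canon_key[!is.na(canon_key)])) {
      grp <- which(!is.na(canon_key) & canon_key == kgrp)
      if (length(grp) < 2) next
      # orient every branch consistently with the group's canonical key
      gseq <- ifelse(paste(u$pred[grp], u$succ[grp]) == kgrp,
                     u$seqs[grp], revcomp(u$seqs[grp]))
      gcov <- u$cov[grp]
      ord <- order(-gcov, gseq)
      survivor <- grp[ord[1]]
      for (q in ord[-1]) {
        ident <- cpp_nw_identity(gseq[ord[1]], gseq[q])$identity
        if (ident >= bubble_pop_identity) losers <- c(losers, grp[q])
      }
    }
    if (length(losers)) {
      rm_nodes <- unique(unlist(u$paths[losers]))
      upd <- drop_nodes(kmers, counts, rm_nodes)
      kmers <- upd$kmers; counts <- upd$counts
      if (length(kmers) == 0) return(empty())
      next
    }
    break
  }

  u <- unitigs_of(kmers, counts)
  keep <- which(nchar(u$seqs) >= min_contig_len)
  seqs <- u$seqs[keep]; cov <- u$cov[keep]
  rc <- revcomp(seqs)
  canon <- ifelse(rc < seqs, rc, seqs)
  ord <- order(-nchar(canon), canon)
  contigs <- data.frame(id = make_ids("contig", length(keep)),
                        seq = canon[ord], length = nchar(canon[ord]),
                        mean_kmer_coverage = cov[ord],
                        stringsAsFactors = FALSE)
  structure(list(contigs = contigs, n_reads_skipped = n_skipped,
                 params = params), class = "dbg_assembly")
}

#' @export
print.dbg_assembly <- function(x, ...) {
  cat("DBG assembly (k =", x$params$k, "):", nrow(x$contigs), "contigs")
  if (nrow(x$contigs))
    cat(", lengths", min(x$contigs$length), "-", max(x$contigs$length))
  cat("\n")
  if (x$n_reads_skipped)
    cat("  ", x$n_reads_skipped, "reads shorter than k skipped\n")
  invisible(x)
}
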