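# Read-to-OTU mapping and per-library abundance.
#
# Mapping is an exact affine semi-global alignment (read end-to-end, free
# gaps on the OTU; match +1, mismatch -1, gap open -2, gap extend -1)
# against every OTU on both strands.  The best hit is chosen by maximal
# identity, then maximal aligned columns, then lexicographically smallest
# OTU id ('+' strand before '-'), and a read is unmapped when the best
# identity or aligned length falls below the thresholds.  Ties at the best
# (identity, length) are counted so ambiguous placements can be audited.

#' Map reads onto OTU consensus sequences
#'
#' @param reads a reads data.frame or character vector of sequences.
#' @param otus OTU set: an `olc_assembly`, `dbg_assembly`, data.frame with
#'   `id`/`consensus`, or named character vector.
#' @param min_identity minimum percent identity of the best alignment for
#'   a read to be assigned (default 90).
#' @param min_aligned_len minimum alignment columns (default 50).
#' @param method `"auto"` (exhaustive DP for small problems, k-mer seeded
#'   candidate shortlist with exhaustive fallback for large ones) or
#'   `"exhaustive"`.
#' @return a data.frame of assignments: `read_id`, `library`, `otu`
#'   (`"unmapped"` when unassigned), `identity`, `aligned_cols`, `strand`,
#'   `n_ties`.
#' @export
map_reads <- function(reads, otus, min_identity = 90, min_aligned_len = 50,
                      method = c("auto", "exhaustive")) {
  method <- match.arg(method)
  if (is.character(reads))
    reads <- new_reads(names(reads) %||% make_ids("read", length(reads)),
                       reads)
  ot <- as_otu_frame(otus)
  if (nrow(ot) == 0) stop("otus must be non-empty")
  stopifnot(min_identity > 0, min_aligned_len > 0)
  res <- cpp_map_reads(reads$seq, ot$consensus, min_identity,
                       as.integer(min_aligned_len),
                       exhaustive = (method == "exhaustive"))
  data.frame(read_id = reads$id, library = reads$library,
             otu = ifelse(is.na(res$otu_idx), "unmapped",
                          ot$id[res$otu_idx]),
             identity = res$identity, aligned_cols = res$aligned_cols,
             strand = res$strand, n_ties = res$n_ties,
             stringsAsFactors = FALSE)
}

#' Map a single read
#'
#' @inheritParams map_reads
#' @param read a single DNA string.
#' @return a one-row assignment data.frame (see [map_reads()]).
#' @export
map_read <- function(read, otus, min_identity = 90, min_aligned_len = 50) {
  map_reads(setNames(read, "read"), otus, min_identity, min_aligned_len,
            method = "exhaustive")
}

#' Tabulate per-library OTU abundance
#'
#' Builds the OTU x library count matrix from read assignments, with
#' per-library unmapped counts kept alongside so that for every library
#' `column sum + unmapped == total reads`.
#'
#' @param assignments assignment data.frame from [map_reads()].
#' @param libraries library names defining the columns; defaults to the
#'   libraries present.  An assignment whose library is not listed is an
#'   error.
#' @param otu_ids OTU ids defining the rows (zero-count OTUs retained);
#'   defaults to the OTUs present.
#' @return an integer matrix of class `abundance_table` with attributes
#'   `unmapped` and `total` (named per-library vectors).
#' @export
count_abundance <- function(assignments, libraries = NULL, otu_ids = NULL) {
  libs <- as.character(assignments$library)
  if (is.null(libraries)) libraries <- sort(unique(libs))
  unknown <- setdiff(unique(libs), libraries)
  if (length(unknown))
    stop("assignment refers to unknown library: ", unknown[1])
  mapped <- assignments$otu != "unmapped"
  if (is.null(otu_ids)) otu_ids <- sort(unique(assignments$otu[mapped]))
  counts <- matrix(0L, length(otu_ids), length(libraries),
                   dimnames = list(otu_ids, libraries))
  if (any(mapped)) {
    tab <- table(factor(assignments$otu[mapped], levels = otu_ids),
                 factor(libs[mapped], levels = libraries))
    counts[] <- as.integer(tab)
  }
  total <- as.integer(table(factor(libs, levels = libraries)))
  unmapped <- total - colSums(counts)
  abundance_table(counts, setNames(unmapped, libraries),
                  setNames(total, libraries))
}

#' Construct an abundance table
#'
#' @param counts OTU x library integer matrix (dimnames required).
#' @param unmapped,total named per-library integer vectors; for every
#'   library `colSums(counts) + unmapped` must equal `total`.
#' @return the validated `abundance_table`.
#' @export
abundance_table <- function(counts, unmapped = NULL, total = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(unmapped)) unmapped <- setNames(rep(0L, ncol(counts)),
                                              colnames(counts))
  if (is.null(total)) total <- colSums(counts) + unmapped
  if (any(counts < 0)) stop("negative abundance")
  if (!isTRUE(all.equal(unname(colSums(counts) + unmapped),
                        as.numeric(unname(total)))))
    stop("abundance table violates conservation: column sums + unmapped ",
         "must equal totals")
  structure(counts, unmapped = unmapped[colnames(counts)],
            total = total[colnames(counts)],
            class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", nrow(x), "OTUs x", ncol(x), "libraries\n")
  print(`attributes<-`(x, list(dim = dim(x), dimnames = dimnames(x))))
  cat("unmapped:", paste(sprintf("%s=%d", colnames(x),
                                 attr(x, "unmapped")), collapse = " "), "\n")
  invisible(x)
}

#' Down-sample libraries to equal depth
#'
#' Randomly subsamples every library's mapped reads, without replacement,
#' to the depth of the smallest library (rarefaction), so ecological
#' comparisons see equal sampling effort.  The returned table's unmapped
#' counts are zero (down-sampling operates on the mapped profile).
#'
#' @param table an `abundance_table`.
#' @param seed integer RNG seed; the same seed reproduces the same table.
#' @return a down-sampled `abundance_table` with attribute `seed`; the
#'   input table is left untouched for retention alongside.
#' @export
downsample_abundance <- function(table, seed) {
  stopifnot(inherits(table, "abundance_table"))
  depths <- colSums(table)
  if (any(depths == 0))
    stop("library with zero mapped reads: ",
         colnames(table)[depths == 0][1],
         "; exclude it before down-sampling")
  target <- min(depths)
  out <- with_seed(seed, {
    vapply(seq_len(ncol(table)), function(j) {
      pool <- rep(seq_len(nrow(table)), table[, j])
      kept <- pool[sample.int(length(pool), target)]
      tabulate(kept, nbins = nrow(table))
    }, integer(nrow(table)))
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(table))
  dimnames(out) <- dimnames(table)
  res <- abundance_table(out,
                         unmapped = setNames(rep(0L, ncol(table)),
                                             colnames(table)),
                         total = setNames(rep(as.integer(target),
                                              ncol(table)),
                                          colnames(table)))
  attr(res, "seed") <- seed
  res
}
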