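# Synthetic barcode community generator and amplicon read simulator.
#
# The generator emulates the structure of the cpn60 validation community:
# n coding sequences whose pairwise nucleotide identities span a configured
# envelope (60-96% by default), including one near-identical pair whose
# divergence is purely synonymous so the translated peptides are identical.
# Members are derived from a single random ancestor coding sequence by
# per-member substitution loads, then the realized identity matrix is
# nudged site-by-site until both ends of the envelope are attained.

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("T","C","A","G"), c("T","C","A","G"),
                                  paste0)), c("T","C","A","G"), paste0)),
  c("TAA", "TAG", "TGA"))

# codon table for synonymous third-position changes
codon_aa <- local({
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(SENSE_CODONS)))
  setNames(aa, SENSE_CODONS)
})

seq_to_codons <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

has_internal_stop_nt <- function(s) {
  any(seq_to_codons(s) %in% c("TAA", "TAG", "TGA"))
}

# Hamming identity for equal-length sequences (the generator works in a
# substitution-only space, where global alignment reduces to this)
hamming_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  100 * sum(av == bv) / length(av)
}

#' Generate a synthetic barcode community
#'
#' Builds `n` protein-coding DNA sequences (no internal stops in frame 0,
#' length divisible by 3) whose pairwise global-alignment identities lie in
#' `[identity_min, identity_max]`, with at least one pair attaining each
#' end of the envelope to within one percentage point.  When
#' `synonymous_pair = TRUE` the maximum-identity pair differs only by
#' synonymous third-position substitutions, so its frame-0 peptides are
#' identical.
#'
#' Member proportions default to a geometric abundance series (ratio
#' `geometric_ratio`) as a stand-in for an uneven community.
#'
#' @param n number of members (>= 2).
#' @param length_nt sequence length in bases, divisible by 3 (default 552).
#' @param identity_min,identity_max pairwise identity envelope in percent.
#' @param synonymous_pair make the top pair synonymous-only (default TRUE).
#' @param geometric_ratio ratio of the geometric abundance series
#'   (default 0.85).
#' @param seed integer RNG seed; the same seed reproduces the same
#'   community exactly.
#' @return an object of class `community_template`: a list with `members`
#'   (data.frame `name`, `seq`), `proportions`, `identity_matrix`, and the
#'   generation parameters.
#' @export
generate_community <- function(n, length_nt = 552, identity_min = 60,
                               identity_max = 96, synonymous_pair = TRUE,
                               geometric_ratio = 0.85, seed = 1) {
  if (n < 2) stop("n must be >= 2")
  if (length_nt %% 3 != 0) stop("length_nt must be divisible by 3")
  if (identity_min <= 0 || identity_max > 100 || identity_min > identity_max)
    stop("infeasible identity constraints: need 0 < identity_min <= ",
         "identity_max <= 100")
  if (identity_max >= 100 - 1e-9 && !synonymous_pair)
    stop("infeasible constraints: identity_max = 100 requires ",
         "synonymous_pair = TRUE for distinct members")
  L <- length_nt
  with_seed(seed, {
    n_codons <- L / 3
    ancestor <- paste(sample(SENSE_CODONS, n_codons, replace = TRUE),
                      collapse = "")
    anc <- strsplit(ancestor, "")[[1]]

    mutate_sites <- function(seqv, k, avoid = NULL) {
      # apply k random substitutions avoiding in-frame stops
      sites <- sample(setdiff(seq_len(L), avoid), k)
      for (p in sites) {
        for (try_base in sample(setdiff(c("A","C","G","T"), seqv[p]))) {
          old <- seqv[p]; seqv[p] <- try_base
          cod0 <- (p - 1) %/% 3
          codon <- paste(seqv[(cod0 * 3 + 1):(cod0 * 3 + 3)], collapse = "")
          if (!(codon %in% c("TAA", "TAG", "TGA"))) break
          seqv[p] <- old
        }
      }
      seqv
    }

    n_core <- if (synonymous_pair) n - 1 else n
    # per-member divergence ladder from the ancestor
    diff_max <- 1 - identity_min / 100
    d_hi <- if (diff_max > 0) (2 - sqrt(max(0, 4 - 16 * diff_max / 3))) /
      (8 / 3) else 0
    gap <- min(3, (identity_max - identity_min) / 2)
    diff_top <- 1 - (identity_max - gap) / 100
    d_lo <- diff_top / 2
    dvg <- if (n_core == 1) 0 else seq(d_lo, d_hi, length.out = n_core)
    members <- vector("list", n)
    for (i in seq_len(n_core)) {
      k <- round(dvg[i] * L)
      members[[i]] <- if (k == 0) anc else mutate_sites(anc, k)
    }
    if (synonymous_pair) {
      # top pair: synonymous third-position changes on a copy of the most
      # diverged core member
      parent <- members[[n_core]]
      s <- max(1L, round((1 - identity_max / 100) * L))
      cods <- seq_to_codons(paste(parent, collapse = ""))
      opts <- lapply(seq_along(cods), function(ci) {
        third <- substr(cods[ci], 3, 3)
        alt <- setdiff(c("A","C","G","T"), third)
        alt_cod <- paste0(substr(cods[ci], 1, 2), alt)
        alt[alt_cod %in% SENSE_CODONS &
              codon_aa[alt_cod] == codon_aa[cods[ci]]]
      })
      avail <- which(lengths(opts) > 0)
      if (length(avail) < s)
        stop("infeasible constraints: only ", length(avail), " codons ",
             "admit synonymous changes but ", s, " are required")
      pick <- sample(avail, s)
      twin <- parent
      for (ci in pick) {
        alt <- sample(opts[[ci]], 1)
        twin[ci * 3] <- alt
      }
      members[[n]] <- twin
    }

    seqs <- vapply(members, paste, "", collapse = "")
    names(seqs) <- make_ids("member", n)

    # realized identity matrix (equal lengths, substitution-only space)
    idm <- function(sq) {
      M <- diag(100, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        M[i, j] <- M[j, i] <- hamming_identity(sq[i], sq[j])
      M
    }
    seqv_list <- members
    M <- idm(seqs)
    syn_pair <- if (synonymous_pair) c(n_core, n) else NULL
    cap_pairs <- function(M) {
      # off-diagonal pairs excluding the synonymous pair
      Mx <- M; diag(Mx) <- NA
      if (!is.null(syn_pair)) Mx[syn_pair[1], syn_pair[2]] <-
          Mx[syn_pair[2], syn_pair[1]] <- NA
      Mx
    }

    # nudge the realized envelope onto its configured ends
    if (n > 2) {
      for (iter in 1:4000) {
        Mx <- cap_pairs(M)
        lo <- min(Mx, na.rm = TRUE)
        done_lo <- abs(lo - identity_min) <= 0.5 ||
          (lo >= identity_min && lo <= identity_min + 0.5)
        # keep every pair inside [min-1, max+1]
        viol_hi <- which(Mx > identity_max - 0.5, arr.ind = TRUE)
        if (!nrow(viol_hi) && done_lo) break
        if (nrow(viol_hi)) {
          ij <- viol_hi[1, ]
        } else {
          ij <- which(Mx == lo, arr.ind = TRUE)[1, ]
        }
        i <- min(ij); j <- max(ij)
        a <- seqv_list[[i]]; b <- seqv_list[[j]]
        target_raise <- !nrow(viol_hi) && lo < identity_min - 0.5
        # never edit a synonymous-pair member's partner-relevant identity
        # by editing the twin; edit the non-pair member where possible
        edit <- if (!is.null(syn_pair) && j %in% syn_pair &&
                    !(i %in% syn_pair)) i else j
        ev <- seqv_list[[edit]]; ov <- seqv_list[[if (edit == i) j else i]]
        if (target_raise) {
          # revert one differing non-ancestral site toward the ancestor
          cand <- which(ev != ov & ev != anc & ov == anc)
          if (!length(cand)) cand <- which(ev != ov & ev != anc)
          if (!length(cand)) break
          p <- cand[sample.int(length(cand), 1)]
          old <- ev[p]; ev[p] <- anc[p]
          cod0 <- (p - 1) %/% 3
          codon <- paste(ev[(cod0 * 3 + 1):(cod0 * 3 + 3)], collapse = "")
          if (codon %in% c("TAA", "TAG", "TGA")) { ev[p] <- old; next }
        } else {
          # push the pair apart at a currently matching site
          cand <- which(ev == ov)
          if (!length(cand)) break
          p <- cand[sample.int(length(cand), 1)]
          for (try_base in sample(setdiff(c("A","C","G","T"), ev[p]))) {
            old <- ev[p]; ev[p] <- try_base
            cod0 <- (p - 1) %/% 3
            codon <- paste(ev[(cod0 * 3 + 1):(cod0 * 3 + 3)],
                           collapse = "")
            if (!(codon %in% c("TAA", "TAG", "TGA"))) break
            ev[p] <- old
          }
          if (identical(ev, seqv_list[[edit]])) next
        }
        seqv_list[[edit]] <- ev
        s_new <- paste(ev, collapse = "")
        seqs[edit] <- s_new
        for (kx in seq_len(n)) if (kx != edit)
          M[edit, kx] <- M[kx, edit] <- hamming_identity(s_new, seqs[kx])
      }
    }
    Mx <- cap_pairs(M)
    if (n > 2) {
      if (min(Mx, na.rm = TRUE) < identity_min - 1 ||
          abs(min(Mx, na.rm = TRUE) - identity_min) > 1)
        stop("community generation failed to attain identity_min; ",
             "realized minimum ", round(min(Mx, na.rm = TRUE), 2))
      if (max(M[upper.tri(M)]) > identity_max + 1)
        stop("community generation exceeded identity_max")
    }
    if (!is.null(syn_pair)) {
      top <- M[syn_pair[1], syn_pair[2]]
      if (abs(top - identity_max) > 1)
        stop("synonymous pair missed identity_max: realized ", round(top, 2))
      if (n > 2 && max(Mx, na.rm = TRUE) >= top)
        stop("synonymous pair is not the maximum-identity pair")
    }
    stopifnot(!any(vapply(seqs, has_internal_stop_nt, TRUE)))

    props <- geometric_ratio ^ (seq_len(n) - 1)
    props <- props / sum(props)
    structure(list(
      members = data.frame(name = names(seqs), seq = unname(seqs),
                           stringsAsFactors = FALSE),
      proportions = setNames(props, names(seqs)),
      identity_matrix = `dimnames<-`(M, list(names(seqs), names(seqs))),
      synonymous_pair = if (!is.null(syn_pair)) names(seqs)[syn_pair] else NULL,
      params = list(n = n, length_nt = L, identity_min = identity_min,
                    identity_max = identity_max,
                    synonymous_pair = synonymous_pair,
                    geometric_ratio = geometric_ratio, seed = seed)),
      class = "community_template")
  })
}

#' @export
print.community_template <- function(x, ...) {
  M <- x$identity_matrix; diag(M) <- NA
  cat("Synthetic barcode community:", nrow(x$members), "members of",
      nchar(x$members$seq[1]), "bp\n")
  cat(sprintf("  pairwise identity: %.1f-%.1f%%\n",
              min(M, na.rm = TRUE), max(M, na.rm = TRUE)))
  if (!is.null(x$synonymous_pair))
    cat("  synonymous (identical-peptide) pair:",
        paste(x$synonymous_pair, collapse = " / "), "\n")
  invisible(x)
}

#' Translate community members to peptides
#'
#' Frame-0 translation of every member; used as the protein reference for
#' reading-frame identification in simulated runs.
#'
#' @param community a `community_template`.
#' @return a `reference_set` data.frame of peptides.
#' @export
community_peptides <- function(community) {
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(community$members$seq)))
  res <- data.frame(id = community$members$name,
                    desc = community$members$name,
                    seq = pep, stringsAsFactors = FALSE)
  attr(res, "alphabet") <- "aa"
  class(res) <- c("reference_set", "data.frame")
  res
}

#' Simulate amplicon reads from a community
#'
#' Each read is drawn from one member (or, with probability
#' `chimera_rate`, from a two-member chimera joined at a uniform breakpoint
#' in the central half of the template), taken from the 5' or 3' end of the
#' primer-flanked amplicon, and subjected to i.i.d. substitution (and
#' optionally indel) errors.  Every read carries its ground-truth source in
#' `truth_source` (`"chimera:A+B"` for chimeras).
#'
#' @param community a `community_template`.
#' @param n_reads reads per library.
#' @param libraries character vector of library names.
#' @param read_length_mean,read_length_sd normal read-length model (bp).
#' @param frac_5prime fraction of reads taken from the 5' end.
#' @param error_rate per-base substitution probability.
#' @param indel_rate per-base indel probability (default 0).
#' @param chimera_rate fraction of chimeric reads.
#' @param primer_f,primer_r PCR primer sequences flanking the amplicon.
#' @param qual_const constant Phred quality assigned to simulated bases.
#' @param seed integer RNG seed; output is reproducible byte-for-byte.
#' @return a list with `reads` (reads data.frame) and `truth` (a
#'   `community_truth`: members, proportions and per-read sources).
#' @export
simulate_reads <- function(community, n_reads = 5000, libraries = "lib1",
                           read_length_mean = 400, read_length_sd = 40,
                           frac_5prime = 0.5, error_rate = 0.005,
                           indel_rate = 0, chimera_rate = 0,
                           primer_f = "GAAGTCGAGCTTGAAGACCC",
                           primer_r = "CTTCAGGCACAGTTCAGGAC",
                           qual_const = 30L, seed = 1) {
  stopifnot(inherits(community, "community_template"))
  rates <- c(frac_5prime, error_rate, indel_rate, chimera_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (n_reads < 1) stop("n_reads must be positive")
  primer_f <- validate_dna(primer_f, "forward primer")
  primer_r <- validate_dna(primer_r, "reverse primer")
  mem <- community$members
  n_mem <- nrow(mem)
  mlen <- nchar(mem$seq)
  amp_len <- mlen + nchar(primer_f) + nchar(primer_r)
  if (read_length_mean > min(amp_len))
    stop("read_length_mean (", read_length_mean,
         ") exceeds the shortest amplicon length (", min(amp_len), ")")
  if (chimera_rate > 0 && n_mem < 2)
    stop("chimeric reads require at least 2 members")
  props <- community$proportions
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    all_reads <- vector("list", length(libraries))
    all_truth <- vector("list", length(libraries))
    for (li in seq_along(libraries)) {
      lib <- libraries[li]
      is_chi <- runif(n_reads) < chimera_rate
      src_a <- sample.int(n_mem, n_reads, replace = TRUE, prob = props)
      src_b <- rep(NA_integer_, n_reads)
      tmpl <- character(n_reads)
      truth <- character(n_reads)
      for (r in seq_len(n_reads)) {
        if (is_chi[r]) {
          b <- sample.int(n_mem - 1, 1, prob = props[-src_a[r]])
          b <- setdiff(seq_len(n_mem), src_a[r])[b]
          src_b[r] <- b
          L <- mlen[src_a[r]]
          bp <- sample(seq(floor(0.25 * L), ceiling(0.75 * L)), 1)
          tmpl[r] <- paste0(substr(mem$seq[src_a[r]], 1, bp),
                            substr(mem$seq[b], bp + 1, mlen[b]))
          truth[r] <- paste0("chimera:", mem$name[src_a[r]], "+",
                             mem$name[b])
        } else {
          tmpl[r] <- mem$seq[src_a[r]]
          truth[r] <- mem$name[src_a[r]]
        }
      }
      amplicon <- paste0(primer_f, tmpl, revcomp(primer_r))
      alen <- nchar(amplicon)
      len <- pmin(pmax(30L, round(rnorm(n_reads, read_length_mean,
                                        read_length_sd))), alen)
      from5 <- runif(n_reads) < frac_5prime
      raw <- ifelse(from5, substr(amplicon, 1, len),
                    revcomp(substr(amplicon, alen - len + 1, alen)))
      # substitution errors
      seqs <- if (error_rate == 0 && indel_rate == 0) unname(raw) else
        vapply(raw, function(s) {
        v <- strsplit(s, "")[[1]]
        hit <- which(runif(length(v)) < error_rate)
        for (p in hit) v[p] <- sample(setdiff(bases, v[p]), 1)
        if (indel_rate > 0) {
          ind <- which(runif(length(v)) < indel_rate)
          for (p in rev(ind)) {
            if (runif(1) < 0.5) v <- v[-p]           # deletion
            else v <- append(v, sample(bases, 1), p) # insertion
          }
        }
        paste(v, collapse = "")
      }, "", USE.NAMES = FALSE)
      ids <- sprintf("%s_r%06d", lib, seq_len(n_reads))
      qual <- vapply(nchar(seqs), function(nc)
        strrep(rawToChar(as.raw(qual_const + 33L)), nc), "")
      all_reads[[li]] <- new_reads(ids, seqs, qual, lib, truth)
      all_truth[[li]] <- data.frame(read_id = ids, source = truth,
                                    library = lib, end = ifelse(from5, "5p", "3p"),
                                    stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, all_reads)
    truth <- structure(list(
      members = mem, proportions = props,
      read_sources = do.call(rbind, all_truth),
      synonymous_pair = community$synonymous_pair),
      class = "community_truth")
    list(reads = reads, truth = truth)
  })
}

#' Pairwise global-alignment identity
#'
#' Percent identity (matches / alignment columns x 100) of the optimal
#' global alignment under match +1, mismatch -1, gap -2.  Symmetric.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap scoring parameters.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  cpp_nw_identity(toupper(a), toupper(b), match, mismatch, gap)$identity
}

#' Write simulator outputs to disk
#'
#' Writes the community FASTA, a per-read truth TSV and one FASTQ per
#' library.
#'
#' @param sim result of [simulate_reads()].
#' @param community the `community_template` the reads were drawn from.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(community = file.path(dir, "community.fasta"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(community$members$name, community$members$seq, paths["community"])
  write.table(sim$truth$read_sources, paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (lib in unique(sim$reads$library)) {
    p <- file.path(dir, paste0(lib, ".fastq"))
    write_fastq(sim$reads[sim$reads$library == lib, ], p)
    paths[lib] <- p
  }
  invisible(paths)
}
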