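# Independent reference implementations used as oracles.  These are
# straightforward full dynamic-programming / brute-force versions written
# in plain R, kept deliberately separate from the package's optimized
# paths; tie preferences mirror the documented conventions so results are
# comparable exactly.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, n_sub) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), n_sub)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# global alignment, linear gap, identity from traceback (diag > up > left)
r_nw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0L, n + 1, m + 1)
  D <- matrix(0L, n + 1, m + 1)  # 0 diag, 1 up, 2 left
  S[1, ] <- (0:m) * gap; D[1, ] <- 2L
  S[, 1] <- (0:n) * gap; D[, 1] <- 1L
  for (i in 1:n) for (j in 1:m) {
    sd <- S[i, j] + if (av[i] == bv[j] && av[i] != "N") match else mismatch
    su <- S[i, j + 1] + gap
    sl <- S[i + 1, j] + gap
    best <- sd; d <- 0L
    if (su > best) { best <- su; d <- 1L }
    if (sl > best) { best <- sl; d <- 2L }
    S[i + 1, j + 1] <- best; D[i + 1, j + 1] <- d
  }
  i <- n; j <- m; cols <- 0L; matches <- 0L
  while (i > 0 || j > 0) {
    d <- D[i + 1, j + 1]
    if (i > 0 && j > 0 && d == 0L) {
      if (av[i] == bv[j] && av[i] != "N") matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && d == 1L) i <- i - 1 else j <- j - 1
    cols <- cols + 1L
  }
  list(score = S[n + 1, m + 1], identity = 100 * matches / cols)
}

# affine local alignment score (no traceback)
r_sw_score <- function(a, b, match = 1, mismatch = -1, gap_open = -2,
                       gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv); NEG <- -1e9
  M <- matrix(0, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    sub <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
    M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + sub
    X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open, X[i, j + 1] + gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, Y[i + 1, j] + gap_extend)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# semi-global (query end-to-end, free subject ends), affine; identity from
# a traceback with the same preferences as the implementation
# (M > Ix > Iy; end at smallest subject column among maxima, M before Ix)
r_semiglobal <- function(q, s, match = 1, mismatch = -1, gap_open = -2,
                         gap_extend = -1) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  pM <- matrix(1L, n + 1, m + 1); pX <- matrix(1L, n + 1, m + 1)
  pY <- matrix(1L, n + 1, m + 1)
  M[1, ] <- 0
  for (i in 1:n) {
    xo <- M[i, 1] + gap_open; xe <- X[i, 1] + gap_extend
    if (xo >= xe) { X[i + 1, 1] <- xo; pX[i + 1, 1] <- 1L }
    else { X[i + 1, 1] <- xe; pX[i + 1, 1] <- 2L }
    for (j in 1:m) {
      sub <- if (qv[i] == sv[j] && qv[i] != "N") match else mismatch
      mv <- NEG; mp <- 1L
      if (M[i, j] > mv) { mv <- M[i, j]; mp <- if (i == 1) 0L else 1L }
      if (X[i, j] > mv) { mv <- X[i, j]; mp <- 2L }
      if (Y[i, j] > mv) { mv <- Y[i, j]; mp <- 3L }
      M[i + 1, j + 1] <- mv + sub; pM[i + 1, j + 1] <- mp
      xo <- M[i, j + 1] + gap_open; xe <- X[i, j + 1] + gap_extend
      if (xo >= xe) { X[i + 1, j + 1] <- xo; pX[i + 1, j + 1] <- 1L }
      else { X[i + 1, j + 1] <- xe; pX[i + 1, j + 1] <- 2L }
      yo <- M[i + 1, j] + gap_open; ye <- Y[i + 1, j] + gap_extend
      if (yo >= ye) { Y[i + 1, j + 1] <- yo; pY[i + 1, j + 1] <- 1L }
      else { Y[i + 1, j + 1] <- ye; pY[i + 1, j + 1] <- 3L }
    }
  }
  best <- NEG; bj <- 0L; bstate <- 1L
  for (j in 0:m) {
    if (M[n + 1, j + 1] > best) { best <- M[n + 1, j + 1]; bj <- j; bstate <- 1L }
    if (X[n + 1, j + 1] > best) { best <- X[n + 1, j + 1]; bj <- j; bstate <- 2L }
  }
  i <- n; j <- bj; st <- bstate; cols <- 0L; matches <- 0L
  while (i > 0) {
    if (st == 1L) {
      if (qv[i] == sv[j] && qv[i] != "N") matches <- matches + 1L
      cols <- cols + 1L
      p <- pM[i + 1, j + 1]; i <- i - 1; j <- j - 1
      if (p == 0L) break
      st <- p
    } else if (st == 2L) {
      cols <- cols + 1L; p <- pX[i + 1, j + 1]; i <- i - 1; st <- p
    } else {
      cols <- cols + 1L; p <- pY[i + 1, j + 1]; j <- j - 1; st <- p
    }
  }
  list(score = best, identity = 100 * matches / cols, columns = cols)
}

# brute-force gapless overlap scan: best qualifying overlap of oriented b
# against a over every offset and both strands (matches desc, length desc,
# '+' first, offset asc)
r_best_overlap <- function(a, b, min_len, min_ident) {
  la <- nchar(a); lb <- nchar(b)
  av <- strsplit(a, "")[[1]]
  best <- NULL
  for (orient in c("+", "-")) {
    bs <- if (orient == "+") b else revcomp(b)
    bv <- strsplit(bs, "")[[1]]
    for (d in (-(lb - min_len)):(la - min_len)) {
      lo <- max(0, d); hi <- min(la, d + lb)
      len <- hi - lo
      if (len < min_len) next
      apos <- (lo + 1):hi
      bpos <- apos - d
      matches <- sum(av[apos] == bv[bpos] & av[apos] != "N")
      ident <- 100 * matches / len
      if (ident < min_ident) next
      cand <- list(orient = orient, offset = d, length = len,
                   matches = matches, identity = ident)
      if (is.null(best) ||
          matches > best$matches ||
          (matches == best$matches && len > best$length) ||
          (matches == best$matches && len == best$length &&
           orient == "+" && best$orient == "-") ||
          (matches == best$matches && len == best$length &&
           orient == best$orient && d < best$offset))
        best <- cand
    }
  }
  best
}

# exhaustive best-hit mapping of one read over all OTUs and strands,
# ranked like the implementation (identity desc, columns desc, otu id asc,
# '+' before '-')
r_map_best <- function(read, otus, min_identity, min_aligned_len) {
  ot <- otus[order(otus$id), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(ot))) {
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") read else revcomp(read)
      al <- r_semiglobal(qq, ot$consensus[i])
      cand <- list(otu = ot$id[i], strand = strand,
                   identity = al$identity, columns = al$columns,
                   score = al$score)
      if (is.null(best) ||
          cand$identity > best$identity ||
          (cand$identity == best$identity && cand$columns > best$columns))
        best <- cand
    }
  }
  if (best$identity < min_identity || best$columns < min_aligned_len)
    best$otu <- "unmapped"
  best
}

# brute-force anchored primer prefix scan (mismatch-count based)
r_trim_prefix <- function(seq, primers, max_mismatch, slack) {
  sv <- strsplit(seq, "")[[1]]
  best <- 0L; best_mm <- Inf
  for (pr in primers) {
    pv <- strsplit(pr, "")[[1]]
    pl <- length(pv)
    if (pl > length(sv)) next
    for (off in 0:slack) {
      if (off + pl > length(sv)) break
      win <- sv[(off + 1):(off + pl)]
      mm <- sum(!mapply(function(p, b)
        b %in% otuforge:::IUPAC_SETS[[p]], pv, win))
      if (mm <= max_mismatch && (mm < best_mm ||
                                 (mm == best_mm && off + pl > best))) {
        best <- off + pl; best_mm <- mm
      }
    }
  }
  best
}

# Biostrings-based independent score oracles
bios_global_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = 2,
                                type = "global", scoreOnly = TRUE)
}

bios_local_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                gapOpening = 1, gapExtension = 1,
                                type = "local", scoreOnly = TRUE)
}

# shared small fixture: community + error-free or noisy reads
make_test_sim <- function(n_members = 6, length_nt = 300, n_reads = 600,
                          identity_min = 60, identity_max = 90,
                          synonymous_pair = FALSE, error_rate = 0,
                          read_length_mean = 220, seed = 7,
                          sim_seed = 17, ...) {
  com <- generate_community(n_members, length_nt, identity_min,
                            identity_max, synonymous_pair, seed = seed)
  sim <- simulate_reads(com, n_reads = n_reads, error_rate = error_rate,
                        read_length_mean = read_length_mean,
                        read_length_sd = read_length_mean / 10,
                        seed = sim_seed, ...)
  list(com = com, sim = sim)
}

TEST_PRIMER_F <- "GAAGTCGAGCTTGAAGACCC"
TEST_PRIMER_R <- "CTTCAGGCACAGTTCAGGAC"
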