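# Dereplication, reading-frame identification and peptide collapse

test_that("identical, reverse-complement and contained OTUs are merged", {
  tab <- abundance_table(matrix(c(4L, 6L, 2L, 1L), 4,
                                dimnames = list(sprintf("otu_%04d", 1:4),
                                                "libA")))
  otus <- data.frame(
    id = sprintf("otu_%04d", 1:4),
    consensus = c("ACGTACGTCCGG", "ACGTACGTCCGG",
                  revcomp("ACGTACGTCCGG"), "GTACGTCC"),
    stringsAsFactors = FALSE)
  dr <- dereplicate_nt(otus, tab)
  expect_equal(nrow(dr$otus), 1)
  expect_equal(dr$otus$id, "otu_0001")
  expect_equal(unname(dr$table["otu_0001", ]), 13L)
  # one-base difference: both retained
  otus2 <- data.frame(id = c("a", "b"),
                      consensus = c("ACGTACGTCCGG", "ACGTACGTCCGA"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(dereplicate_nt(otus2)$otus), 2)
})

test_that("frame identification recovers the generative frame and strand", {
  com <- generate_community(4, 300, seed = 6)
  pref <- community_peptides(com)
  cds <- com$members$seq[2]
  f <- find_frame(cds, pref)
  expect_equal(f$frame, 1)
  expect_false(f$has_internal_stop)
  expect_equal(f$peptide, pref$seq[2])
  frc <- find_frame(revcomp(cds), pref)
  expect_equal(frc$frame, -1)
  expect_equal(frc$peptide, f$peptide)
  # offset frames
  expect_equal(find_frame(substr(cds, 2, 300), pref)$frame, 3)
  expect_error(find_frame("AC", pref), "shorter than 3")
})

test_that("a frameshift is detected as internal stop or low score", {
  set.seed(44)
  com <- generate_community(4, 300, seed = 6)
  pref <- community_peptides(com)
  cds <- com$members$seq[1]
  broken <- paste0(substr(cds, 1, 150), substr(cds, 152, 300))
  f <- find_frame(broken, pref)
  # six-frame oracle: the chosen frame must be the score argmax
  bl <- otuforge:::get_blosum62()
  alpha <- paste(rownames(bl), collapse = "")
  oracle <- vapply(c(1, 2, 3, -1, -2, -3), function(fr) {
    p <- translate_frame(broken, fr)
    if (nchar(p) == 0) return(-Inf)
    max(vapply(pref$seq, function(r)
      otuforge:::cpp_protein_sw_score(p, r, bl, alpha), 0L))
  }, 0)
  expect_equal(f$score, max(oracle))
  expect_true(f$has_internal_stop ||
                f$score < 2 * max(nchar(pref$seq)))
})

test_that("frame recovery is exact across a seeded suite", {
  set.seed(55)
  com <- generate_community(6, 330, seed = 23)
  pref <- community_peptides(com)
  n_ok <- 0; n <- 200
  for (q in seq_len(n)) {
    m <- sample(6, 1)
    off <- sample(0:2, 1)
    padded <- paste0(random_dna(off), com$members$seq[m],
                     random_dna(sample(0:2, 1)))
    fr_true <- off + 1
    if (q %% 2 == 0) { padded <- revcomp(padded); fr_true <- -(off + 1) }
    got <- find_frame(padded, pref)
    if (got$frame == fr_true) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, n)
})

test_that("synonymous nucleotide OTUs collapse into one peptide OTU", {
  com <- generate_community(5, 300, identity_min = 70, identity_max = 95,
                            synonymous_pair = TRUE, seed = 31)
  pref <- community_peptides(com)
  otus <- data.frame(id = sprintf("otu_%04d", 1:5),
                     consensus = com$members$seq, stringsAsFactors = FALSE)
  tab <- abundance_table(matrix(c(10L, 8L, 6L, 4L, 2L), 5,
                                dimnames = list(otus$id, "libA")))
  fr <- find_frames(otus, pref)
  cp <- collapse_peptides(fr, tab)
  expect_equal(nrow(cp$peptide_otus), 4)
  merged <- cp$peptide_otus[grepl(",", cp$peptide_otus$members), ]
  expect_equal(nrow(merged), 1)
  syn_idx <- match(com$synonymous_pair, com$members$name)
  expect_setequal(strsplit(merged$members, ",")[[1]],
                  otus$id[syn_idx])
  # count conservation
  expect_equal(sum(cp$table), sum(tab))
  # type invariant: translating each member in its frame gives the peptide
  for (q in seq_len(nrow(cp$peptide_otus))) {
    members <- strsplit(cp$peptide_otus$members[q], ",")[[1]]
    frs <- as.integer(strsplit(cp$peptide_otus$frames[q], ",")[[1]])
    for (w in seq_along(members)) {
      nt <- otus$consensus[otus$id == members[w]]
      expect_true(grepl(translate_frame(nt, frs[w]),
                        cp$peptide_otus$peptide[q], fixed = TRUE))
    }
  }
})

test_that("internal-stop OTUs are excluded and counts reconciled", {
  com <- generate_community(3, 300, seed = 41)
  pref <- community_peptides(com)
  cds <- com$members$seq
  broken <- paste0(substr(cds[3], 1, 100), substr(cds[3], 102, 300))
  otus <- data.frame(id = c("otu_0001", "otu_0002", "otu_0003"),
                     consensus = c(cds[1], cds[2], broken),
                     stringsAsFactors = FALSE)
  tab <- abundance_table(matrix(c(5L, 3L, 2L), 3,
                                dimnames = list(otus$id, "libA")))
  fr <- find_frames(otus, pref)
  cp <- collapse_peptides(fr, tab)
  if (length(cp$excluded)) {
    expect_equal(sum(cp$table),
                 sum(tab) - sum(tab[cp$excluded, , drop = FALSE]))
    expect_equal(unname(attr(cp$table, "total")),
                 unname(attr(tab, "total")))
  } else {
    expect_equal(sum(cp$table), sum(tab))
  }
  # single clean OTU passes counts through unchanged
  cp1 <- collapse_peptides(fr[1, , drop = FALSE],
                           abundance_table(tab[1, , drop = FALSE]))
  expect_equal(unname(cp1$table[1, ]), 5L)
})
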