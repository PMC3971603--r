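# Split-end chimera classification and filtering

chim_fixture <- function(seed = 19) {
  com <- generate_community(8, 552, identity_min = 60, identity_max = 88,
                            synonymous_pair = FALSE, seed = seed)
  setNames(com$members$seq, com$members$name)
}

test_that("an OTU equal to a reference is non-chimeric", {
  refs <- chim_fixture()
  v <- c3_classify(setNames(refs[1], "otu_0001"), refs)
  expect_equal(v$status, "non-chimeric")
  expect_match(v$best5_refs, names(refs)[1])
  expect_match(v$best3_refs, names(refs)[1])
  # the reverse complement is also consistent (orientation-aware)
  v2 <- c3_classify(setNames(revcomp(refs[1]), "otu_0001"), refs)
  expect_equal(v2$status, "non-chimeric")
})

test_that("constructed two-parent chimeras are flagged", {
  refs <- chim_fixture()
  chi <- paste0(substr(refs[1], 1, 300), substr(refs[5], 301, 552))
  v <- c3_classify(setNames(chi, "otu_0001"), refs)
  expect_equal(v$status, "chimeric")
  expect_match(v$best5_refs, names(refs)[1])
  expect_match(v$best3_refs, names(refs)[5])
})

test_that("short OTUs and unmatched ends are indeterminate", {
  refs <- chim_fixture()
  v <- c3_classify(setNames(substr(refs[1], 1, 250), "otu_0001"), refs,
                   end_len = 150)
  expect_equal(v$status, "indeterminate")
  v2 <- c3_classify(setNames(paste0(substr(refs[1], 1, 150),
                                    strrep("ACGT", 50),
                                    random_dna(150)), "otu_0001"),
                    refs, min_end_identity = 95)
  expect_equal(v2$status, "indeterminate")
})

test_that("near-identical reference ties do not cause false chimera calls", {
  refs <- chim_fixture()
  dup <- c(refs, setNames(refs[1], "dup_of_1"))  # identical pair in refs
  v <- c3_classify(setNames(refs[1], "otu_0001"), dup)
  expect_equal(v$status, "non-chimeric")
})

test_that("chimera filtering moves reads to unmapped and conserves totals", {
  refs <- chim_fixture()
  otus <- data.frame(id = c("otu_0001", "otu_0002"),
                     consensus = c(unname(refs[1]),
                                   paste0(substr(refs[2], 1, 300),
                                          substr(refs[6], 301, 552))),
                     stringsAsFactors = FALSE)
  tab <- abundance_table(matrix(c(12L, 7L), 2,
                                dimnames = list(otus$id, "libA")))
  v <- c3_classify(otus, refs)
  expect_equal(v$status, c("non-chimeric", "chimeric"))
  fc <- filter_chimeras(otus, tab, v)
  expect_equal(rownames(fc$table), "otu_0001")
  expect_equal(unname(attr(fc$table, "unmapped")), 7L)
  expect_equal(unname(colSums(fc$table) + attr(fc$table, "unmapped")),
               unname(attr(tab, "total")))
  # no chimeric verdicts: output identical to input
  v0 <- v; v0$status <- "non-chimeric"
  fc0 <- filter_chimeras(otus, tab, v0)
  expect_identical(unclass(fc0$table)[, , drop = FALSE],
                   unclass(tab)[, , drop = FALSE])
  # all chimeric: empty set with a warning
  v1 <- v; v1$status <- "chimeric"
  expect_warning(fc1 <- filter_chimeras(otus, tab, v1), "all OTUs")
  expect_equal(nrow(fc1$otus), 0)
})

test_that("no chimera-free assembly OTU is called chimeric", {
  fx <- make_test_sim(n_members = 5, length_nt = 450, n_reads = 500,
                      identity_min = 60, identity_max = 88,
                      error_rate = 0.005, read_length_mean = 320,
                      seed = 10, sim_seed = 31)
  tr <- trim_primers(fx$sim$reads, TEST_PRIMER_F, TEST_PRIMER_R)
  asm <- olc_assemble(tr$reads, min_overlap_len = 100)
  refs <- setNames(fx$com$members$seq, fx$com$members$name)
  v <- c3_classify(asm, refs)
  expect_equal(sum(v$status == "chimeric"), 0)
})
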