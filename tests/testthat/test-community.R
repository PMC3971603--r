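# Synthetic community generator and read simulator

test_that("generated communities honour the identity envelope", {
  com <- generate_community(8, 300, identity_min = 65, identity_max = 92,
                            synonymous_pair = TRUE, seed = 3)
  M <- com$identity_matrix
  off <- M[upper.tri(M)]
  expect_true(all(off >= 65 - 1 & off <= 92 + 1))
  expect_lt(abs(min(off) - 65), 1)
  expect_lt(abs(max(off) - 92), 1)
  # every member is a stop-free coding sequence of the requested length
  expect_true(all(nchar(com$members$seq) == 300))
  expect_false(any(vapply(com$members$seq,
                          otuforge:::has_internal_stop_nt, TRUE)))
  # the top pair is the synonymous pair, with identical peptides
  pep <- community_peptides(com)
  sp <- match(com$synonymous_pair, pep$id)
  expect_equal(pep$seq[sp[1]], pep$seq[sp[2]])
  pair_id <- M[com$synonymous_pair[1], com$synonymous_pair[2]]
  expect_equal(max(off), pair_id)
})

test_that("community generation is deterministic under the seed", {
  a <- generate_community(6, 300, seed = 11)
  b <- generate_community(6, 300, seed = 11)
  c <- generate_community(6, 300, seed = 12)
  expect_identical(a$members, b$members)
  expect_false(identical(a$members$seq, c$members$seq))
})

test_that("degenerate and infeasible envelopes are handled", {
  # synonymous-only divergence: distinct DNA, identical peptides
  com <- generate_community(2, 300, identity_min = 100, identity_max = 100,
                            synonymous_pair = TRUE, seed = 5)
  expect_false(com$members$seq[1] == com$members$seq[2])
  pep <- community_peptides(com)
  expect_equal(pep$seq[1], pep$seq[2])
  expect_error(generate_community(3, 300, identity_min = 90,
                                  identity_max = 60),
               "infeasible")
  expect_error(generate_community(3, 300, identity_min = 60,
                                  identity_max = 100,
                                  synonymous_pair = FALSE),
               "infeasible")
  expect_error(generate_community(1, 300), "n must be")
  expect_error(generate_community(4, 301), "divisible by 3")
})

test_that("pairwise identity matches its definition and the DP oracle", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 75)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
  set.seed(421)
  for (q in 1:8) {
    a <- random_dna(300)
    b <- if (q %% 2) random_dna(280) else mutate_dna(a, 30)
    got <- otuforge:::cpp_nw_identity(a, b)
    want <- r_nw(a, b)
    expect_equal(got$score, want$score)
    expect_equal(got$identity, want$identity)
    expect_equal(got$score, as.integer(bios_global_score(a, b)))
    # symmetry
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("error-free reads are exact and map back to their source", {
  fx <- make_test_sim(n_members = 2, n_reads = 20, error_rate = 0)
  amp <- setNames(paste0(TEST_PRIMER_F, fx$com$members$seq,
                         revcomp(TEST_PRIMER_R)), fx$com$members$name)
  src <- fx$sim$reads$truth_source
  hits <- vapply(seq_len(nrow(fx$sim$reads)), function(i) {
    s <- fx$sim$reads$seq[i]
    grepl(s, amp[src[i]], fixed = TRUE) ||
      grepl(revcomp(s), amp[src[i]], fixed = TRUE)
  }, TRUE)
  expect_true(all(hits))

  fx <- make_test_sim(n_members = 5, n_reads = 120, error_rate = 0)
  tr <- trim_primers(fx$sim$reads, TEST_PRIMER_F, TEST_PRIMER_R)
  asg <- map_reads(tr$reads, setNames(fx$com$members$seq,
                                      fx$com$members$name))
  src <- setNames(fx$sim$truth$read_sources$source,
                  fx$sim$truth$read_sources$read_id)
  expect_true(all(asg$otu == src[asg$read_id]))
  expect_true(all(asg$identity == 100))
})

test_that("chimeric reads are labelled and chimera_rate is respected", {
  fx <- make_test_sim(n_members = 3, n_reads = 40, chimera_rate = 1)
  expect_true(all(grepl("^chimera:", fx$sim$reads$truth_source)))
  fx0 <- make_test_sim(n_members = 3, n_reads = 40, chimera_rate = 0)
  expect_false(any(grepl("^chimera:", fx0$sim$reads$truth_source)))
})

test_that("read simulation is byte-identical under a fixed seed", {
  a <- make_test_sim(n_reads = 100, error_rate = 0.01, sim_seed = 99)
  b <- make_test_sim(n_reads = 100, error_rate = 0.01, sim_seed = 99)
  expect_identical(a$sim$reads, b$sim$reads)
  expect_identical(a$sim$truth$read_sources, b$sim$truth$read_sources)
})

test_that("simulation rejects reads longer than the template", {
  com <- generate_community(2, 150, seed = 2)
  expect_error(simulate_reads(com, n_reads = 5, read_length_mean = 500),
               "exceeds")
})

test_that("empirical member proportions converge to the configured ones", {
  com <- generate_community(5, 300, identity_min = 65, identity_max = 90,
                            synonymous_pair = FALSE, seed = 8)
  rejections <- 0
  for (s in 1:20) {
    sim <- simulate_reads(com, n_reads = 10000, error_rate = 0,
                          read_length_mean = 200, seed = 1000 + s)
    counts <- table(factor(sim$truth$read_sources$source,
                           levels = com$members$name))
    p <- stats::chisq.test(counts, p = com$proportions)$p.value
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 1)
})
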