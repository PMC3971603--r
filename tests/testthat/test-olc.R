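# Overlap detection and greedy OLC assembly

test_that("overlap detection finds containments and dovetails", {
  tmpl <- random_dna(200)
  ed <- find_overlaps(setNames(c(tmpl, tmpl), c("r1", "r2")),
                      min_overlap_len = 100)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$length, 200)
  expect_equal(ed$identity, 100)

  a <- paste0(random_dna(80), substr(tmpl, 1, 120))
  b <- paste0(substr(tmpl, 1, 120), random_dna(90))
  ed <- find_overlaps(setNames(c(a, b), c("r1", "r2")),
                      min_overlap_len = 100)
  expect_equal(ed$length, 120)
  expect_equal(ed$offset, 80)
  # below the threshold: no edge
  a2 <- paste0(random_dna(80), substr(tmpl, 1, 80))
  b2 <- paste0(substr(tmpl, 1, 80), random_dna(90))
  ed <- find_overlaps(setNames(c(a2, b2), c("r1", "r2")),
                      min_overlap_len = 100)
  expect_equal(nrow(ed), 0)
})

test_that("overlap edges agree with the brute-force all-offset oracle", {
  set.seed(33)
  tmpl <- random_dna(400)
  for (q in 1:20) {
    s1 <- sample(1:150, 1); s2 <- sample(1:150, 1)
    a <- substr(tmpl, s1, s1 + 149)
    b <- substr(tmpl, s2, s2 + 149)
    if (q %% 3 == 0) b <- revcomp(b)
    if (q %% 2 == 0) b <- mutate_dna(b, 5)
    ed <- find_overlaps(setNames(c(a, b), c("r1", "r2")),
                        min_overlap_len = 60, min_overlap_identity = 85,
                        method = "exhaustive")
    want <- r_best_overlap(a, b, 60, 85)
    if (is.null(want)) {
      expect_equal(nrow(ed), 0)
    } else {
      expect_equal(nrow(ed), 1)
      expect_equal(ed$orient, want$orient)
      expect_equal(ed$offset, want$offset)
      expect_equal(ed$length, want$length)
      expect_equal(ed$identity, want$identity)
    }
  }
})

test_that("seeded overlap detection agrees with the exhaustive scan", {
  fx <- make_test_sim(n_members = 4, n_reads = 80, error_rate = 0.005)
  tr <- trim_primers(fx$sim$reads, TEST_PRIMER_F, TEST_PRIMER_R)
  a <- find_overlaps(tr$reads, min_overlap_len = 80, method = "exhaustive")
  b <- find_overlaps(tr$reads, min_overlap_len = 80, method = "seeded")
  key <- function(e) paste(e$a, e$b, e$orient, e$offset, e$length)
  expect_setequal(key(a), key(b))
})

test_that("perfect tilings assemble into the template", {
  tmpl <- random_dna(500)
  starts <- seq(1, 301, by = 50)
  reads <- setNames(substring(tmpl, starts, starts + 199),
                    sprintf("r%02d", seq_along(starts)))
  asm <- olc_assemble(reads, min_overlap_len = 100)
  expect_equal(nrow(asm$otus), 1)
  expect_true(asm$otus$consensus %in% c(tmpl, revcomp(tmpl)))
  expect_equal(asm$otus$n_reads, length(reads))
  expect_equal(length(asm$unassembled), 0)
  expect_equal(asm$depth[[1]][1], 1L)  # single read covers each end

  # threshold above the true overlaps: nothing assembles
  asm2 <- olc_assemble(reads, min_overlap_len = 160)
  expect_equal(nrow(asm2$otus), 0)
  expect_equal(sort(asm2$unassembled), sort(names(reads)))
})

test_that("read conservation holds: tracked + unassembled == input", {
  fx <- make_test_sim(n_members = 5, n_reads = 250, error_rate = 0.005)
  tr <- trim_primers(fx$sim$reads, TEST_PRIMER_F, TEST_PRIMER_R)
  asm <- olc_assemble(tr$reads, min_overlap_len = 80)
  tracked <- unlist(asm$tracked_reads)
  expect_equal(length(tracked) + length(asm$unassembled), nrow(tr$reads))
  expect_false(any(duplicated(tracked)))
  expect_setequal(c(tracked, asm$unassembled), tr$reads$id)
  expect_true(all(asm$otus$n_reads >= asm$params$min_reads_per_otu))
})

test_that("raising the minimum overlap never decreases unassembled reads", {
  fx <- make_test_sim(n_members = 4, n_reads = 300, error_rate = 0.005,
                      read_length_mean = 200)
  tr <- trim_primers(fx$sim$reads, TEST_PRIMER_F, TEST_PRIMER_R)
  un <- vapply(c(60, 100, 140, 180), function(L)
    length(olc_assemble(tr$reads, min_overlap_len = L)$unassembled), 0L)
  expect_true(all(diff(un) >= 0))
})

test_that("assembly is closed under reverse complement of the input", {
  fx <- make_test_sim(n_members = 3, n_reads = 150, error_rate = 0.002)
  tr <- trim_primers(fx$sim$reads, TEST_PRIMER_F, TEST_PRIMER_R)
  asm1 <- olc_assemble(tr$reads, min_overlap_len = 80)
  flipped <- tr$reads
  flipped$seq <- revcomp(flipped$seq)
  flipped$qual <- vapply(flipped$qual, function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), "")
  asm2 <- olc_assemble(flipped, min_overlap_len = 80)
  expect_setequal(asm1$otus$consensus, asm2$otus$consensus)
})

test_that("singleton contigs are dissolved to unassembled", {
  reads <- setNames(c(random_dna(150), random_dna(150)), c("a", "b"))
  asm <- olc_assemble(reads, min_overlap_len = 100)
  expect_equal(nrow(asm$otus), 0)
  expect_setequal(asm$unassembled, c("a", "b"))
})

test_that("a small community end-to-end: every member resolved", {
  fx <- make_test_sim(n_members = 8, length_nt = 450, n_reads = 1200,
                      identity_min = 60, identity_max = 90,
                      error_rate = 0.005, read_length_mean = 320,
                      seed = 4, sim_seed = 21)
  tr <- trim_primers(fx$sim$reads, TEST_PRIMER_F, TEST_PRIMER_R)
  asm <- olc_assemble(tr$reads, min_overlap_len = 100)
  per_member <- vapply(fx$com$members$seq, function(m)
    max(vapply(asm$otus$consensus, function(s)
      max(pairwise_identity(s, m), pairwise_identity(revcomp(s), m)),
      0)), 0)
  expect_true(all(per_member >= 99))
})
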