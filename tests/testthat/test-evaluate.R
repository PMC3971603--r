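# Reference identity screening, per-OTU Sn/Sp and profile comparison

test_that("the identity screen finds exact and mutated matches", {
  set.seed(61)
  refs <- setNames(vapply(1:30, function(i) random_dna(400), ""),
                   sprintf("ref%02d", 1:30))
  wb <- watered_blast_identity(refs[7], refs)
  expect_equal(wb$ref_ids, "ref07")
  expect_equal(wb$identity, 100)
  # 5 substitutions inside an exact-flanked 100 bp region
  q <- paste0(substr(refs[3], 1, 150), mutate_dna(substr(refs[3], 151,
                                                         250), 5),
              substr(refs[3], 251, 400))
  wb2 <- watered_blast_identity(q, refs)
  wb2x <- watered_blast_identity(q, refs, exhaustive = TRUE)
  expect_equal(wb2$ref_ids, wb2x$ref_ids)
  expect_equal(wb2$identity, wb2x$identity)
  expect_equal(wb2$ref_ids, "ref03")
  # score agrees with an independent local aligner
  expect_equal(wb2$hits$score[1], as.integer(bios_local_score(q, refs[3])))
})

test_that("an unalignable query yields an empty result with a warning", {
  refs <- setNames(c(random_dna(100)), "r1")
  expect_warning(wb <- watered_blast_identity(strrep("N", 60), refs),
                 "no alignable|no candidates")
  expect_equal(length(wb$ref_ids), 0)
})

test_that("shortlisting equals the exhaustive screen across random queries", {
  set.seed(62)
  refs <- setNames(vapply(1:60, function(i) random_dna(300), ""),
                   sprintf("ref%02d", 1:60))
  for (q in 1:25) {
    i <- sample(60, 1)
    query <- mutate_dna(substr(refs[i], sample(1:100, 1), 300), 12)
    if (q %% 4 == 0) query <- revcomp(query)
    a <- watered_blast_identity(query, refs)
    b <- watered_blast_identity(query, refs, exhaustive = TRUE)
    expect_equal(a$identity, b$identity)
    expect_equal(a$ref_ids, b$ref_ids)
  }
})

test_that("per-OTU sensitivity and specificity follow their definitions", {
  set.seed(63)
  refs <- setNames(vapply(1:2, function(i) random_dna(200), ""),
                   c("src_a", "src_b"))
  # 100 reads from src_a: 90 assigned to its OTU, 10 lost; 10 alien reads
  asg <- data.frame(
    read_id = sprintf("r%03d", 1:110),
    library = "libA",
    otu = c(rep("otu_0001", 90), rep("unmapped", 10), rep("otu_0001", 10)),
    stringsAsFactors = FALSE)
  src <- setNames(c(rep("src_a", 100), rep("src_b", 10)), asg$read_id)
  q <- otu_sn_sp(setNames(refs["src_a"], "otu_0001"), asg, src, refs)
  expect_equal(q$nearest_ref, "src_a")
  expect_equal(q$sensitivity, 0.90)
  expect_equal(q$specificity, 0.90)
  # a source with zero reads: sensitivity undefined, flagged
  src0 <- src[101:110]
  asg0 <- asg[101:110, ]
  q0 <- otu_sn_sp(setNames(refs["src_a"], "otu_0001"), asg0, src0, refs)
  expect_false(q0$sn_defined)
  expect_true(is.na(q0$sensitivity))
})

test_that("profile comparison computes total variation and recovery", {
  fx <- make_test_sim(n_members = 2, n_reads = 100, error_rate = 0)
  members <- fx$com$members
  # estimated profile equals truth exactly
  src <- fx$sim$truth$read_sources$source
  counts <- matrix(as.integer(table(factor(src,
                                           levels = members$name))),
                   ncol = 1, dimnames = list(members$name, "libA"))
  tab <- abundance_table(counts)
  otus <- data.frame(id = members$name, consensus = members$seq,
                     stringsAsFactors = FALSE)
  cmp <- compare_profiles(tab, otus, fx$sim$truth)
  expect_equal(cmp$l1_error, 0)
  expect_equal(cmp$members_recovered, 2)
  expect_equal(cmp$unmapped_fraction, 0)
  # one member entirely missed in a 50/50 community
  fx2 <- make_test_sim(n_members = 2, n_reads = 2000, error_rate = 0)
  fx2$sim$truth$proportions[] <- 0.5
  src2 <- fx2$sim$truth$read_sources$source
  n1 <- sum(src2 == members$name[1])
  tab1 <- abundance_table(matrix(n1, 1, 1,
                                 dimnames = list(fx2$com$members$name[1],
                                                 "libA")))
  cmp2 <- compare_profiles(tab1, otus[1, ], fx2$sim$truth)
  expect_equal(cmp2$members_recovered, 1)
  p_true <- mean(src2 == fx2$com$members$name[1])
  expect_equal(cmp2$l1_error, 1 - p_true)
})

test_that("the total variation distance is bounded and faithful", {
  p <- c(0.5, 0.3, 0.2); q <- c(0.2, 0.3, 0.5)
  tv <- function(a, b) 0.5 * sum(abs(a - b))
  expect_equal(tv(p, p), 0)
  expect_equal(tv(p, q), tv(q, p))
  expect_gte(tv(p, q), 0)
  expect_lte(tv(p, q), 1)
})
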