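# Read-to-OTU mapping, abundance tabulation and down-sampling

test_that("substring reads map to their OTU with full identity", {
  set.seed(14)
  otus <- data.frame(id = c("otu_0001", "otu_0002", "otu_0003"),
                     consensus = vapply(1:3, function(i) random_dna(300),
                                        ""),
                     stringsAsFactors = FALSE)
  read <- substr(otus$consensus[3], 51, 150)
  asg <- map_read(read, otus)
  expect_equal(asg$otu, "otu_0003")
  expect_equal(asg$identity, 100)
  expect_equal(asg$aligned_cols, 100)
  expect_equal(asg$strand, "+")
  # reverse-complement read maps on the minus strand
  asg2 <- map_read(revcomp(read), otus)
  expect_equal(asg2$otu, "otu_0003")
  expect_equal(asg2$strand, "-")
})

test_that("equidistant reads break ties toward the smaller OTU id", {
  set.seed(15)
  core <- random_dna(120)
  otus <- data.frame(id = c("otu_0002", "otu_0001"),
                     consensus = c(paste0(core, random_dna(40)),
                                   paste0(core, random_dna(40))),
                     stringsAsFactors = FALSE)
  asg <- map_read(core, otus)
  expect_equal(asg$otu, "otu_0001")
  expect_equal(asg$n_ties, 1)
})

test_that("reads below the identity or length gates are unmapped", {
  set.seed(16)
  otu <- random_dna(200)
  read <- mutate_dna(substr(otu, 1, 100), 15)  # ~85% identity
  asg <- map_read(read, setNames(otu, "otu_0001"), min_identity = 90)
  expect_equal(asg$otu, "unmapped")
  want <- r_map_best(read, data.frame(id = "otu_0001", consensus = otu,
                                      stringsAsFactors = FALSE), 90, 50)
  expect_equal(asg$otu, want$otu)
  expect_equal(asg$identity, want$identity)
  short <- substr(otu, 1, 30)
  asg2 <- map_read(short, setNames(otu, "otu_0001"), min_aligned_len = 50)
  expect_equal(asg2$otu, "unmapped")
})

test_that("mapping agrees with the exhaustive DP oracle", {
  set.seed(17)
  for (q in 1:15) {
    otus <- data.frame(id = sprintf("otu_%04d", 1:3),
                       consensus = vapply(1:3, function(i)
                         random_dna(120), ""),
                       stringsAsFactors = FALSE)
    pick <- sample(3, 1)
    read <- substr(otus$consensus[pick], 11, 90)
    read <- mutate_dna(read, sample(0:6, 1))
    if (q %% 3 == 0) read <- revcomp(read)
    got <- map_reads(setNames(read, "r"), otus, min_identity = 80,
                     min_aligned_len = 40, method = "exhaustive")
    want <- r_map_best(read, otus, 80, 40)
    expect_equal(got$otu, want$otu)
    expect_equal(got$identity, want$identity)
    expect_equal(got$aligned_cols, want$columns)
  }
})

test_that("the seeded shortlist agrees with exhaustive mapping", {
  fx <- make_test_sim(n_members = 6, length_nt = 450, n_reads = 400,
                      error_rate = 0.005, read_length_mean = 300,
                      seed = 9, sim_seed = 23)
  tr <- trim_primers(fx$sim$reads, TEST_PRIMER_F, TEST_PRIMER_R)
  otus <- setNames(fx$com$members$seq, fx$com$members$name)
  a <- map_reads(tr$reads, otus, method = "auto")
  b <- map_reads(tr$reads, otus, method = "exhaustive")
  expect_equal(a$otu, b$otu)
  expect_equal(a$identity, b$identity)
})

test_that("abundance tabulation conserves reads per library", {
  asg <- data.frame(
    read_id = sprintf("r%02d", 1:15),
    library = rep(c("libA", "libB"), c(10, 5)),
    otu = c(rep("otu_0001", 10), "otu_0001", "otu_0002", "otu_0002",
            "unmapped", "unmapped"),
    stringsAsFactors = FALSE)
  tab <- count_abundance(asg)
  expect_equal(unname(tab["otu_0001", ]), c(10L, 1L))
  expect_equal(unname(tab["otu_0002", ]), c(0L, 2L))
  expect_equal(unname(attr(tab, "unmapped")), c(0L, 2L))
  expect_equal(unname(colSums(tab) + attr(tab, "unmapped")),
               unname(attr(tab, "total")))
  expect_error(count_abundance(asg, libraries = "libA"),
               "unknown library")
  empty <- count_abundance(asg[0, ], libraries = "libA",
                           otu_ids = "otu_0001")
  expect_true(all(empty == 0))
})

test_that("down-sampling equalises library depth deterministically", {
  counts <- matrix(c(60L, 40L, 150L, 100L), 2,
                   dimnames = list(c("otu_0001", "otu_0002"),
                                   c("libA", "libB")))
  tab <- abundance_table(counts)
  ds1 <- downsample_abundance(tab, seed = 7)
  ds2 <- downsample_abundance(tab, seed = 7)
  expect_identical(unclass(ds1)[, ], unclass(ds2)[, ])
  expect_equal(unname(colSums(ds1)), c(100, 100))
  # equal depths: the subsample of everything is everything
  eq <- abundance_table(matrix(c(3L, 7L, 6L, 4L), 2,
                               dimnames = list(c("a", "b"),
                                               c("l1", "l2"))))
  expect_equal(unname(colSums(downsample_abundance(eq, 1))), c(10, 10))
  expect_identical(unclass(downsample_abundance(eq, 1))[, ],
                   unclass(eq)[, ])
  zero <- abundance_table(matrix(c(5L, 0L), 1,
                                 dimnames = list("a", c("l1", "l2"))))
  expect_error(downsample_abundance(zero, 1), "zero mapped reads")
})

test_that("error-free reads from well-separated members map perfectly", {
  fx <- make_test_sim(n_members = 5, n_reads = 200, error_rate = 0,
                      identity_min = 60, identity_max = 85)
  tr <- trim_primers(fx$sim$reads, TEST_PRIMER_F, TEST_PRIMER_R)
  otus <- setNames(fx$com$members$seq, fx$com$members$name)
  asg <- map_reads(tr$reads, otus)
  src <- setNames(fx$sim$truth$read_sources$source,
                  fx$sim$truth$read_sources$read_id)
  expect_true(all(asg$otu == src[asg$read_id]))
  tab <- count_abundance(asg)
  truth_counts <- table(factor(src, levels = sort(fx$com$members$name)))
  expect_equal(unname(rowSums(tab)), as.vector(truth_counts))
})
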