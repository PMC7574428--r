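# High-frequency k-mer set and whole-read classification / partitioning.

test_that("select_high_frequency_kmers thresholds inclusively", {
  tab <- count_kmers(c(strrep("A", 12), "CCCG", "CCCG", "CCCG"), 3,
                     canonical = FALSE)
  # AAA:10, CCC:3, CCG:3
  sh <- select_high_frequency_kmers(tab, 5)
  expect_equal(sh$members, "AAA")
  expect_setequal(select_high_frequency_kmers(tab, 1)$members,
                  names(tab$counts))
  expect_length(select_high_frequency_kmers(tab, 11)$members, 0)
  expect_equal(select_high_frequency_kmers(tab, 3)$members,
               names(tab$counts)) # boundary is inclusive
})

test_that("classify_read applies the endpoint and fraction rules", {
  sh <- structure(list(k = 3L, t1 = 1L, canonical = FALSE,
                       members = c("ACG", "CGT", "GTA")),
                  class = "highfreq_kmers")
  all_in <- classify_read("ACGTA", sh, t2 = 0.9)
  expect_equal(all_in$q, 3L)
  expect_equal(all_in$fraction, 1)
  expect_true(all_in$is_high_frequency)

  # first window not in the set: endpoint rule dominates
  sh2 <- structure(list(k = 3L, t1 = 1L, canonical = FALSE,
                        members = c("CGT", "GTA")),
                   class = "highfreq_kmers")
  miss1 <- classify_read("ACGTA", sh2, t2 = 0.5)
  expect_false(miss1$first_in)
  expect_equal(miss1$fraction, 2 / 3, tolerance = 1e-12)
  expect_false(miss1$is_high_frequency)

  # q = 10, n_high = 9 with both endpoints: 0.9 >= 0.9 passes (inclusive)
  seq12 <- "ACGTACGTACGT"
  wins <- substring(seq12, 1:10, 3:12)
  drop <- wins[5]
  sh3 <- structure(list(k = 3L, t1 = 1L, canonical = FALSE,
                        members = setdiff(unique(wins), drop)),
                   class = "highfreq_kmers")
  # all windows equal one of 4 distinct 3-mers here; build a cleaner case
  seq12 <- "AACCGGTTAACC"
  wins <- substring(seq12, 1:10, 3:12)
  expect_equal(anyDuplicated(wins[-c(1, 10)]), 0)
  sh3 <- structure(list(k = 3L, t1 = 1L, canonical = FALSE,
                        members = setdiff(wins, wins[5])),
                   class = "highfreq_kmers")
  cl <- classify_read(seq12, sh3, t2 = 0.9)
  expect_equal(cl$q, 10L)
  expect_equal(cl$n_high, 9L)
  expect_true(cl$first_in && cl$last_in)
  expect_true(cl$is_high_frequency)
  expect_false(classify_read(seq12, sh3, t2 = 0.95)$is_high_frequency)

  # reads shorter than k never error
  short <- classify_read("AC", sh, t2 = 0.9)
  expect_equal(short$q, 0L)
  expect_false(short$is_high_frequency)
})

test_that("classification agrees with the brute-force re-scan", {
  set.seed(202)
  for (i in 1:20) {
    k <- sample(3:7, 1)
    pool <- count_kmers(random_dna(300), k, canonical = TRUE)
    members <- sample(names(pool$counts), min(40, length(pool$counts)))
    sh <- structure(list(k = k, t1 = 1L, canonical = TRUE,
                         members = members), class = "highfreq_kmers")
    reads <- vapply(1:8, function(j) random_dna(sample(k:40, 1)), "")
    got <- classify_reads(reads, sh, t2 = 0.6)
    for (j in seq_along(reads)) {
      want <- oracle_classify(reads[j], members, k, 0.6)
      expect_equal(got$q[j], want$q)
      expect_equal(got$n_high[j], want$n_high)
      expect_equal(got$is_high_frequency[j], want$is_high)
    }
  }
})

test_that("classification is strand-symmetric in canonical mode", {
  set.seed(303)
  tab <- count_kmers(vapply(1:30, function(i) random_dna(60), ""), 5, TRUE)
  sh <- select_high_frequency_kmers(tab, 2)
  reads <- vapply(1:40, function(i) random_dna(30), "")
  a <- classify_reads(reads, sh, 0.5)$is_high_frequency
  b <- classify_reads(revcomp(reads), sh, 0.5)$is_high_frequency
  expect_identical(a, b)
})

test_that("high-frequency read sets are nested under t1 and t2", {
  fx <- small_fixture(seed = 11, divergence = 0, error_rate = 0.002,
                      coverage = 20, genome = 10000L, unit = 400L,
                      copies = 6L)
  reads <- rbind(fx$reads$r1, fx$reads$r2)
  tab <- count_kmers(reads, 21, TRUE)
  t1s <- c(20L, 40L, 80L)
  t2s <- c(0.5, 0.7, 0.9)
  sets <- lapply(t1s, function(t1) {
    sh <- select_high_frequency_kmers(tab, t1)
    lapply(t2s, function(t2) {
      cl <- classify_reads(reads, sh, t2)
      cl$read_id[cl$is_high_frequency]
    })
  })
  for (i in seq_along(t1s)) {
    for (j in seq_along(t2s)) {
      if (j > 1) expect_true(all(sets[[i]][[j]] %in% sets[[i]][[j - 1]]))
      if (i > 1) expect_true(all(sets[[i]][[j]] %in% sets[[i - 1]][[j]]))
    }
  }
  expect_gt(length(sets[[1]][[1]]), 0)
})

test_that("error-free reads inside a high-copy family are recalled", {
  fx <- small_fixture(seed = 5, divergence = 0, error_rate = 0,
                      coverage = 40, genome = 20000L, unit = 500L,
                      copies = 8L) # copy number 8 >= 2c with c = 2
  reads <- rbind(fx$reads$r1, fx$reads$r2)
  tab15 <- count_kmers(reads, 15, TRUE)
  p <- find_main_peak(build_histogram(tab15))
  cov <- estimate_coverage(p, 100, 15)$cov
  t1 <- compute_t1(cov, 2)
  sh <- select_high_frequency_kmers(count_kmers(reads, 31, TRUE), t1)
  cl <- classify_reads(reads, sh, 0.9)
  sc <- score_classification(fx$reads$labels, cl)
  expect_gte(sc$read_recall, 0.95)
  expect_lte(sc$read_fpr, 0.05)
})

test_that("partition_reads honours the pairing modes", {
  sh <- structure(list(k = 3L, t1 = 1L, canonical = FALSE,
                       members = c("AAA")), class = "highfreq_kmers")
  pass <- data.frame(id = c("p1", "p2"), seq = c("AAAAA", "AAAA"),
                     qual = NA_character_)
  fail <- data.frame(id = c("f1", "f2"), seq = c("CCCCC", "CCCC"),
                     qual = NA_character_)

  both <- partition_reads(pass, pass, sh, 0.9, "strict")
  expect_equal(nrow(both$paired_pass$r1), 2)
  expect_equal(both$rejected_count, 0)

  mixed <- partition_reads(pass, fail, sh, 0.9, "strict")
  expect_equal(nrow(mixed$paired_pass$r1), 0)
  expect_equal(mixed$singleton_pass$id, c("p1", "p2"))
  expect_equal(mixed$rejected_count, 2)

  either <- partition_reads(pass, fail, sh, 0.9, "either")
  expect_equal(nrow(either$paired_pass$r1), 2)
  expect_equal(either$rejected_count, 0)

  ignore <- partition_reads(pass, fail, sh, 0.9, "ignore")
  expect_equal(nrow(ignore$paired_pass$r1), 0)
  expect_equal(ignore$singleton_pass$id, c("p1", "p2"))
  expect_equal(ignore$rejected_count, 2)

  # partition counts always sum to the input count
  for (part in list(both, mixed, either, ignore)) {
    expect_equal(2L * nrow(part$paired_pass$r1) +
                   nrow(part$singleton_pass) + part$rejected_count,
                 part$n_input)
  }

  expect_error(partition_reads(pass, fail[1, ], sh), "unequal pair files")
})
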