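# Planted-repeat genome generator and read simulator.

test_that("make_genome plants the requested copies and is seed-deterministic", {
  fam <- repeat_family(500, 10, divergence = 0)
  tr <- make_genome(10000, list(fam), seed = 3)
  expect_equal(nchar(tr$genome), 10000)
  expect_equal(nrow(tr$repeat_intervals), 10)
  units <- substring(tr$genome, tr$repeat_intervals$start + 1,
                     tr$repeat_intervals$end)
  expect_equal(nchar(units), rep(500L, 10))
  expect_length(unique(units), 1) # divergence 0: all copies identical

  tr2 <- make_genome(10000, list(fam), seed = 3)
  expect_identical(tr$genome, tr2$genome)
  expect_identical(tr$repeat_intervals, tr2$repeat_intervals)
  expect_false(identical(make_genome(10000, list(fam), seed = 4)$genome,
                         tr$genome))
})

test_that("tandem copies are adjacent; intervals never overlap", {
  fam <- repeat_family(100, 5, divergence = 0, arrangement = "tandem")
  tr <- make_genome(5000, list(fam), seed = 9)
  iv <- tr$repeat_intervals
  expect_equal(iv$start[-1], iv$end[-nrow(iv)]) # adjacent block
  fam2 <- repeat_family(200, 6, divergence = 0.05)
  tr2 <- make_genome(8000, list(fam2, fam), seed = 9)
  iv2 <- tr2$repeat_intervals
  expect_true(all(iv2$start[-1] >= iv2$end[-nrow(iv2)]))
})

test_that("divergence produces the expected pairwise identity", {
  d <- 0.02
  fam <- repeat_family(2000, 6, divergence = d)
  ids <- c()
  for (seed in 1:5) {
    tr <- make_genome(30000, list(fam), seed = seed)
    units <- strsplit(substring(tr$genome, tr$repeat_intervals$start + 1,
                                tr$repeat_intervals$end), "")
    for (i in 1:5) for (j in (i + 1):6) {
      ids <- c(ids, mean(units[[i]] == units[[j]]))
    }
  }
  # two copies independently mutated at rate d agree with probability
  # (1-d)^2 + d^2/3
  expected <- (1 - d)^2 + d^2 / 3
  expect_equal(mean(ids), expected, tolerance = 0.01)
  expect_gt(mean(ids), 0.95)
})

test_that("impossible plantings error", {
  expect_error(make_genome(1000, list(repeat_family(600, 2))),
               "smaller than background_length")
  # mass fits, but this seed leaves no room for the second copy
  expect_error(make_genome(1000, list(repeat_family(450, 2)), seed = 2),
               "too crowded")
})

test_that("simulate_reads produces the stated pair count and exact reads", {
  tr <- make_genome(100000, list(), seed = 2)
  rd <- simulate_reads(tr, coverage = 40, read_length = 100, seed = 2)
  expect_equal(nrow(rd$r1), 20000) # 40 * 100000 / (2 * 100)
  expect_equal(nrow(rd$r2), 20000)
  expect_equal(nrow(rd$labels), 40000)

  # error-free reads are exact substrings (mate 2 reverse-complemented)
  idx <- sample(nrow(rd$r1), 50)
  lay <- rd$layout[idx, ]
  expect_equal(substring(tr$genome, lay$start, lay$start + 99),
               rd$r1$seq[idx])
  expect_equal(revcomp(substring(tr$genome, lay$start + lay$fragment - 100,
                                 lay$start + lay$fragment - 1)),
               rd$r2$seq[idx])
  expect_error(simulate_reads(tr, 40, 100, insert_mean = 2e5),
               "insert longer than genome")
})

test_that("labels partition the reads and respect containment", {
  fx <- small_fixture(seed = 13, coverage = 10)
  lab <- fx$reads$labels
  expect_equal(nrow(lab), 2L * nrow(fx$reads$r1))
  expect_setequal(unique(lab$label), c("repeat", "unique", "boundary"))
  # every repeat-labelled mate lies inside one planted interval
  iv <- fx$truth$repeat_intervals
  r1lab <- lab$label[seq_len(nrow(fx$reads$r1))]
  s0 <- fx$reads$layout$start - 1L
  inside <- vapply(s0, function(s)
    any(s >= iv$start & s + 100L <= iv$end), TRUE)
  expect_identical(r1lab == "repeat", inside)
})

test_that("error injection perturbs roughly the stated base fraction", {
  tr <- make_genome(50000, list(), seed = 21)
  clean <- simulate_reads(tr, 20, 100, error_rate = 0, seed = 77)
  noisy <- simulate_reads(tr, 20, 100, error_rate = 0.01, seed = 77)
  # same seed: identical layout, so differences are exactly the errors
  expect_identical(clean$layout, noisy$layout)
  mm <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               clean$r1$seq, noisy$r1$seq)
  rate <- sum(mm) / sum(nchar(clean$r1$seq))
  expect_equal(rate, 0.01, tolerance = 0.15)
})

test_that("the unique-sequence k-mer peak sits near Cov*(L-k+1)/L", {
  tr <- make_genome(100000, list(), seed = 8)
  rd <- simulate_reads(tr, 40, 100, error_rate = 0, seed = 8)
  tab <- count_kmers(rbind(rd$r1, rd$r2), 15, TRUE)
  p <- as.integer(find_main_peak(build_histogram(tab)))
  expect_equal(p, 40 * 86 / 100, tolerance = 0.10)
})

test_that("a divergence-0 family concentrates mass near m times the peak", {
  m <- 6L
  fx <- small_fixture(seed = 19, divergence = 0, coverage = 30,
                      genome = 50000L, unit = 1000L, copies = m)
  reads <- rbind(fx$reads$r1, fx$reads$r2)
  tab <- count_kmers(reads, 15, TRUE)
  p <- as.integer(find_main_peak(build_histogram(tab)))
  # k-mers of the planted unit should cluster around m * p
  unit <- substring(fx$truth$genome, fx$truth$repeat_intervals$start[1] + 1,
                    fx$truth$repeat_intervals$end[1])
  unit_kmers <- names(count_kmers(unit, 15, TRUE)$counts)
  obs <- stats::median(tab$counts[unit_kmers], na.rm = TRUE)
  expect_equal(as.numeric(obs), m * p, tolerance = 0.25)
})

test_that("write_fixture emits the documented files", {
  fx <- small_fixture(seed = 23, coverage = 2, genome = 5000L, unit = 300L,
                      copies = 3L)
  dir <- withr::local_tempdir()
  write_fixture(fx$truth, fx$reads, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fasta", "reads_R1.fastq", "reads_R2.fastq",
    "truth_intervals.bed", "read_labels.tsv")))))
  bed <- utils::read.table(file.path(dir, "truth_intervals.bed"), sep = "\t")
  expect_equal(nrow(bed), 3)
  expect_equal(bed[[3]] - bed[[2]], rep(300L, 3))
  genome_rt <- read_sequences(file.path(dir, "genome.fasta"))
  expect_identical(genome_rt$seq, fx$truth$genome)
})
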