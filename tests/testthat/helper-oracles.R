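# Independent brute-force oracles, deliberately written in plain R with no
# use of the package's compiled paths.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Substring tally of all k-windows over A/C/G/T, optionally canonical.
oracle_count_kmers <- function(reads, k, canonical) {
  tab <- new.env()
  for (s in reads) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      if (canonical) {
        rc <- oracle_revcomp(w)
        if (rc < w) w <- rc
      }
      tab[[w]] <- (if (is.null(tab[[w]])) 0L else tab[[w]]) + 1L
    }
  }
  keys <- sort(ls(tab))
  stats::setNames(vapply(keys, function(x) tab[[x]], 0L), keys)
}

# Re-scan a read against a plain membership dictionary.
oracle_classify <- function(seq, members, k, t2, canonical = TRUE) {
  n <- nchar(seq)
  q <- max(0L, n - k + 1L)
  hits <- logical(q)
  if (q > 0) for (i in 1:q) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    if (canonical) {
      rc <- oracle_revcomp(w)
      if (rc < w) w <- rc
    }
    hits[i] <- w %in% members
  }
  list(q = q, n_high = sum(hits),
       first_in = q > 0 && hits[1], last_in = q > 0 && hits[q],
       is_high = q > 0 && hits[1] && hits[q] && sum(hits) / q >= t2)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Small planted-repeat fixture used by several module tests: one
# interspersed family, error-free unless stated.
small_fixture <- function(seed = 42, divergence = 0, error_rate = 0,
                          coverage = 40, genome = 20000L,
                          unit = 500L, copies = 8L) {
  truth <- make_genome(genome, list(repeat_family(unit, copies, divergence)),
                       seed = seed)
  reads <- simulate_reads(truth, coverage, read_length = 100L,
                          insert_mean = 300L, insert_sd = 30L,
                          error_rate = error_rate, seed = seed + 1L)
  list(truth = truth, reads = reads)
}
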