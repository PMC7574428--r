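# Read-filtering stage: the high-frequency k-mer set S_h and the whole-read
# classification rule (terminal k-mers in S_h and at least a fraction t2 of
# all windows in S_h), plus pair-aware partitioning of the input reads.

#' Select the high-frequency k-mer set
#'
#' Keeps every k-mer whose count is at or above the threshold t1 (the
#' comparison is inclusive).
#'
#' @param table a `kmer_counts` object.
#' @param t1 integer threshold (>= 1), typically from [compute_t1()].
#' @return an object of class `highfreq_kmers`: list with `k`, `t1`,
#'   `canonical` and `members` (character vector of k-mers).
#' @export
select_high_frequency_kmers <- function(table, t1) {
  stopifnot(inherits(table, "kmer_counts"))
  t1 <- as.integer(t1)
  if (is.na(t1) || t1 < 1L) stop("t1 must be >= 1")
  structure(
    list(k = table$k, t1 = t1, canonical = table$canonical,
         members = names(table$counts)[table$counts >= t1]),
    class = "highfreq_kmers"
  )
}

#' @export
print.highfreq_kmers <- function(x, ...) {
  cat(sprintf("high-frequency k-mer set: k=%d, t1=%d, %d members\n",
              x$k, x$t1, length(x$members)))
  invisible(x)
}

#' Classify reads against the high-frequency k-mer set
#'
#' A read of length L has q = L - k + 1 windows s_1..s_q (windows containing
#' non-ACGT symbols count toward q but can never be members). The read is a
#' high-frequency read iff its terminal windows s_1 and s_q are both in the
#' set and the fraction of member windows is at least t2 (inclusive). Reads
#' shorter than k get q = 0 and are never high-frequency (no error is
#' raised).
#'
#' @param reads character vector of sequences or a read data frame.
#' @param sh a `highfreq_kmers` object.
#' @param t2 fraction threshold in (0, 1] (default 0.9).
#' @return data frame with one row per read: `read_id`, `q`, `n_high`,
#'   `first_in`, `last_in`, `fraction`, `is_high_frequency`.
#' @export
classify_reads <- function(reads, sh, t2 = 0.9) {
  stopifnot(inherits(sh, "highfreq_kmers"))
  if (!is.finite(t2) || t2 <= 0 || t2 > 1) stop("t2 must be in (0, 1]")
  r <- as_reads(reads)
  res <- kmer_classify_cpp(r$seq, sh$members, sh$k, sh$canonical)
  fraction <- ifelse(res$q > 0L, res$n_high / res$q, 0)
  data.frame(
    read_id = r$id, q = res$q, n_high = res$n_high,
    first_in = res$first_in, last_in = res$last_in,
    fraction = fraction,
    is_high_frequency = res$q > 0L & res$first_in & res$last_in &
      fraction >= t2,
    stringsAsFactors = FALSE
  )
}

#' @rdname classify_reads
#' @param seq a single nucleotide string.
#' @export
classify_read <- function(seq, sh, t2 = 0.9) {
  classify_reads(as.character(seq)[1L], sh, t2)
}

#' Partition reads into high-frequency output sets
#'
#' Classifies every read with [classify_reads()] and splits the input into
#' the pairs kept whole (`paired_pass`), the lone passing mates or unpaired
#' passers (`singleton_pass`) and a rejected remainder. Pairing modes:
#' `strict` (default) keeps a pair whole only when both mates pass, routing a
#' lone passing mate to the singletons; `either` keeps the whole pair when at
#' least one mate passes; `ignore` treats every read as unpaired.
#'
#' @param reads1 first-mate reads (data frame or character vector).
#' @param reads2 second-mate reads, positionally aligned with `reads1`, or
#'   `NULL` for unpaired input.
#' @param sh a `highfreq_kmers` object.
#' @param t2 fraction threshold (default 0.9).
#' @param pairing_mode one of `"strict"`, `"either"`, `"ignore"`.
#' @return an object of class `read_partition`: list with `paired_pass`
#'   (list of data frames `r1`, `r2`), `singleton_pass` (data frame),
#'   `rejected_count`, `n_input` and the per-read `classification` table.
#' @export
partition_reads <- function(reads1, reads2 = NULL, sh, t2 = 0.9,
                            pairing_mode = c("strict", "either", "ignore")) {
  pairing_mode <- match.arg(pairing_mode)
  r1 <- as_reads(reads1)
  r2 <- if (!is.null(reads2)) as_reads(reads2)
  if (!is.null(r2) && nrow(r1) != nrow(r2)) stop("unequal pair files")

  c1 <- classify_reads(r1, sh, t2)
  c2 <- if (!is.null(r2)) classify_reads(r2, sh, t2)
  cls <- rbind(c1, c2)

  empty <- r1[0L, ]
  if (is.null(r2) || pairing_mode == "ignore") {
    pass <- c(c1$is_high_frequency, if (!is.null(c2)) c2$is_high_frequency)
    all_reads <- rbind(r1, r2)
    part <- list(
      paired_pass = list(r1 = empty, r2 = empty),
      singleton_pass = all_reads[pass, , drop = FALSE],
      rejected_count = sum(!pass)
    )
  } else {
    p1 <- c1$is_high_frequency
    p2 <- c2$is_high_frequency
    keep_pair <- if (pairing_mode == "strict") p1 & p2 else p1 | p2
    lone1 <- p1 & !keep_pair
    lone2 <- p2 & !keep_pair
    part <- list(
      paired_pass = list(r1 = r1[keep_pair, , drop = FALSE],
                         r2 = r2[keep_pair, , drop = FALSE]),
      singleton_pass = rbind(r1[lone1, , drop = FALSE],
                             r2[lone2, , drop = FALSE]),
      rejected_count = sum(!p1 & !keep_pair) + sum(!p2 & !keep_pair)
    )
  }
  part$n_input <- nrow(r1) + if (is.null(r2)) 0L else nrow(r2)
  part$classification <- cls
  short <- sum(cls$q == 0L)
  if (short > 0L)
    message(short, " read(s) shorter than k=", sh$k, " rejected")
  structure(part, class = "read_partition")
}

#' @export
print.read_partition <- function(x, ...) {
  cat(sprintf(paste0("read partition: %d input, %d pairs kept whole, ",
                     "%d singletons, %d rejected\n"),
              x$n_input, nrow(x$paired_pass$r1), nrow(x$singleton_pass),
              x$rejected_count))
  invisible(x)
}

# All passing reads of a partition, for downstream assembly.
partition_pass_reads <- function(part) {
  stopifnot(inherits(part, "read_partition"))
  rbind(part$paired_pass$r1, part$paired_pass$r2, part$singleton_pass)
}
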