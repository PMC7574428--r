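# Evaluation: library-level summary statistics (N50/N90 over the library's
# own total length) and truth-based scoring of the pipeline on synthetic
# fixtures (read-level recall/FPR, base-level repeat recovery by exact
# canonical k-mer anchoring).

contig_like <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- read_sequences(x)
  if (is.data.frame(x)) {
    seqs <- if (!is.null(x$seq)) x$seq else stop("no 'seq' column")
  } else if (is.character(x)) {
    seqs <- unname(x)
  } else {
    stop("cannot interpret object of class '", class(x)[1L],
         "' as a sequence library")
  }
  toupper(seqs)
}

#' Repeat-library summary statistics
#'
#' N50 (N90) is the length of the longest sequence such that all sequences at
#' least that long cover >= 50% (90%) of the library's own total length.
#'
#' @param x a repeat library: FASTA path, `repeat_contigs` data frame or
#'   character vector of sequences.
#' @return an object of class `library_stats`: list with `num`, `size_bp`,
#'   `max_len`, `min_len`, `n50`, `n90`, `avg_len`.
#' @export
#' @examples
#' library_stats(c(strrep("A", 50), strrep("C", 30), strrep("G", 20)))
library_stats <- function(x) {
  lens <- nchar(contig_like(x))
  if (length(lens) == 0L) stop("empty repeat library")
  nx <- function(q) {
    s <- sort(lens, decreasing = TRUE)
    s[which(cumsum(s) >= q * sum(s))[1L]]
  }
  structure(
    list(num = length(lens), size_bp = sum(lens),
         max_len = max(lens), min_len = min(lens),
         n50 = nx(0.5), n90 = nx(0.9), avg_len = mean(lens)),
    class = "library_stats"
  )
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf(paste0("repeat library: %d sequences, %d bp total, ",
                     "max/min %d/%d, N50=%d, N90=%d, mean %.1f bp\n"),
              x$num, x$size_bp, x$max_len, x$min_len, x$n50, x$n90,
              x$avg_len))
  invisible(x)
}

#' Score a read classification against truth labels
#'
#' Recall is the passing fraction among `repeat`-labelled reads; the false
#' positive rate is the passing fraction among `unique`-labelled reads.
#' `boundary` reads are excluded from both.
#'
#' @param labels data frame with `read_id` and `label`
#'   (`repeat`/`unique`/`boundary`), e.g. from [simulate_reads()].
#' @param classifications data frame with `read_id` and `is_high_frequency`
#'   (e.g. from [classify_reads()]), or a logical vector named by read id.
#' @return list with `read_recall`, `read_fpr`, `n_repeat`, `n_unique`,
#'   `n_boundary`.
#' @export
score_classification <- function(labels, classifications) {
  stopifnot(is.data.frame(labels),
            all(c("read_id", "label") %in% names(labels)))
  if (is.data.frame(classifications)) {
    pass <- stats::setNames(classifications$is_high_frequency,
                            classifications$read_id)
  } else if (is.logical(classifications)) {
    pass <- classifications
  } else stop("classifications must be a data frame or named logical vector")
  if (is.null(names(pass)) || !setequal(names(pass), labels$read_id) ||
      length(pass) != nrow(labels))
    stop("read id mismatch between labels and classifications")
  pass <- pass[labels$read_id]
  rep_i <- labels$label == "repeat"
  uni_i <- labels$label == "unique"
  frac <- function(sel) if (any(sel)) mean(pass[sel]) else NA_real_
  list(read_recall = frac(rep_i), read_fpr = frac(uni_i),
       n_repeat = sum(rep_i), n_unique = sum(uni_i),
       n_boundary = sum(labels$label == "boundary"))
}

# Logical per-window membership of `seq` against a canonical k-mer set.
window_hits <- function(seq, members, k) {
  if (length(members) == 0L)
    return(logical(max(0L, nchar(seq) - k + 1L)))
  kmer_window_counts_cpp(seq, members, rep(1, length(members)), k, TRUE) > 0
}

#' Base-level recovery of planted repeats by a library
#'
#' A truth repeat base is recovered when at least one genome window of length
#' `anchor_k` covering it occurs (canonically) among the k-mers of some
#' library contig. Returns the recovered fraction of all planted repeat
#' bases, plus a per-family breakdown. Contigs shorter than `anchor_k`
#' contribute no anchors.
#'
#' @param truth a `synthetic_truth`.
#' @param library repeat library (path, `repeat_contigs` or character
#'   vector). An empty library yields 0 with a warning.
#' @param anchor_k anchoring k-mer size (default 31).
#' @return list with `recovery`, `recovered_bases`, `total_bases` and
#'   `per_family` (data frame).
#' @export
repeat_base_recovery <- function(truth, library, anchor_k = 31L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  anchor_k <- as.integer(anchor_k)
  iv <- truth$repeat_intervals
  total <- sum(iv$end - iv$start)
  seqs <- contig_like(library)
  seqs <- seqs[nchar(seqs) >= anchor_k]
  if (length(seqs) == 0L) {
    warning("empty repeat library: recovery is 0")
    return(list(recovery = 0, recovered_bases = 0L, total_bases = total,
                per_family = data.frame(family = unique(iv$family),
                                        recovery = 0)))
  }
  members <- kmer_count_cpp(seqs, anchor_k, TRUE)$kmer
  g <- nchar(truth$genome)
  hits <- window_hits(truth$genome, members, anchor_k)
  covered <- rep(FALSE, g)
  if (any(hits)) {
    r <- rle(hits)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    for (j in which(r$values)) {
      covered[s[j]:min(g, e[j] + anchor_k - 1L)] <- TRUE
    }
  }
  per_iv_rec <- vapply(seq_len(nrow(iv)), function(i)
    sum(covered[(iv$start[i] + 1L):iv$end[i]]), 0)
  fam <- unique(iv$family)
  per_family <- data.frame(
    family = fam,
    recovery = vapply(fam, function(f) {
      sel <- iv$family == f
      sum(per_iv_rec[sel]) / sum(iv$end[sel] - iv$start[sel])
    }, 0, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  list(recovery = if (total > 0) sum(per_iv_rec) / total else NA_real_,
       recovered_bases = as.integer(sum(per_iv_rec)), total_bases = total,
       per_family = per_family)
}

#' Anchor contigs onto the truth genome
#'
#' For each contig, counts how many of its `anchor_k`-mers occur in the truth
#' genome at windows overlapping a planted repeat interval versus windows
#' wholly in unique sequence. Useful to flag contigs that anchor exclusively
#' to unique regions (likely false positives).
#'
#' @inheritParams repeat_base_recovery
#' @param contigs repeat library (path, `repeat_contigs` or character
#'   vector).
#' @return data frame with one row per contig: `n_anchor` (anchored genome
#'   windows), `n_repeat_anchor`, `n_unique_anchor`,
#'   `exclusively_unique`.
#' @export
contig_anchors <- function(truth, contigs, anchor_k = 31L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  seqs <- contig_like(contigs)
  iv <- truth$repeat_intervals
  g <- nchar(truth$genome)
  q <- max(0L, g - anchor_k + 1L)
  win_start0 <- seq_len(q) - 1L
  # does window i (0-based start) overlap any repeat interval?
  in_repeat <- rep(FALSE, q)
  for (i in seq_len(nrow(iv))) {
    lo <- max(1L, iv$start[i] - anchor_k + 2L)
    hi <- min(q, iv$end[i])
    if (lo <= hi) in_repeat[lo:hi] <- TRUE
  }
  res <- lapply(seq_along(seqs), function(i) {
    if (nchar(seqs[i]) < anchor_k)
      return(c(0L, 0L, 0L))
    members <- kmer_count_cpp(seqs[i], anchor_k, TRUE)$kmer
    hits <- window_hits(truth$genome, members, anchor_k)
    c(sum(hits), sum(hits & in_repeat), sum(hits & !in_repeat))
  })
  m <- do.call(rbind, res)
  if (is.null(m)) m <- matrix(integer(0), ncol = 3L)
  data.frame(
    contig = seq_along(seqs), n_anchor = m[, 1L],
    n_repeat_anchor = m[, 2L], n_unique_anchor = m[, 3L],
    exclusively_unique = m[, 1L] > 0L & m[, 2L] == 0L
  )
}
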