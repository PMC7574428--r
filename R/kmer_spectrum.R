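# k-mer spectrum stage: counting, frequency histogram, main-peak location,
# coverage estimation and the high-frequency threshold t1.

#' Count k-mers in a set of reads
#'
#' Slides a window of length `k` over every read and tallies each window made
#' only of A/C/G/T; windows containing any other symbol contribute nothing.
#' With `canonical = TRUE` (the default) a window and its reverse complement
#' are collapsed onto the lexicographically smaller of the two, so counting is
#' strand-symmetric.
#'
#' @param reads character vector of sequences, or a read data frame as
#'   returned by [read_sequences()].
#' @param k k-mer length (1--31).
#' @param canonical collapse reverse-complement pairs (default `TRUE`).
#' @return an object of class `kmer_counts`: a list with elements `k`,
#'   `canonical`, `counts` (named integer vector, keys sorted) and
#'   `total_instances` (number of counted windows).
#' @export
#' @examples
#' count_kmers("ACGTA", k = 3, canonical = FALSE)
count_kmers <- function(reads, k, canonical = TRUE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  seqs <- as_reads(reads)$seq
  if (length(seqs) == 0L) stop("no reads supplied")
  res <- kmer_count_cpp(seqs, k, canonical)
  structure(
    list(k = k, canonical = canonical,
         counts = stats::setNames(res$count, res$kmer),
         total_instances = res$total_instances,
         mean_read_length = mean(nchar(seqs))),
    class = "kmer_counts"
  )
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("k-mer count table: k=%d, %s, %d distinct k-mers, %s instances\n",
              x$k, if (x$canonical) "canonical" else "stranded",
              length(x$counts), format(x$total_instances, big.mark = ",")))
  invisible(x)
}

#' Build the k-mer frequency histogram
#'
#' Tallies, for every occurrence count t, the number f(t) of distinct k-mers
#' seen exactly t times. Two conservation identities hold by construction:
#' the f(t) sum to the number of distinct k-mers, and the t*f(t) sum to the
#' total number of counted windows.
#'
#' @param table a `kmer_counts` object.
#' @return an object of class `kmer_histogram`: a data frame with columns `t`
#'   and `f` (ascending t) and attributes `k`, `distinct` and
#'   `total_instances`.
#' @export
build_histogram <- function(table) {
  stopifnot(inherits(table, "kmer_counts"))
  if (length(table$counts) == 0L) {
    h <- data.frame(t = integer(0), f = integer(0))
  } else {
    tb <- table(table$counts)
    h <- data.frame(t = as.integer(names(tb)), f = as.integer(tb))
    h <- h[order(h$t), , drop = FALSE]
    rownames(h) <- NULL
  }
  structure(h, k = table$k, distinct = length(table$counts),
            total_instances = table$total_instances,
            class = c("kmer_histogram", "data.frame"))
}

#' Write a histogram as tab-separated text
#'
#' Two columns `t<TAB>f(t)`, ascending t, preceded by a single `#k=<k>`
#' comment line.
#'
#' @param hist a `kmer_histogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "kmer_histogram"))
  writeLines(c(sprintf("#k=%d", attr(hist, "k")),
               sprintf("%d\t%d", hist$t, hist$f)), path)
  invisible(path)
}

#' Locate the main peak of a k-mer spectrum
#'
#' Treats the histogram as a dense array over t = 1..max(t) (missing bins are
#' zero). The error-driven decay at small t is skipped by finding the first
#' trough: the smallest `t >= max(2, t_floor)` where f stops decreasing
#' (either a local minimum, or the first rise for spectra with no initial
#' decay). The raw peak is the argmax of f at or beyond the trough (smallest
#' t on ties). When `smooth_window > 0` the peak is refined by fitting a
#' quadratic to log f(t) over a window of that half-width around the raw peak
#' (clipped to the valid range) and rounding the vertex to the nearest
#' integer inside the window.
#'
#' @param hist a `kmer_histogram`.
#' @param t_floor smallest frequency eligible to start the trough search
#'   (default 1).
#' @param smooth_window half-width of the log-quadratic refinement window
#'   (default 5; 0 disables refinement).
#' @return integer peak position p, with attributes `t_min` (trough) and
#'   `p_raw` (unrefined argmax).
#' @export
find_main_peak <- function(hist, t_floor = 1L, smooth_window = 5L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (nrow(hist) == 0L) stop("empty histogram")
  t_floor <- as.integer(t_floor)
  if (is.na(t_floor) || t_floor < 1L) stop("t_floor must be >= 1")
  tmax <- max(hist$t)
  f <- numeric(tmax)
  f[hist$t] <- hist$f

  no_peak <- paste0("spectrum has no secondary peak; ",
                    "supply known coverage (Depth)")
  start <- max(2L, t_floor)
  if (start > tmax) stop(no_peak)
  t_min <- NA_integer_
  for (t in start:tmax) {
    ft <- f[t]; fp <- f[t - 1L]
    fn <- if (t < tmax) f[t + 1L] else 0
    if ((ft <= fp && ft < fn) || ft > fp) { t_min <- t; break }
  }
  if (is.na(t_min)) stop(no_peak)

  p_raw <- which.max(f[t_min:tmax]) + t_min - 1L
  p <- p_raw
  if (smooth_window > 0L) {
    lo <- max(t_min, p_raw - as.integer(smooth_window))
    hi <- min(tmax, p_raw + as.integer(smooth_window))
    tt <- lo:hi
    tt <- tt[f[tt] > 0]
    if (length(tt) >= 3L) {
      y <- log(f[tt])
      fit <- lm(y ~ tt + I(tt^2))
      a <- coef(fit)[[3L]]; b <- coef(fit)[[2L]]
      if (is.finite(a) && a < 0) {
        v <- -b / (2 * a)
        p <- as.integer(round(min(max(v, lo), hi)))
      }
    }
  }
  structure(as.integer(p), t_min = t_min, p_raw = p_raw)
}

#' Estimate average read coverage from the spectrum peak
#'
#' The modal k-mer frequency p under-counts read coverage because a read of
#' length L yields only L - k + 1 windows; the estimate rescales:
#' Cov = p * L / (L - k + 1).
#'
#' @param p integer peak frequency (>= 1).
#' @param read_length mean input read length in bp (must be >= k).
#' @param k k-mer length used for the spectrum.
#' @return an object of class `coverage_estimate`: list with `p`,
#'   `read_length`, `k` and `cov`.
#' @export
#' @examples
#' estimate_coverage(40, 100, 15) # Cov = 4000 / 86
estimate_coverage <- function(p, read_length, k) {
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("p must be a positive integer")
  if (!is.finite(read_length) || !is.finite(k) || k < 1)
    stop("read_length and k must be positive numbers")
  if (read_length < k) stop("read_length must be >= k")
  structure(
    list(p = p, read_length = read_length, k = as.integer(k),
         cov = p * read_length / (read_length - k + 1)),
    class = "coverage_estimate"
  )
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("coverage estimate: p=%d, read_length=%.6g, k=%d -> Cov=%.4f\n",
              x$p, x$read_length, x$k, x$cov))
  invisible(x)
}

#' High-frequency k-mer threshold t1
#'
#' Scales the (known or estimated) average read coverage by the coverage
#' factor c and takes the ceiling, with a floor of 2 so the threshold always
#' exceeds singleton noise. The recommended range for c is \[1.5, 3\]; the
#' larger c, the more stringent the selection. Values outside that interval
#' trigger a warning, not an error.
#'
#' @param cov_or_depth positive average read coverage (known depth, or the
#'   `cov` field of a [estimate_coverage()] result).
#' @param c coverage factor (default 2, midpoint of the recommended range).
#' @return integer threshold t1.
#' @export
#' @examples
#' compute_t1(30, c = 1.5) # 45
compute_t1 <- function(cov_or_depth, c = 2) {
  if (!is.finite(cov_or_depth) || cov_or_depth <= 0)
    stop("cov_or_depth must be a positive number")
  if (!is.finite(c) || c <= 0) stop("coverage factor c must be positive")
  if (c < 1.5 || c > 3)
    warning("coverage factor c = ", c,
            " is outside the recommended interval [1.5, 3]")
  max(2L, as.integer(ceiling(c * cov_or_depth)))
}
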