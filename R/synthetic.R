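# Synthetic ground-truth generator: random background genomes with planted
# repeat families, a uniform paired-end read simulator with substitution
# errors, and per-read origin labels. Every downstream stage is testable
# against these fixtures without any external data.

#' Describe a repeat family to plant
#'
#' @param unit_length repeat unit length in bp (>= 1).
#' @param copy_number number of copies (>= 2).
#' @param divergence per-base substitution probability applied independently
#'   to each copy relative to the family master (in \[0, 0.25)).
#' @param arrangement `"interspersed"` (copies placed independently) or
#'   `"tandem"` (copies adjacent in one block).
#' @return an object of class `repeat_family`.
#' @export
repeat_family <- function(unit_length, copy_number, divergence = 0,
                          arrangement = c("interspersed", "tandem")) {
  arrangement <- match.arg(arrangement)
  unit_length <- as.integer(unit_length)
  copy_number <- as.integer(copy_number)
  if (is.na(unit_length) || unit_length < 1L) stop("unit_length must be >= 1")
  if (is.na(copy_number) || copy_number < 2L) stop("copy_number must be >= 2")
  if (!is.finite(divergence) || divergence < 0 || divergence >= 0.25)
    stop("divergence must be in [0, 0.25)")
  structure(list(unit_length = unit_length, copy_number = copy_number,
                 divergence = divergence, arrangement = arrangement),
            class = "repeat_family")
}

random_bases <- function(n) sample(BASES, n, replace = TRUE)

# Substitute bases at the given per-base rate; substitutions never reproduce
# the original base.
mutate_bases <- function(x, rate) {
  if (rate <= 0) return(x)
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    idx <- match(x[hit], BASES)
    x[hit] <- BASES[((idx - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L) + 1L]
  }
  x
}

#' Generate a genome with planted repeat families
#'
#' Starts from an i.i.d. uniform A/C/G/T background of the requested length,
#' draws one random master unit per family, mutates it independently per copy
#' at the family divergence rate, and overwrites background stretches with
#' the copies: interspersed copies at uniform non-overlapping positions,
#' tandem copies as one adjacent block. Deterministic for a given seed.
#'
#' @param background_length genome length in bp.
#' @param families list of [repeat_family()] objects (possibly empty).
#' @param seed RNG seed.
#' @return an object of class `synthetic_truth`: list with `genome` (string),
#'   `repeat_intervals` (data frame of 0-based half-open `start`, `end`,
#'   `family`), `families` and `seed`.
#' @export
make_genome <- function(background_length, families = list(), seed = 1L) {
  background_length <- as.integer(background_length)
  if (is.na(background_length) || background_length < 1L)
    stop("background_length must be >= 1")
  if (inherits(families, "repeat_family")) families <- list(families)
  stopifnot(all(vapply(families, inherits, TRUE, "repeat_family")))
  planted <- sum(vapply(families, function(f)
    f$unit_length * f$copy_number, 0))
  if (planted >= background_length)
    stop("total planted length must be smaller than background_length")

  set.seed(seed)
  genome <- random_bases(background_length)
  occupied_start <- integer(0)  # 1-based inclusive
  occupied_end <- integer(0)
  iv <- list()

  place <- function(len) {
    # uniform non-overlapping placement with bounded retries
    for (try in 1:1000) {
      s <- sample.int(background_length - len + 1L, 1L)
      e <- s + len - 1L
      if (!any(s <= occupied_end & e >= occupied_start)) return(s)
    }
    stop("genome too crowded: could not place a repeat copy")
  }

  for (fi in seq_along(families)) {
    fam <- families[[fi]]
    master <- random_bases(fam$unit_length)
    copies <- lapply(seq_len(fam$copy_number), function(i)
      mutate_bases(master, fam$divergence))
    if (fam$arrangement == "tandem") {
      block_len <- fam$unit_length * fam$copy_number
      s <- place(block_len)
      occupied_start <- c(occupied_start, s)
      occupied_end <- c(occupied_end, s + block_len - 1L)
      for (i in seq_len(fam$copy_number)) {
        cs <- s + (i - 1L) * fam$unit_length
        genome[cs:(cs + fam$unit_length - 1L)] <- copies[[i]]
        iv[[length(iv) + 1L]] <- c(cs - 1L, cs - 1L + fam$unit_length, fi)
      }
    } else {
      for (i in seq_len(fam$copy_number)) {
        s <- place(fam$unit_length)
        occupied_start <- c(occupied_start, s)
        occupied_end <- c(occupied_end, s + fam$unit_length - 1L)
        genome[s:(s + fam$unit_length - 1L)] <- copies[[i]]
        iv[[length(iv) + 1L]] <- c(s - 1L, s - 1L + fam$unit_length, fi)
      }
    }
  }

  ivdf <- if (length(iv)) {
    m <- do.call(rbind, iv)
    data.frame(start = m[, 1L], end = m[, 2L],
               family = sprintf("family_%d", m[, 3L]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(start = integer(0), end = integer(0), family = character(0))
  }
  ivdf <- ivdf[order(ivdf$start), , drop = FALSE]
  rownames(ivdf) <- NULL
  structure(
    list(genome = paste(genome, collapse = ""), repeat_intervals = ivdf,
         families = families, seed = seed),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic genome: %d bp, %d planted repeat copies (%d families)\n",
              nchar(x$genome), nrow(x$repeat_intervals), length(x$families)))
  invisible(x)
}

# Label the 0-based half-open read interval [s0, e0) against sorted
# non-overlapping repeat intervals.
label_intervals <- function(s0, e0, iv) {
  if (nrow(iv) == 0L) return(rep("unique", length(s0)))
  idx <- findInterval(s0, iv$start)
  inside <- idx >= 1L & ifelse(idx >= 1L, e0 <= iv$end[pmax(idx, 1L)], FALSE)
  # overlap with the interval at idx or the next one
  ov_prev <- idx >= 1L & s0 < iv$end[pmax(idx, 1L)]
  nxt <- pmin(idx + 1L, nrow(iv))
  ov_next <- idx < nrow(iv) & e0 > iv$start[nxt]
  ifelse(inside, "repeat", ifelse(ov_prev | ov_next, "boundary", "unique"))
}

#' Simulate paired-end reads with ground-truth labels
#'
#' Fragment starts are uniform over the genome; fragment lengths are normal
#' with the given mean and sd (clamped to \[read_length, genome length\]).
#' The number of pairs is `round(coverage * genome_length / (2 *
#' read_length))`. Mate 1 is the fragment 5' end, mate 2 the
#' reverse-complemented 3' end. Substitution errors are applied per base at
#' `error_rate`. Each mate is labelled `repeat` if its source interval lies
#' wholly inside one planted repeat copy, `unique` if wholly outside all, and
#' `boundary` otherwise.
#'
#' @param truth a `synthetic_truth` from [make_genome()].
#' @param coverage target average read coverage (> 0).
#' @param read_length read length in bp (<= insert_mean).
#' @param insert_mean,insert_sd fragment length distribution (bp).
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @return an object of class `synthetic_reads`: list with `r1`, `r2` (read
#'   data frames), `labels` (data frame `read_id`, `label`, one row per
#'   mate) and `layout` (fragment coordinates).
#' @export
simulate_reads <- function(truth, coverage, read_length = 100L,
                           insert_mean = 300L, insert_sd = 30L,
                           error_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  g <- nchar(truth$genome)
  read_length <- as.integer(read_length)
  if (!is.finite(coverage) || coverage <= 0) stop("coverage must be > 0")
  if (read_length > insert_mean) stop("read_length must be <= insert_mean")
  if (insert_mean > g) stop("insert longer than genome")
  if (!is.finite(error_rate) || error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)")

  set.seed(seed)
  n <- as.integer(round(coverage * g / (2 * read_length)))
  if (n < 1L) stop("coverage too low: no read pairs to simulate")
  frag <- pmin(g, pmax(read_length, as.integer(round(
    rnorm(n, insert_mean, insert_sd)))))
  start <- as.integer(floor(runif(n) * (g - frag + 1L))) + 1L

  s1 <- start
  s2 <- start + frag - read_length
  r1 <- substring(truth$genome, s1, s1 + read_length - 1L)
  r2 <- revcomp(substring(truth$genome, s2, s2 + read_length - 1L))
  r1 <- inject_errors(r1, error_rate)
  r2 <- inject_errors(r2, error_rate)

  ids <- sprintf("read_%06d", seq_len(n))
  lab1 <- label_intervals(s1 - 1L, s1 - 1L + read_length,
                          truth$repeat_intervals)
  lab2 <- label_intervals(s2 - 1L, s2 - 1L + read_length,
                          truth$repeat_intervals)
  qual <- strrep("I", read_length)
  structure(
    list(
      r1 = data.frame(id = paste0(ids, "/1"), seq = r1, qual = qual,
                      stringsAsFactors = FALSE),
      r2 = data.frame(id = paste0(ids, "/2"), seq = r2, qual = qual,
                      stringsAsFactors = FALSE),
      labels = data.frame(read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
                          label = c(lab1, lab2), stringsAsFactors = FALSE),
      layout = data.frame(pair = ids, start = start, fragment = frag,
                          stringsAsFactors = FALSE)
    ),
    class = "synthetic_reads"
  )
}

#' @export
print.synthetic_reads <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("synthetic reads: %d pairs (%s)\n", nrow(x$r1),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Substitution errors over a vector of equal-length reads, applied at
# uniformly chosen base positions.
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(seqs)
  pos <- sort(sample.int(total, n_err))
  ends <- cumsum(lens)
  read_idx <- findInterval(pos - 1L, ends) + 1L
  offset <- pos - c(0L, ends)[read_idx]  # 1-based within read
  for (j in seq_len(n_err)) {
    i <- read_idx[j]; o <- offset[j]
    b <- substr(seqs[i], o, o)
    idx <- match(b, BASES)
    if (is.na(idx)) next
    sub <- BASES[((idx - 1L + sample(1:3, 1L)) %% 4L) + 1L]
    substr(seqs[i], o, o) <- sub
  }
  seqs
}

#' Write a synthetic fixture to disk
#'
#' Writes `genome.fasta`, `reads_R1.fastq`, `reads_R2.fastq`,
#' `truth_intervals.bed` (BED3 plus family name) and `read_labels.tsv` under
#' `dir`.
#'
#' @param truth a `synthetic_truth`.
#' @param reads a `synthetic_reads`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(truth, reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(stats::setNames(truth$genome, "synthetic_genome"),
              file.path(dir, "genome.fasta"))
  write_fastq(reads$r1, file.path(dir, "reads_R1.fastq"))
  write_fastq(reads$r2, file.path(dir, "reads_R2.fastq"))
  iv <- truth$repeat_intervals
  writeLines(sprintf("synthetic_genome\t%d\t%d\t%s", iv$start, iv$end,
                     iv$family), file.path(dir, "truth_intervals.bed"))
  writeLines(c("read_id\tlabel",
               sprintf("%s\t%s", reads$labels$read_id, reads$labels$label)),
             file.path(dir, "read_labels.tsv"))
  invisible(dir)
}
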