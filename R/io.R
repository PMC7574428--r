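# Shared sequence I/O. FASTA parsing is delegated to Biostrings; FASTQ uses a
# small strict 4-line reader because the downstream pair-partitioning contract
# requires verbatim quality strings and line-numbered errors on malformed
# records. Plain and gzip-compressed files are both accepted (base R
# connections decompress transparently).

#' Read sequences from FASTA or FASTQ
#'
#' Reads a (optionally gzip-compressed) FASTA or FASTQ file into a data frame
#' with columns `id`, `seq` and `qual` (`NA` for FASTA). The format is sniffed
#' from the first non-empty character (`>` FASTA, `@` FASTQ). Sequences are
#' folded to upper case on ingest; identifiers are truncated at the first
#' whitespace; quality strings are kept verbatim.
#'
#' @param path file path.
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- ""
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("empty sequence file: ", path)
    if (nzchar(trimws(line))) { first <- substr(trimws(line), 1L, 1L); break }
  }
  if (first == ">") {
    set <- Biostrings::readBStringSet(path)
    data.frame(
      id = sub("\\s.*$", "", names(set)),
      seq = toupper(as.character(set)),
      qual = NA_character_,
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else if (first == "@") {
    read_fastq(path)
  } else {
    stop("unrecognized sequence format in ", path,
         " (expected '>' or '@' as first character)")
  }
}

read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only; blanks inside a record are malformed
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  n <- length(lines)
  if (n == 0L) stop("empty FASTQ file: ", path)
  if (n %% 4L != 0L)
    stop("truncated FASTQ record at line ", (n %/% 4L) * 4L + 1L, " in ", path)
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]; seq <- lines[idx + 1L]
  plus <- lines[idx + 2L]; qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("malformed FASTQ record at line ", (bad[1L] - 1L) * 4L + 1L,
         ": header must start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record at line ", (bad[1L] - 1L) * 4L + 3L,
         ": separator must start with '+'")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record at line ", (bad[1L] - 1L) * 4L + 4L,
         ": quality length differs from sequence length")
  data.frame(
    id = sub("\\s.*$", "", sub("^@", "", hdr)),
    seq = toupper(seq),
    qual = qual,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Coerce the various read containers to a data frame with id/seq[/qual].
as_reads <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(x))
    return(data.frame(id = ids, seq = toupper(unname(x)),
                      qual = rep(NA_character_, length(x)),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x)))
      stop("read data frame needs columns 'id' and 'seq'")
    x$seq <- toupper(x$seq)
    if (is.null(x$qual)) x$qual <- NA_character_
    return(x[, c("id", "seq", "qual")])
  }
  stop("cannot interpret object of class '", class(x)[1L], "' as reads")
}

#' Write sequences as FASTA
#'
#' @param x a named character vector, a read data frame (`id`, `seq`) or a
#'   contig data frame (`contig_id`, `seq`, `length`, `mean_cov`; the header
#'   then carries `length=` and `cov=` tokens).
#' @param path output file.
#' @param wrap line width for the sequence (default 80; `0` disables
#'   wrapping).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, wrap = 80L) {
  if (is.data.frame(x) && all(c("contig_id", "seq") %in% names(x))) {
    ids <- x$contig_id
    if (all(c("length", "mean_cov") %in% names(x)))
      ids <- sprintf("%s length=%d cov=%.6g", ids, x$length, x$mean_cov)
    seqs <- x$seq
  } else {
    r <- as_reads(x)
    ids <- r$id; seqs <- r$seq
  }
  out <- character(0)
  if (length(ids)) {
    chunks <- lapply(seqs, function(s) {
      if (wrap <= 0L || nchar(s) <= wrap) return(s)
      substring(s, seq(1L, nchar(s), by = wrap),
                pmin(nchar(s), seq(wrap, nchar(s) + wrap - 1L, by = wrap)))
    })
    out <- unlist(mapply(function(i, ch) c(paste0(">", i), ch),
                         ids, chunks, SIMPLIFY = FALSE), use.names = FALSE)
  }
  writeLines(out, path)
  invisible(path)
}

#' Write sequences as FASTQ
#'
#' Records missing a quality string receive a constant `I` quality.
#'
#' @param x read data frame (`id`, `seq`, optional `qual`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  r <- as_reads(x)
  qual <- ifelse(is.na(r$qual), strrep("I", nchar(r$seq)), r$qual)
  out <- character(0)
  if (nrow(r))
    out <- as.vector(rbind(paste0("@", r$id), r$seq, "+", qual))
  writeLines(out, path)
  invisible(path)
}
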