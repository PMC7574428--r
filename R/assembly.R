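# Assembly stage: a minimal unitig-only de Bruijn assembler for desk-scale
# runs, an adapter contract for an external assembler, and the contig
# coverage/length filters that produce the final repeat library.

#' Build a de Bruijn graph from reads
#'
#' Edges are canonical `k_asm`-mers of the reads with their multiplicities;
#' edges seen fewer than `prune_below` times are removed (dropping orphan
#' nodes implicitly). `k_asm` must be odd so no edge is its own reverse
#' complement.
#'
#' @param reads character vector of sequences or a read data frame.
#' @param k_asm assembly k-mer size (odd, default 31).
#' @param prune_below minimum edge multiplicity kept (default 2, which drops
#'   singleton edges from sequencing errors).
#' @return an object of class `debruijn_graph`: list with `k`, `kmers`,
#'   `multiplicity` and `prune_below`.
#' @export
build_graph <- function(reads, k_asm = 31L, prune_below = 2L) {
  k_asm <- as.integer(k_asm)
  if (is.na(k_asm) || k_asm < 3L || k_asm %% 2L == 0L)
    stop("k_asm must be an odd integer >= 3")
  seqs <- as_reads(reads)$seq
  if (length(seqs) == 0L || !any(nchar(seqs) >= k_asm))
    stop("no assembly k-mers: no read reaches length k_asm")
  res <- kmer_count_cpp(seqs, k_asm, TRUE)
  keep <- res$count >= prune_below
  structure(
    list(k = k_asm, kmers = res$kmer[keep],
         multiplicity = res$count[keep],
         prune_below = as.integer(prune_below)),
    class = "debruijn_graph"
  )
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf("de Bruijn graph: k=%d, %d edges (pruned below %d)\n",
              x$k, length(x$kmers), x$prune_below))
  invisible(x)
}

#' Emit unitig contigs from a de Bruijn graph
#'
#' Contigs are maximal unbranched paths; each is reported once in canonical
#' orientation (the lexicographically smaller of the sequence and its reverse
#' complement), ordered by descending length with ties broken by sequence.
#' `mean_cov` is the mean edge multiplicity along the path.
#'
#' @param graph a `debruijn_graph`.
#' @return an object of class `repeat_contigs`: data frame with columns
#'   `contig_id`, `seq`, `length`, `mean_cov`.
#' @export
emit_contigs <- function(graph) {
  stopifnot(inherits(graph, "debruijn_graph"))
  if (length(graph$kmers) == 0L) return(empty_contigs())
  res <- dbg_unitigs_cpp(graph$kmers, as.numeric(graph$multiplicity), graph$k)
  seqs <- res$seq
  rc <- revcomp(seqs)
  seqs <- ifelse(rc < seqs, rc, seqs)
  ord <- order(-nchar(seqs), seqs)
  as_contigs(seqs[ord], res$mean_cov[ord])
}

empty_contigs <- function() {
  structure(
    data.frame(contig_id = character(0), seq = character(0),
               length = integer(0), mean_cov = numeric(0),
               stringsAsFactors = FALSE),
    class = c("repeat_contigs", "data.frame")
  )
}

as_contigs <- function(seqs, mean_cov) {
  structure(
    data.frame(contig_id = sprintf("contig_%d", seq_along(seqs)),
               seq = seqs, length = nchar(seqs), mean_cov = mean_cov,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("repeat_contigs", "data.frame")
  )
}

#' Filter contigs into the repeat library
#'
#' Keeps contigs with mean coverage at least `min_cov` and length at least
#' `min_len` (both inclusive), sorted by descending length with ties broken
#' by sequence. A warning is raised when everything is filtered away.
#'
#' @param contigs a `repeat_contigs` data frame.
#' @param min_cov minimum mean k-mer coverage (default 0 keeps all).
#' @param min_len minimum contig length in bp (default 0 keeps all).
#' @return the filtered, re-sorted `repeat_contigs`.
#' @export
filter_contigs <- function(contigs, min_cov = 0, min_len = 0L) {
  stopifnot(is.data.frame(contigs),
            all(c("seq", "length", "mean_cov") %in% names(contigs)))
  keep <- contigs$mean_cov >= min_cov & contigs$length >= min_len
  out <- contigs[keep, , drop = FALSE]
  if (nrow(contigs) > 0L && nrow(out) == 0L)
    warning("all contigs removed by the coverage/length filters")
  ord <- order(-out$length, out$seq)
  out <- out[ord, , drop = FALSE]
  as_contigs(out$seq, out$mean_cov)
}

#' Run an external assembler through a command template
#'
#' Substitutes `{input}` (space-separated, shell-quoted read file paths),
#' `{output}` (the contig FASTA the command must create) and `{workdir}` into
#' `adapter_cmd`, runs it through the shell, and parses the resulting FASTA.
#' Mean contig coverage is taken from a `cov_<x>` or `cov=<x>` token in each
#' header when present; otherwise it is recomputed by mapping canonical
#' `k`-mer counts of the input reads onto the contig.
#'
#' @param reads character vector of read file paths (FASTA/FASTQ).
#' @param adapter_cmd shell command template containing `{input}` and
#'   `{output}`.
#' @param workdir working directory for the assembler (created; default a
#'   fresh temporary directory).
#' @param k k-mer size for the coverage re-mapping fallback (default 31).
#' @return a `repeat_contigs` data frame.
#' @export
run_external_assembler <- function(reads, adapter_cmd,
                                   workdir = tempfile("hifrep_asm_"),
                                   k = 31L) {
  stopifnot(is.character(reads), length(reads) > 0L)
  missing <- reads[!file.exists(reads)]
  if (length(missing)) stop("read file not found: ", missing[1L])
  if (!grepl("{output}", adapter_cmd, fixed = TRUE))
    stop("adapter_cmd must contain the {output} placeholder")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  out_fa <- file.path(workdir, "contigs.fasta")
  cmd <- adapter_cmd
  cmd <- gsub("{input}", paste(shQuote(reads), collapse = " "), cmd,
              fixed = TRUE)
  cmd <- gsub("{output}", shQuote(out_fa), cmd, fixed = TRUE)
  cmd <- gsub("{workdir}", shQuote(workdir), cmd, fixed = TRUE)

  exe <- strsplit(trimws(adapter_cmd), "\\s+")[[1L]][1L]
  if (!file.exists(exe) && Sys.which(exe) == "")
    stop("assembler not found: ", exe)

  log <- suppressWarnings(system2("sh", c("-c", shQuote(cmd)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(log, "status")
  if (!is.null(status) && status != 0L)
    stop("external assembler failed (exit ", status, "): ",
         paste(tail(log, 5L), collapse = " | "))
  if (!file.exists(out_fa))
    stop("external assembler produced no contig FASTA at ", out_fa, ": ",
         paste(tail(log, 5L), collapse = " | "))

  fa <- tryCatch(read_sequences(out_fa), error = function(e)
    stop("unparsable assembler output: ", conditionMessage(e)))
  if (nrow(fa) == 0L) return(empty_contigs())

  hdr <- sub("\\s.*$", "", fa$id)
  m <- regmatches(fa$id, regexpr("cov[_=]([0-9]+\\.?[0-9]*)", fa$id))
  mean_cov <- rep(NA_real_, nrow(fa))
  has <- lengths(regmatches(fa$id, gregexpr("cov[_=]", fa$id))) > 0
  mean_cov[has] <- as.numeric(sub("cov[_=]", "", m))
  if (anyNA(mean_cov)) {
    tab <- count_kmers(do.call(rbind, lapply(reads, read_sequences)),
                       k = k, canonical = TRUE)
    for (i in which(is.na(mean_cov))) {
      w <- kmer_window_counts_cpp(fa$seq[i], names(tab$counts),
                                  as.numeric(tab$counts), tab$k, TRUE)
      mean_cov[i] <- if (length(w)) mean(w) else 0
    }
  }
  seqs <- fa$seq
  rc <- revcomp(seqs)
  flip <- rc < seqs
  seqs <- ifelse(flip, rc, seqs)
  ord <- order(-nchar(seqs), seqs)
  as_contigs(seqs[ord], mean_cov[ord])
}
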