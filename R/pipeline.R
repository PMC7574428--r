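# Pipeline driver: spectrum -> threshold -> high-frequency k-mer set ->
# read partition -> assembly -> contig filters -> repeat library, with a
# machine-readable JSON run report and a run log.

#' Assemble a pipeline configuration
#'
#' Collects and validates every tunable of the pipeline. `min_contig_cov =
#' "auto"` resolves at run time to the genome-average k-mer coverage,
#' `ceiling(cov * (L - k_asm + 1) / L)`: a contig assembled from repeats
#' should exceed the single-copy expectation.
#'
#' @param reads1 path to the first-mate FASTQ/FASTA (or unpaired reads).
#' @param reads2 optional path to the second-mate file.
#' @param out_dir output directory for all artifacts.
#' @param k_hist spectrum k-mer size (default 15).
#' @param k_filter filtering k-mer size (default 31).
#' @param canonical strand-collapsing flag (default `TRUE`).
#' @param depth optional known average read coverage; when given, t1 is
#'   computed from it directly and the spectrum peak is reported for
#'   diagnostics only.
#' @param c_factor coverage factor c (default 2).
#' @param t2 read-level high-frequency fraction threshold (default 0.9).
#' @param pairing_mode `"strict"`, `"either"` or `"ignore"`.
#' @param smooth_window peak refinement half-width (default 5).
#' @param assembler `"builtin"` or `"external"`.
#' @param assembler_cmd command template for the external assembler (see
#'   [run_external_assembler()]).
#' @param k_asm assembly k-mer size (odd, default 31).
#' @param prune_below de Bruijn edge pruning threshold (default 2).
#' @param min_contig_cov minimum contig mean coverage, or `"auto"`.
#' @param min_contig_len minimum contig length in bp (default 100).
#' @param seed seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(reads1, reads2 = NULL, out_dir,
                            k_hist = 15L, k_filter = 31L, canonical = TRUE,
                            depth = NULL, c_factor = 2, t2 = 0.9,
                            pairing_mode = "strict", smooth_window = 5L,
                            assembler = c("builtin", "external"),
                            assembler_cmd = NULL, k_asm = 31L,
                            prune_below = 2L, min_contig_cov = "auto",
                            min_contig_len = 100L, seed = 1L) {
  assembler <- match.arg(assembler)
  if (assembler == "external" && is.null(assembler_cmd))
    stop("assembler = 'external' requires assembler_cmd")
  if (!is.null(depth) && (!is.finite(depth) || depth <= 0))
    stop("depth must be a positive number")
  if (!is.finite(t2) || t2 <= 0 || t2 > 1) stop("t2 must be in (0, 1]")
  if (!is.finite(c_factor) || c_factor <= 0) stop("c_factor must be > 0")
  if (!identical(min_contig_cov, "auto") &&
      (!is.numeric(min_contig_cov) || min_contig_cov < 0))
    stop("min_contig_cov must be 'auto' or a non-negative number")
  structure(
    list(reads1 = reads1, reads2 = reads2, out_dir = out_dir,
         k_hist = as.integer(k_hist), k_filter = as.integer(k_filter),
         canonical = isTRUE(canonical), depth = depth,
         c_factor = c_factor, t2 = t2,
         pairing_mode = match.arg(pairing_mode,
                                  c("strict", "either", "ignore")),
         smooth_window = as.integer(smooth_window),
         assembler = assembler, assembler_cmd = assembler_cmd,
         k_asm = as.integer(k_asm), prune_below = as.integer(prune_below),
         min_contig_cov = min_contig_cov,
         min_contig_len = as.integer(min_contig_len),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full repeat-identification pipeline
#'
#' Executes: count `k_hist`-mers, build and persist the frequency histogram,
#' locate the peak and estimate coverage (skipped for t1 when `depth` is
#' supplied), derive t1, count `k_filter`-mers, select the high-frequency
#' set, partition the reads, assemble the passing reads, filter the contigs
#' and write the repeat library plus a JSON run report.
#'
#' Outputs under `out_dir`: `histogram_k<k>.tsv`, `highfreq_R1.fastq`,
#' `highfreq_R2.fastq`, `highfreq_singletons.fastq`, `repeats.fasta`,
#' `report.json`, `run.log`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (default `FALSE`).
#' @return the run report (list), invisibly; its `library` element holds the
#'   final `repeat_contigs`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(config$seed)
  started <- Sys.time()

  say("reading input reads")
  r1 <- stage("input", read_sequences(config$reads1))
  r2 <- if (!is.null(config$reads2))
    stage("input", read_sequences(config$reads2))
  n_reads <- nrow(r1) + if (is.null(r2)) 0L else nrow(r2)
  mean_len <- mean(nchar(c(r1$seq, r2$seq)))
  say(sprintf("%d reads, mean length %.1f bp", n_reads, mean_len))

  say(sprintf("counting k=%d spectrum k-mers", config$k_hist))
  tab_h <- stage("spectrum",
                 count_kmers(rbind(r1, r2), config$k_hist, config$canonical))
  hist <- stage("spectrum", build_histogram(tab_h))
  hist_path <- file.path(config$out_dir,
                         sprintf("histogram_k%d.tsv", config$k_hist))
  write_histogram(hist, hist_path)

  p <- tryCatch(find_main_peak(hist, smooth_window = config$smooth_window),
                error = function(e) {
                  if (is.null(config$depth)) stop(
                    "pipeline stage 'peak' failed: ", conditionMessage(e),
                    call. = FALSE)
                  NA_integer_
                })
  cov_est <- if (!is.na(p))
    estimate_coverage(p, mean_len, config$k_hist)
  cov_used <- if (!is.null(config$depth)) config$depth else cov_est$cov
  say(sprintf("peak p=%s, estimated Cov=%s, using Cov=%.3f (%s)",
              ifelse(is.na(p), "NA", p),
              ifelse(is.null(cov_est), "NA", sprintf("%.3f", cov_est$cov)),
              cov_used,
              if (is.null(config$depth)) "estimated" else "known depth"))

  t1 <- stage("threshold", compute_t1(cov_used, config$c_factor))
  say(sprintf("high-frequency threshold t1=%d (c=%.2f)", t1,
              config$c_factor))

  say(sprintf("counting k=%d filtering k-mers", config$k_filter))
  tab_f <- stage("filter-kmers",
                 count_kmers(rbind(r1, r2), config$k_filter,
                             config$canonical))
  sh <- select_high_frequency_kmers(tab_f, t1)
  say(sprintf("%d of %d distinct k-mers are high-frequency",
              length(sh$members), length(tab_f$counts)))

  say("partitioning reads")
  part <- stage("partition",
                suppressMessages(partition_reads(
                  r1, r2, sh, t2 = config$t2,
                  pairing_mode = config$pairing_mode)))
  write_fastq(part$paired_pass$r1,
              file.path(config$out_dir, "highfreq_R1.fastq"))
  write_fastq(part$paired_pass$r2,
              file.path(config$out_dir, "highfreq_R2.fastq"))
  write_fastq(part$singleton_pass,
              file.path(config$out_dir, "highfreq_singletons.fastq"))
  asm_reads <- partition_pass_reads(part)
  say(sprintf("%d pairs kept whole, %d singletons, %d reads rejected",
              nrow(part$paired_pass$r1), nrow(part$singleton_pass),
              part$rejected_count))
  if (nrow(asm_reads) == 0L)
    stop("no high-frequency reads; lower c or t2", call. = FALSE)

  say(sprintf("assembling %d high-frequency reads (%s, k=%d)",
              nrow(asm_reads), config$assembler, config$k_asm))
  contigs <- if (config$assembler == "builtin") {
    g <- stage("assembly", build_graph(asm_reads, config$k_asm,
                                       config$prune_below))
    stage("assembly", emit_contigs(g))
  } else {
    paths <- c(file.path(config$out_dir, "highfreq_R1.fastq"),
               file.path(config$out_dir, "highfreq_R2.fastq"),
               file.path(config$out_dir, "highfreq_singletons.fastq"))
    paths <- paths[file.size(paths) > 0]
    stage("assembly", run_external_assembler(
      paths, config$assembler_cmd,
      workdir = file.path(config$out_dir, "external_asm"),
      k = config$k_asm))
  }

  min_cov <- config$min_contig_cov
  if (identical(min_cov, "auto"))
    min_cov <- ceiling(cov_used * (mean_len - config$k_asm + 1) / mean_len)
  say(sprintf("%d raw contigs; filtering at min_cov=%.3g, min_len=%d",
              nrow(contigs), min_cov, config$min_contig_len))
  lib <- stage("contig-filter",
               suppressWarnings(filter_contigs(contigs, min_cov,
                                               config$min_contig_len)))
  if (nrow(lib) == 0L)
    say("warning: repeat library is empty after filtering")
  lib$contig_id <- sprintf("hifrep_contig_%d", seq_len(nrow(lib)))
  write_fasta(lib, file.path(config$out_dir, "repeats.fasta"))
  say(sprintf("final library: %d contigs", nrow(lib)))

  stats <- if (nrow(lib) > 0L) unclass(library_stats(lib))
  report <- list(
    config = config[!vapply(config, is.null, TRUE)],
    n_input_reads = n_reads,
    mean_read_length = mean_len,
    spectrum = list(k = config$k_hist, distinct = length(tab_h$counts),
                    total_instances = tab_h$total_instances),
    p = if (is.na(p)) NULL else as.integer(p),
    cov_estimated = if (is.null(cov_est)) NULL else cov_est$cov,
    cov_used = cov_used,
    t1 = t1, t2 = config$t2,
    n_highfreq_kmers = length(sh$members),
    n_pairs_pass = nrow(part$paired_pass$r1),
    n_singletons_pass = nrow(part$singleton_pass),
    n_rejected = part$rejected_count,
    contigs_before_filter = nrow(contigs),
    contigs_after_filter = nrow(lib),
    library_stats = stats,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$library <- lib
  invisible(report)
}
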