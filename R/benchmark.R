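# Recovery benchmarks of the kernel-density caller against the fixed-window
# crosslink-centered-region (CCR) baseline on simulated libraries.

#' Benchmark site callers on a simulated library
#'
#' Runs [call_sites()] and the 41-nt CCR baseline on the same classified
#' reads and reports planted-site recall (a planted crosslink recovered when
#' a called site midpoint lies within `tol` nt of it), nucleotide precision
#' (called nucleotides within `truth_window` nt of a planted crosslink over
#' all called nucleotides), and optionally the motif-match signal-to-noise of
#' called sites against the whole simulated transcriptome.
#'
#' @param reads classified reads ([classify_reads()] output).
#' @param reference output of [simulate_reference()] (provides genome and
#'   ground truth).
#' @param mode site extension mode passed to [call_sites()].
#' @param tol midpoint tolerance in nt for recall (default 3).
#' @param truth_window half-width of the true-site window used for
#'   nucleotide precision (default 20).
#' @param motif optional IUPAC motif; when given, match signal-to-noise of
#'   each caller's regions vs. the transcriptome is reported.
#' @param ... further arguments to [call_sites()].
#' @return list with per-caller data.frames `sites` / `ccrs` and a `metrics`
#'   data.frame (caller, n_regions, recall, nt_precision, motif_sn).
#' @export
benchmark_callers <- function(reads, reference, mode = "fixed5", tol = 3L,
                              truth_window = 20L, motif = NULL, ...) {
  genome <- reference$genome
  truth <- reference$truth
  sites <- call_sites(reads, genome, mode = mode, ...)
  ccrs <- ccr_regions(reads, genome)
  metrics <- rbind(
    caller_metrics("kde", sites, truth, genome, tol, truth_window, motif),
    caller_metrics("ccr", ccrs, truth, genome, tol, truth_window, motif))
  list(sites = sites, ccrs = ccrs, metrics = metrics)
}

#' @noRd
caller_metrics <- function(name, regions, truth, genome, tol, truth_window,
                           motif) {
  recall <- planted_recall(regions, truth, tol)
  prec <- nt_precision(regions, truth, truth_window)
  sn <- NA_real_
  if (!is.null(motif) && nrow(regions) > 0L) {
    fg_seqs <- region_sequences(regions, genome)
    fg_m <- sum(vapply(fg_seqs, function(s) length(iupac_scan(s, motif)),
                       integer(1)))
    fg_nt <- sum(nchar(fg_seqs))
    bg_seqs <- unname(genome)
    bg_m <- sum(vapply(bg_seqs, function(s) {
      length(iupac_scan(s, motif)) + length(iupac_scan(revcomp(s), motif))
    }, integer(1)))
    bg_nt <- 2L * sum(nchar(bg_seqs))
    if (fg_nt > 0 && bg_m > 0) {
      sn <- signal_to_noise(fg_m, fg_nt, bg_m, bg_nt)$ratio
    }
  }
  data.frame(caller = name, n_regions = nrow(regions), recall = recall,
             nt_precision = prec, motif_sn = sn, stringsAsFactors = FALSE)
}

#' Fraction of planted crosslinks with a called-site midpoint within `tol` nt
#' @noRd
planted_recall <- function(regions, truth, tol = 3L) {
  if (nrow(truth) == 0L) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    sel <- regions$chrom == truth$chrom[i] &
      regions$strand == truth$strand[i]
    if (!any(sel)) return(FALSE)
    mid <- (regions$start[sel] + regions$end[sel] - 1) / 2
    any(abs(mid - truth$crosslink_pos[i]) <= tol)
  }, logical(1))
  mean(hit)
}

#' Fraction of called nucleotides within the true-site windows
#' @noRd
nt_precision <- function(regions, truth, truth_window = 20L) {
  if (nrow(regions) == 0L) return(NA_real_)
  reg <- gr0(regions$chrom, regions$start, regions$end, regions$strand)
  if (nrow(truth) == 0L) return(0)
  tw <- gr0(truth$chrom, pmax(0L, truth$crosslink_pos - truth_window),
            truth$crosslink_pos + truth_window + 1L, truth$strand)
  ov <- sum(width(GenomicRanges::intersect(
    reduce(reg, ignore.strand = FALSE), reduce(tw, ignore.strand = FALSE))))
  ov / sum(width(reduce(reg)))
}
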