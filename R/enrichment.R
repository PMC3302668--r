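# Expressed-gene backgrounds, the signal-to-noise statistic and positional
# analysis along normalised 3' UTRs.

#' Expressed gene set from a probe-level expression table
#'
#' Replicate probe measurements are averaged per probe, a gene takes the
#' maximum of its probe values, and a gene is called expressed when its value
#' strictly exceeds the given percentile of all background probes (probes not
#' associated with any gene). The percentile uses the linear-interpolation
#' convention of the empirical distribution.
#'
#' @param table data.frame with `gene_id`, `probe_id`, `value` and logical
#'   `is_background` (one row per probe measurement; replicates share a
#'   probe_id).
#' @param percentile background percentile used as threshold (default 80).
#' @return list with `genes` (character vector of expressed gene ids),
#'   `threshold` and per-gene `values`.
#' @export
expressed_gene_set <- function(table, percentile = 80) {
  bg <- table$value[table$is_background]
  if (length(bg) == 0L) stop("no background probes in expression table")
  thr <- unname(quantile(bg, percentile / 100, type = 7))
  fg <- table[!table$is_background, , drop = FALSE]
  probe_means <- tapply(fg$value, list(fg$gene_id, fg$probe_id), mean)
  gene_vals <- apply(probe_means, 1, max, na.rm = TRUE)
  list(genes = names(gene_vals)[gene_vals > thr], threshold = thr,
       values = gene_vals)
}

#' Signal-to-noise ratio of motif matches in interaction sites
#'
#' The number of matches per nucleotide in the foreground set (called sites)
#' divided by the matches per nucleotide in the background set (expressed
#' genes or their 3' UTRs).
#'
#' @param fg_matches,fg_nt foreground match and nucleotide counts.
#' @param bg_matches,bg_nt background match and nucleotide counts.
#' @return object of class `sn_result`: list with the four counts and
#'   `ratio`.
#' @export
signal_to_noise <- function(fg_matches, fg_nt, bg_matches, bg_nt) {
  stopifnot(fg_nt > 0, bg_nt > 0, fg_matches >= 0)
  if (bg_matches <= 0) stop("undefined ratio: zero background matches")
  structure(list(fg_matches = fg_matches, fg_nucleotides = fg_nt,
                 bg_matches = bg_matches, bg_nucleotides = bg_nt,
                 ratio = (fg_matches / fg_nt) / (bg_matches / bg_nt)),
            class = "sn_result")
}

#' @export
print.sn_result <- function(x, ...) {
  cat(sprintf(
    "signal-to-noise: %.2f  (%s matches / %s nt vs %s matches / %s nt)\n",
    round(x$ratio, 2), format(x$fg_matches, big.mark = ","),
    format(x$fg_nucleotides, big.mark = ","),
    format(x$bg_matches, big.mark = ","),
    format(x$bg_nucleotides, big.mark = ",")))
  invisible(x)
}

#' Position of an interaction site along a normalised 3' UTR
#'
#' The site midpoint, as a fraction of the UTR length measured from the UTR
#' 5' end, scaled to 100% for genes with a single annotated polyadenylation
#' site and to 200% for genes with two or more.
#'
#' @param site_start,site_end site coordinates (0-based half-open).
#' @param utr_start,utr_end 3' UTR coordinates (0-based half-open).
#' @param n_polya number of annotated polyadenylation sites for the gene.
#' @param strand `"+"` or `"-"` (the fraction is measured in transcript
#'   orientation).
#' @return list with `fraction` (in percent of the normalised scale) and
#'   `scale` (100 or 200).
#' @export
normalized_utr_position <- function(site_start, site_end, utr_start, utr_end,
                                    n_polya = 1L, strand = "+") {
  mid <- (site_start + site_end) / 2
  if (mid < utr_start || mid > utr_end) stop("site midpoint outside the UTR")
  len <- utr_end - utr_start
  frac <- if (strand == "+") (mid - utr_start) / len else (utr_end - mid) / len
  scale <- if (n_polya >= 2L) 200 else 100
  list(fraction = frac * scale, scale = scale)
}

#' Smoothed signal-to-noise along the miRNA expression ranking
#'
#' Centered moving average of log2 signal-to-noise ratios over miRNAs ordered
#' by expression rank; partial windows at the edges, and a window at least as
#' long as the list collapses to the single global mean.
#'
#' @param ratios per-miRNA signal-to-noise ratios, in expression-rank order.
#' @param window moving-average window size (default 21).
#' @return numeric vector of averaged log2 ratios, same length as `ratios`.
#' @export
sliding_expression_sn <- function(ratios, window = 21L) {
  stopifnot(all(ratios > 0), window >= 1L)
  centered_ma(log2(ratios), window)
}
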