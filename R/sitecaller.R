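# Kernel-density classification of crosslink conversion signal within read
# groups, and extension/merging of signal runs into interaction sites.
#
# Within a read group of length L, conversion (T=>C) and non-conversion
# (T read as T) event counts x_TC(i), x_TT(i) are tallied per offset
# i in 1..L. Each class is smoothed with a Gaussian kernel of scale lambda
# and normalised to a density over offsets; positions where the conversion
# density exceeds the non-conversion density at sufficient read depth are the
# site cores. Offsets run in genome orientation (i = 1 at group start);
# "transcript T" means reference T on '+' groups and reference A on '-'
# groups. The kernel contrast itself is orientation-symmetric.

#' Tally the conversion profile of a read group
#'
#' @param reads classified reads of one group (same chrom/strand; columns as
#'   produced by [classify_reads()]).
#' @param genome named `DNAStringSet` or character vector.
#' @param gstart,gend optional group span (0-based half-open); defaults to the
#'   span of `reads`.
#' @return list of class `conversion_profile` with `L`, `chrom`, `strand`,
#'   `start`, per-offset `x_tc`, `x_tt`, `depth`, logical `is_t` (transcript-T
#'   reference positions), totals `n_tc`, `n_tt`.
#' @export
build_profile <- function(reads, genome, gstart = NULL, gend = NULL) {
  if (nrow(reads) == 0L) stop("empty read group")
  chrom <- reads$chrom[1]
  strand <- reads$strand[1]
  stopifnot(all(reads$chrom == chrom), all(reads$strand == strand))
  if (is.null(gstart)) gstart <- min(reads$start)
  if (is.null(gend)) gend <- max(reads$end)
  L <- gend - gstart
  ref <- str_chars(ref_seq(genome, chrom, gstart, gend))
  t_base <- if (strand == "+") "T" else "A"
  c_base <- if (strand == "+") "C" else "G"
  is_t <- ref == t_base

  depth <- integer(L)
  x_tc <- integer(L)
  x_tt <- integer(L)
  for (i in seq_len(nrow(reads))) {
    lo <- reads$start[i] - gstart + 1L
    hi <- reads$end[i] - gstart
    depth[lo:hi] <- depth[lo:hi] + 1L
    obs <- str_chars(dna_norm(reads$seq[i]))
    span <- lo:hi
    tt <- span[is_t[span] & obs == t_base]
    tc <- span[is_t[span] & obs == c_base]
    x_tt[tt] <- x_tt[tt] + 1L
    x_tc[tc] <- x_tc[tc] + 1L
  }
  structure(list(L = L, chrom = chrom, strand = strand, start = gstart,
                 x_tc = x_tc, x_tt = x_tt, depth = depth, is_t = is_t,
                 n_tc = sum(x_tc), n_tt = sum(x_tt)),
            class = "conversion_profile")
}

#' Gaussian kernel density estimates of conversion and non-conversion signal
#'
#' Each class c computes f_c(j) = sum_i x_c(i)/n_c * exp(-(i-j)^2/(2*lambda^2))
#' at integer offsets j = 1..L and normalises to k_c(j) = f_c(j)/sum_j f_c(j).
#' Any constant kernel prefactor cancels in the normalisation. A class with
#' zero events yields an all-zero density.
#'
#' @param profile a `conversion_profile`.
#' @param lambda Gaussian kernel scale in nucleotides (default 3).
#' @return list of class `density_estimate` with `lambda`, `k_tc`, `k_tt`.
#' @export
estimate_densities <- function(profile, lambda = 3) {
  L <- profile$L
  if (L == 0L) stop("zero-length profile")
  j <- seq_len(L)
  kern <- exp(-outer(j, j, `-`)^2 / (2 * lambda^2))
  smooth <- function(x, n) {
    if (n == 0L) return(numeric(L))
    f <- as.numeric(kern %*% (x / n))
    f / sum(f)
  }
  structure(list(lambda = lambda,
                 k_tc = smooth(profile$x_tc, profile$n_tc),
                 k_tt = smooth(profile$x_tt, profile$n_tt)),
            class = "density_estimate")
}

#' Classify group offsets as interaction-site signal
#'
#' An offset j is signal iff depth(j) >= `min_depth` and the conversion
#' density strictly exceeds the non-conversion density. In the degenerate
#' case of zero non-conversion events every depth-qualified offset is signal
#' (the k_TT -> 0 limit); ties are classified background.
#'
#' @param profile a `conversion_profile`.
#' @param densities matching `density_estimate`.
#' @param min_depth minimum read depth (default 5).
#' @return integer vector of signal offsets (1-based within the group).
#' @export
classify_positions <- function(profile, densities, min_depth = 5L) {
  ok <- profile$depth >= min_depth
  sig <- if (profile$n_tt == 0L) ok else ok & (densities$k_tc > densities$k_tt)
  which(sig)
}

#' Extend a core signal run into an interaction-site span
#'
#' `fixed5` grows the span by up to `max_extension` nucleotides on each side,
#' stopping where read depth drops below `min_depth`. `by_read` grows the
#' span to the most distal ends of conversion-bearing reads that overlap the
#' core by at least one nucleotide, scanning outward from the core and
#' truncating at the first offset where depth falls below `min_depth`
#' (single pass; reads recruited by the extension itself do not extend
#' further).
#'
#' @param core integer vector `c(first, last)` offsets of a contiguous signal
#'   run (1-based within the group).
#' @param profile the group's `conversion_profile`.
#' @param reads the group's classified reads (needed for `by_read`).
#' @param mode `"fixed5"` or `"by_read"`.
#' @param min_depth depth floor maintained during extension (default 5).
#' @param max_extension maximum per-side extension for `fixed5` (default 5).
#' @return `c(first, last)` offsets of the extended span.
#' @export
extend_site <- function(core, profile, reads = NULL,
                        mode = c("fixed5", "by_read"),
                        min_depth = 5L, max_extension = 5L) {
  mode <- match.arg(mode)
  a <- core[1]; b <- core[2]
  stopifnot(a >= 1L, b <= profile$L, a <= b)
  if (mode == "fixed5") {
    lo_lim <- max(1L, a - max_extension)
    hi_lim <- min(profile$L, b + max_extension)
  } else {
    if (is.null(reads)) stop("by_read extension needs the group's reads")
    core_g <- c(profile$start + a - 1L, profile$start + b)  # 0-based half-open
    conv <- reads$n_conversion > 0 &
      reads$start < core_g[2] & reads$end > core_g[1]
    if (any(conv)) {
      lo_lim <- max(1L, min(reads$start[conv]) - profile$start + 1L)
      hi_lim <- min(profile$L, max(reads$end[conv]) - profile$start)
    } else {
      lo_lim <- a; hi_lim <- b
    }
  }
  lo <- a
  while (lo > lo_lim && profile$depth[lo - 1L] >= min_depth) lo <- lo - 1L
  hi <- b
  while (hi < hi_lim && profile$depth[hi + 1L] >= min_depth) hi <- hi + 1L
  c(lo, hi)
}

#' Merge overlapping extended spans and recompute site statistics
#'
#' Spans overlapping by at least one nucleotide are combined into a single
#' interaction site; conversion counts, read counts and evidence are
#' recomputed on the merged span.
#'
#' @param spans list of `c(first, last)` offset pairs within one group.
#' @param profile the group's `conversion_profile`.
#' @param reads the group's classified reads.
#' @param extension_mode label recorded on the output.
#' @param evidence `"conversions"` (log2 of T=>C event count) or `"reads"`
#'   (log2 of read count, for CLIP-seq style input).
#' @return data.frame of interaction sites (0-based half-open genome
#'   coordinates).
#' @export
merge_sites <- function(spans, profile, reads, extension_mode = "fixed5",
                        evidence = c("conversions", "reads")) {
  evidence <- match.arg(evidence)
  if (length(spans) == 0L) return(empty_sites())
  ir <- IRanges(vapply(spans, `[`, numeric(1), 1),
                vapply(spans, `[`, numeric(1), 2))
  merged <- reduce(ir, min.gapwidth = 0L)
  out <- lapply(seq_along(merged), function(k) {
    lo <- start(merged)[k]; hi <- end(merged)[k]
    gstart <- profile$start + lo - 1L
    gend <- profile$start + hi
    n_conv <- sum(profile$x_tc[lo:hi])
    n_locs <- sum(profile$x_tc[lo:hi] > 0L)
    n_reads <- sum(reads$start < gend & reads$end > gstart)
    ev <- if (evidence == "conversions") log2(n_conv) else log2(n_reads)
    data.frame(chrom = profile$chrom, strand = profile$strand,
               start = gstart, end = gend, n_reads = n_reads,
               n_conversions = n_conv, n_conversion_locations = n_locs,
               evidence = ev, extension_mode = extension_mode,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @noRd
empty_sites <- function() {
  data.frame(chrom = character(0), strand = character(0),
             start = integer(0), end = integer(0), n_reads = integer(0),
             n_conversions = integer(0), n_conversion_locations = integer(0),
             evidence = numeric(0), extension_mode = character(0),
             stringsAsFactors = FALSE)
}

#' Call interaction sites from classified reads
#'
#' The full caller: group reads, keep groups with at least `min_reads` reads
#' and `min_conversion_locations` distinct conversion offsets, estimate the
#' class densities, classify offsets, split signal into maximal runs, extend
#' each run, merge overlapping spans, and (optionally) annotate. A group may
#' yield several sites. Setting `min_depth = 1` gives the relaxed variant
#' that requires five reads per group but no per-position depth floor.
#'
#' @param reads classified reads data.frame (from [classify_reads()]; a
#'   `group_id` column from [build_read_groups()] is added if absent).
#' @param genome named `DNAStringSet` or character vector.
#' @param mode extension strategy, `"fixed5"` or `"by_read"`.
#' @param min_reads minimum reads per group (default 5).
#' @param min_conversion_locations minimum distinct T=>C offsets per group
#'   (default 2).
#' @param min_depth per-position depth floor (default 5).
#' @param lambda kernel scale in nucleotides (default 3).
#' @param max_extension per-side extension for `fixed5` mode (default 5).
#' @param evidence site evidence definition, see [merge_sites()].
#' @param annotation optional `annotation_model`; adds `annotation` and
#'   `repeat_flag` columns.
#' @return data.frame of interaction sites with a `group_id` column.
#' @export
call_sites <- function(reads, genome, mode = c("fixed5", "by_read"),
                       min_reads = 5L, min_conversion_locations = 2L,
                       min_depth = 5L, lambda = 3, max_extension = 5L,
                       evidence = c("conversions", "reads"),
                       annotation = NULL) {
  mode <- match.arg(mode)
  evidence <- match.arg(evidence)
  if (!"group_id" %in% names(reads)) {
    reads <- build_read_groups(reads)$reads
  }
  sites <- lapply(split(reads, reads$group_id), function(grp) {
    if (nrow(grp) < min_reads) return(NULL)
    n_locs <- length(unique(unlist(grp$conv_offsets)))
    if (n_locs < min_conversion_locations) return(NULL)
    prof <- build_profile(grp, genome)
    dens <- estimate_densities(prof, lambda)
    sig <- classify_positions(prof, dens, min_depth)
    runs <- int_runs(sig)
    if (length(runs) == 0L) return(NULL)
    spans <- lapply(runs, function(r) {
      extend_site(range(r), prof, grp, mode, min_depth, max_extension)
    })
    out <- merge_sites(spans, prof, grp, extension_mode = mode,
                       evidence = evidence)
    out <- out[out$n_conversions >= 1L, , drop = FALSE]
    if (nrow(out) == 0L) return(NULL)
    out$group_id <- grp$group_id[1]
    out
  })
  sites <- do.call(rbind, sites)
  if (is.null(sites)) {
    sites <- cbind(empty_sites(), group_id = integer(0))
  }
  rownames(sites) <- NULL
  if (!is.null(annotation) && nrow(sites) > 0L) {
    ann <- annotate_interval(sites$chrom, sites$strand, sites$start,
                             sites$end, annotation)
    sites <- cbind(sites, ann)
  }
  sites
}

#' Crosslink-centered regions (41-nt baseline)
#'
#' Baseline comparator: for every read group with at least one conversion, a
#' fixed-width window re-centered on the group offset with the highest
#' fraction of conversion events (ties broken by the leftmost offset). Used
#' only for benchmarking against the kernel-density caller.
#'
#' @param reads classified reads (grouped if a `group_id` column is present).
#' @param genome named `DNAStringSet` or character vector.
#' @param width window width in nucleotides (default 41).
#' @param min_reads minimum reads per group (default 1, as in the baseline).
#' @return data.frame of windows (0-based half-open), one per eligible group.
#' @export
ccr_regions <- function(reads, genome, width = 41L, min_reads = 1L) {
  if (!"group_id" %in% names(reads)) {
    reads <- build_read_groups(reads)$reads
  }
  half <- (width - 1L) %/% 2L
  out <- lapply(split(reads, reads$group_id), function(grp) {
    if (nrow(grp) < min_reads) return(NULL)
    prof <- build_profile(grp, genome)
    tot <- prof$x_tc + prof$x_tt
    frac <- ifelse(tot > 0L, prof$x_tc / pmax(tot, 1L), 0)
    if (all(prof$x_tc == 0L)) return(NULL)
    center <- which.max(frac)  # leftmost maximum
    cg <- prof$start + center - 1L
    chrom_len <- if (is.character(genome)) nchar(genome[[prof$chrom]])
                 else width(genome[[prof$chrom]])
    s <- max(0L, cg - half)
    e <- min(chrom_len, s + width)
    s <- max(0L, e - width)
    data.frame(chrom = prof$chrom, strand = prof$strand, start = s, end = e,
               group_id = grp$group_id[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      group_id = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
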