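# Fixture builders and independent oracles shared across test files.

# A read row in the aligned-reads layout; seq defaults to the reference
# (mismatch-free) and can be modified by the caller.
make_read <- function(genome, chrom, start, end, strand = "+",
                      read_id = "r1", seq = NULL, n_loc = 1L) {
  if (is.null(seq)) {
    seq <- substr(genome[[chrom]], start + 1L, end)
  }
  data.frame(read_id = read_id, chrom = chrom, strand = strand,
             start = start, end = end, seq = seq, n_loc = n_loc,
             stringsAsFactors = FALSE)
}

# Substitute one base of a read (1-based offset within the read).
mutate_read <- function(read, offset, base) {
  substr(read$seq, offset, offset) <- base
  read
}

random_genome <- function(chroms, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  setNames(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1)), chroms)
}

# Brute-force connected components of the >=1-nt-overlap relation
# (union-find over all read pairs), strand- and chromosome-separated.
oracle_groups <- function(reads) {
  n <- nrow(reads)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      same <- reads$chrom[i] == reads$chrom[j] &&
        reads$strand[i] == reads$strand[j]
      overlap <- reads$start[i] < reads$end[j] &&
        reads$start[j] < reads$end[i]
      if (same && overlap) parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Random conversion profile honouring the container invariants: events only
# at transcript-T offsets, x_tc + x_tt <= depth, at least one conversion.
random_profile <- function(L = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(L)) L <- sample(5:200, 1)
  is_t <- runif(L) < 0.3
  if (!any(is_t)) is_t[sample(L, 1)] <- TRUE
  x_tc <- ifelse(is_t, rpois(L, 0.5), 0L)
  x_tt <- ifelse(is_t, rpois(L, 2), 0L)
  if (sum(x_tc) == 0) x_tc[which(is_t)[1]] <- 1L
  depth <- x_tc + x_tt + rpois(L, 3)
  structure(list(L = L, chrom = "chrT", strand = "+", start = 0L,
                 x_tc = as.integer(x_tc), x_tt = as.integer(x_tt),
                 depth = as.integer(depth), is_t = is_t,
                 n_tc = sum(x_tc), n_tt = sum(x_tt)),
            class = "conversion_profile")
}

# Independent evaluation of the density classifier with naive double loops:
# Gaussian-smoothed class frequencies, normalised, strict-inequality signal
# at depth-qualified offsets.
oracle_classify <- function(profile, lambda = 3, min_depth = 5L) {
  L <- profile$L
  smooth <- function(x, n) {
    f <- numeric(L)
    for (j in 1:L) {
      acc <- 0
      for (i in 1:L) {
        acc <- acc + x[i] / n * exp(-(i - j)^2 / (2 * lambda^2))
      }
      f[j] <- acc
    }
    f / sum(f)
  }
  if (profile$n_tt == 0L) {
    return(which(profile$depth >= min_depth))
  }
  k_tc <- smooth(profile$x_tc, profile$n_tc)
  k_tt <- smooth(profile$x_tt, profile$n_tt)
  which(profile$depth >= min_depth & k_tc > k_tt)
}

# Agreement between a discovered motif and the planted pattern: best over
# all alignments of the count of planted positions at which the discovered
# motif carries a matching non-degenerate symbol.
motif_plant_agreement <- function(found, planted) {
  f <- strsplit(found, "")[[1]]
  p <- strsplit(planted, "")[[1]]
  classes <- parclip:::IUPAC_CLASSES
  best <- 0L
  for (off in (-length(f) + 1L):(length(p) - 1L)) {
    agree <- 0L
    for (k in seq_along(p)) {
      fk <- k + off
      if (fk < 1L || fk > length(f)) next
      sym <- f[fk]
      if (sym %in% c("A", "C", "G", "T") &&
          sym %in% classes[[p[k]]]) {
        agree <- agree + 1L
      }
    }
    best <- max(best, agree)
  }
  best
}

# Tiny annotation model on one chromosome for priority tests.
tiny_annotation <- function() {
  annotation_model(
    utr3 = parclip:::gr0("chr1", 100L, 200L, "+"),
    cds = parclip:::gr0("chr1", 150L, 300L, "+"),
    utr5 = parclip:::gr0("chr1", 300L, 350L, "+"),
    intron = parclip:::gr0("chr1", 400L, 500L, "+"),
    repeats = parclip:::gr0("chr1", 450L, 520L))
}
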