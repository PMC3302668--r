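# IUPAC motif scanning, miRNA seed-match definitions and non-redundant seed
# assignment, and composition / conversion-likelihood profiles around matches.
#
# All scanning is on transcript-sense sequence: regions on the genomic '-'
# strand must be reverse-complemented before matching (see region_sequences()).

#' Built-in RBP motif presets
#'
#' Known binding motifs usable as scanning presets: Pumilio2 (`PUM2`),
#' Quaking (`QKI`, two motifs) and IGF2BP1 (two motifs).
#'
#' @return named list of character vectors of IUPAC patterns.
#' @export
motif_presets <- function() {
  list(PUM2 = "UGUANAUA",
       QKI = c("AUUAAY", "ACUAAY"),
       IGF2BP1 = c("CAUU", "CUUU"))
}

#' Scan a sequence for matches to a degenerate IUPAC motif
#'
#' Finds all (possibly overlapping) offsets where every motif symbol's
#' degeneracy class contains the sequence base. T and U are equivalent.
#'
#' @param sequence transcript-sense nucleotide string.
#' @param motif IUPAC pattern (alphabet A,C,G,T/U,W,S,K,M,R,Y,B,D,H,V,N).
#' @return integer vector of 1-based match start offsets.
#' @export
iupac_scan <- function(sequence, motif) {
  motif <- dna_norm(motif)
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_CLASSES), collapse = "")),
            motif)) {
    stop("invalid IUPAC symbol in motif: ", motif)
  }
  sequence <- dna_norm(sequence)
  if (nchar(sequence) < nchar(motif)) return(integer(0))
  m <- matchPattern(DNAString(motif), DNAString(sequence), fixed = FALSE)
  as.integer(start(m))
}

#' Transcript-sense sequences of genomic regions
#'
#' @param regions data.frame with `chrom`, `strand`, `start`, `end`
#'   (0-based half-open).
#' @param genome named `DNAStringSet` or character vector.
#' @return character vector of sequences ('-' strand regions
#'   reverse-complemented).
#' @export
region_sequences <- function(regions, genome) {
  vapply(seq_len(nrow(regions)), function(i) {
    s <- ref_seq(genome, regions$chrom[i], regions$start[i], regions$end[i])
    if (regions$strand[i] == "-") revcomp(s) else s
  }, character(1))
}

SEED_TYPES <- c("8mer-m1", "8mer-A1", "7mer-m1", "7mer-A1", "7mer-m8",
                "6mer2-7", "6mer3-8")

#' Canonical seed-match site patterns of a miRNA
#'
#' Derives the seven canonical seed-match types from the miRNA 5' end, as
#' mRNA-sense site patterns: `8mer-m1` pairs miRNA nucleotides 1-8; `8mer-A1`
#' pairs nucleotides 2-8 with an A opposite position 1 (the site's 3'-most
#' base); `7mer-m1`/`7mer-A1` analogously for nucleotides 1-7 / 2-7 + A;
#' `7mer-m8` pairs nucleotides 2-8; `6mer2-7` nucleotides 2-7 and `6mer3-8`
#' nucleotides 3-8. The order of the returned rows is the match-preference
#' order (longest first).
#'
#' @param mirna_sequence mature miRNA sequence, 5' to 3' (RNA or DNA).
#' @return data.frame with `seed_type`, `site_pattern` (DNA alphabet) and
#'   `length`.
#' @export
seed_sites <- function(mirna_sequence) {
  m <- dna_norm(mirna_sequence)
  if (nchar(m) < 8L) stop("miRNA sequence must be at least 8 nt")
  sub <- function(i, j) substr(m, i, j)
  pats <- c(
    "8mer-m1" = revcomp(sub(1, 8)),
    "8mer-A1" = paste0(revcomp(sub(2, 8)), "A"),
    "7mer-m1" = revcomp(sub(1, 7)),
    "7mer-A1" = paste0(revcomp(sub(2, 7)), "A"),
    "7mer-m8" = revcomp(sub(2, 8)),
    "6mer2-7" = revcomp(sub(2, 7)),
    "6mer3-8" = revcomp(sub(3, 8))
  )
  data.frame(seed_type = SEED_TYPES, site_pattern = unname(pats),
             length = nchar(unname(pats)), stringsAsFactors = FALSE)
}

#' Non-redundant miRNA seed-match scan over a set of regions
#'
#' Seed matches are collected longest first, in the preference order
#' 8mer-m1, 8mer-A1, 7mer-m1, 7mer-A1, 7mer-m8, 6mer2-7, 6mer3-8; a shorter
#' or later match overlapping an already-accepted match in the same region is
#' suppressed. A site matched by several miRNAs is credited once, to the most
#' highly expressed one.
#'
#' @param regions character vector of transcript-sense sequences (names used
#'   as region ids; defaults to their index).
#' @param mirnas data.frame with `mirna_id`, `sequence` and `rank`
#'   (1 = most expressed).
#' @param top_n restrict to the `top_n` most expressed miRNAs (default 20).
#' @return data.frame with `region_id`, `mirna_id`, `seed_type`, `start`,
#'   `end` (1-based closed offsets within the region).
#' @export
nonredundant_seed_scan <- function(regions, mirnas, top_n = 20L) {
  if (is.null(names(regions))) names(regions) <- as.character(seq_along(regions))
  mirnas <- mirnas[order(mirnas$rank), , drop = FALSE]
  mirnas <- head(mirnas, top_n)
  defs <- do.call(rbind, lapply(seq_len(nrow(mirnas)), function(i) {
    cbind(seed_sites(mirnas$sequence[i]),
          mirna_id = mirnas$mirna_id[i], rank = mirnas$rank[i])
  }))
  # preference order: seed type first (longest to shortest), then expression
  defs <- defs[order(match(defs$seed_type, SEED_TYPES), defs$rank), ,
               drop = FALSE]
  out <- list()
  for (rid in names(regions)) {
    seqr <- dna_norm(regions[[rid]])
    taken <- logical(nchar(seqr))
    for (d in seq_len(nrow(defs))) {
      w <- defs$length[d]
      starts <- find_fixed(seqr, defs$site_pattern[d])
      for (s in starts) {
        span <- s:(s + w - 1L)
        if (any(taken[span])) next
        taken[span] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          region_id = rid, mirna_id = defs$mirna_id[d],
          seed_type = defs$seed_type[d], start = s, end = s + w - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(region_id = character(0), mirna_id = character(0),
                      seed_type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' All (overlapping) occurrences of a fixed pattern
#' @noRd
find_fixed <- function(sequence, pattern) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Nucleotide composition around motif matches
#'
#' Per-offset base frequencies relative to a uniform 0.25 background, with one
#' count per match location regardless of read depth.
#'
#' @param matches data.frame with `chrom`, `strand`, `start`, `end` (0-based
#'   half-open genome coordinates of each match).
#' @param genome named `DNAStringSet` or character vector.
#' @param flank flanking nucleotides collected on each side (default 5).
#' @return matrix (4 x offsets) of frequency ratios; offsets are labelled
#'   relative to the match start in transcript orientation.
#' @export
composition_profile <- function(matches, genome, flank = 5L) {
  wlen <- unique(matches$end - matches$start)
  if (length(wlen) != 1L) stop("matches must have equal length")
  n_off <- wlen + 2L * flank
  counts <- matrix(0L, nrow = 4, ncol = n_off,
                   dimnames = list(DNA_BASES, seq_len(n_off) - flank - 1L))
  for (i in seq_len(nrow(matches))) {
    win <- match_window(matches[i, ], genome, flank)
    if (is.null(win)) next
    b <- str_chars(win)
    for (k in seq_len(n_off)) {
      if (b[k] %in% DNA_BASES) counts[b[k], k] <- counts[b[k], k] + 1L
    }
  }
  tot <- colSums(counts)
  freq <- sweep(counts, 2, pmax(tot, 1L), "/")
  freq / 0.25
}

#' @noRd
match_window <- function(m, genome, flank) {
  chrom_len <- if (is.character(genome)) nchar(genome[[m$chrom]])
               else width(genome[[m$chrom]])
  s <- m$start - flank
  e <- m$end + flank
  if (s < 0L || e > chrom_len) return(NULL)
  seqw <- ref_seq(genome, m$chrom, s, e)
  if (m$strand == "-") revcomp(seqw) else seqw
}

#' Conversion likelihood around motif matches
#'
#' For each aligned offset around the matches (transcript orientation, offset
#' 0 = match start), the probability of a T=>C conversion given a reference T:
#' conversions / (conversions + non-conversions), pooled over all matches and
#' all overlapping reads. Offsets with no observed T coverage are `NA`.
#'
#' @inheritParams composition_profile
#' @param reads classified reads (from [classify_reads()]).
#' @param background_regions optional data.frame of regions (same layout as
#'   `matches`) over which the background conversion probability (all
#'   transcript-T positions) is computed.
#' @return list with `profile` (data.frame: offset, n_conversion,
#'   n_nonconversion, p_conversion) and `background` (scalar probability or
#'   NA).
#' @export
conversion_likelihood_profile <- function(matches, reads, genome, flank = 5L,
                                          background_regions = NULL) {
  wlen <- unique(matches$end - matches$start)
  if (length(wlen) != 1L) stop("matches must have equal length")
  n_off <- wlen + 2L * flank
  conv <- nonc <- integer(n_off)
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    tal <- tally_window(m$chrom, m$strand, m$start - flank, m$end + flank,
                        reads, genome)
    if (is.null(tal)) next
    conv <- conv + tal$x_tc
    nonc <- nonc + tal$x_tt
  }
  tot <- conv + nonc
  p <- ifelse(tot > 0L, conv / pmax(tot, 1L), NA_real_)
  bg <- NA_real_
  if (!is.null(background_regions)) {
    bc <- bn <- 0L
    for (i in seq_len(nrow(background_regions))) {
      r <- background_regions[i, ]
      tal <- tally_window(r$chrom, r$strand, r$start, r$end, reads, genome)
      if (is.null(tal)) next
      bc <- bc + sum(tal$x_tc)
      bn <- bn + sum(tal$x_tt)
    }
    if (bc + bn > 0L) bg <- bc / (bc + bn)
  }
  list(profile = data.frame(offset = seq_len(n_off) - flank - 1L,
                            n_conversion = conv, n_nonconversion = nonc,
                            p_conversion = p),
       background = bg)
}

#' Tally conversion / non-conversion events over a genomic window, oriented
#' transcript 5'->3'.
#' @noRd
tally_window <- function(chrom, strand, start, end, reads, genome) {
  chrom_len <- if (is.character(genome)) nchar(genome[[chrom]])
               else width(genome[[chrom]])
  if (start < 0L || end > chrom_len) return(NULL)
  sel <- reads[reads$chrom == chrom & reads$strand == strand &
                 reads$start < end & reads$end > start, , drop = FALSE]
  L <- end - start
  x_tc <- x_tt <- integer(L)
  if (nrow(sel) > 0L) {
    prof <- build_profile(sel, genome,
                          gstart = min(sel$start, start),
                          gend = max(sel$end, end))
    idx <- (start - prof$start + 1L):(end - prof$start)
    x_tc <- prof$x_tc[idx]
    x_tt <- prof$x_tt[idx]
  }
  if (strand == "-") {
    x_tc <- rev(x_tc); x_tt <- rev(x_tt)
  }
  list(x_tc = x_tc, x_tt = x_tt)
}
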