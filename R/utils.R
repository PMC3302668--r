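# Shared small helpers. Coordinates are 0-based half-open everywhere in this
# package (BED convention); GRanges conversions happen at the boundary.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy classes (DNA alphabet; U is normalised to T on input).
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
  R = c("A", "G"), Y = c("C", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' @noRd
dna_norm <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement of a DNA/RNA string
#' @noRd
revcomp <- function(x) {
  as.character(reverseComplement(DNAString(dna_norm(x))))
}

#' Split a string into single characters
#' @noRd
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Build a GRanges from 0-based half-open coordinates
#' @noRd
gr0 <- function(chrom, start, end, strand = "*") {
  GRanges(chrom, IRanges(start + 1L, end), strand = strand)
}

#' Extract reference sequence [start, end) (0-based half-open, plus strand)
#'
#' @param genome named `DNAStringSet` (or named character vector) of reference
#'   sequences.
#' @noRd
ref_seq <- function(genome, chrom, start, end) {
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
    return(substr(genome[[chrom]], start + 1L, end))
  }
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  as.character(subseq(genome[[chrom]], start + 1L, end))
}

#' Maximal runs of consecutive integers
#' @return list of integer vectors
#' @noRd
int_runs <- function(x) {
  if (length(x) == 0L) return(list())
  x <- sort(unique(x))
  grp <- cumsum(c(1L, diff(x) != 1L))
  unname(split(x, grp))
}

#' Centered moving average with partial windows at the edges
#' @noRd
centered_ma <- function(y, window) {
  n <- length(y)
  if (window >= n) return(rep(mean(y), n))
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}
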