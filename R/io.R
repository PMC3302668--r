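# SAM/BAM and tabular I/O. SAM/BAM parsing goes through Rsamtools; mismatch
# information is derived by comparing read sequences with the reference
# FASTA, so no MD tag is required on input (one is written on output).

#' Read aligned PAR-CLIP reads from a SAM or BAM file
#'
#' Reads ungapped primary alignments into the aligned-reads layout. Gapped
#' (non single-M CIGAR) alignments are rejected: the supported mapping mode
#' is mismatch-only. The number of candidate locations is taken from the NH
#' tag when present (1 otherwise).
#'
#' @param path SAM or BAM file.
#' @return data.frame in the aligned-reads layout (see [classify_reads()]).
#' @export
read_parclip_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0L) {
    return(data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), seq = character(0),
                      n_loc = integer(0), stringsAsFactors = FALSE))
  }
  ungapped <- grepl("^[0-9]+M$", b$cigar)
  if (any(!ungapped)) {
    warning(sum(!ungapped), " gapped alignment(s) rejected")
  }
  nh <- b$tag$NH
  if (is.null(nh)) nh <- rep(1L, n)
  nh[is.na(nh)] <- 1L
  seqs <- as.character(b$seq)
  out <- data.frame(
    read_id = b$qname,
    chrom = as.character(b$rname),
    strand = ifelse(bitwAnd(b$flag, 16L) > 0L, "-", "+"),
    start = b$pos - 1L,
    end = b$pos - 1L + nchar(seqs),
    seq = seqs,
    n_loc = as.integer(nh),
    stringsAsFactors = FALSE)
  out[ungapped, , drop = FALSE]
}

#' Write aligned reads as a SAM file
#'
#' Emits already-mapped, ungapped records with NM and MD tags computed
#' against the reference, and an NH tag with the candidate location count.
#'
#' @param reads data.frame in the aligned-reads layout.
#' @param genome named `DNAStringSet` or character vector.
#' @param path output SAM path.
#' @export
write_sam <- function(reads, genome, path) {
  chrom_len <- function(ch) {
    if (is.character(genome)) nchar(genome[[ch]]) else width(genome[[ch]])
  }
  chroms <- names(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           vapply(chroms, function(ch) {
             sprintf("@SQ\tSN:%s\tLN:%d", ch, chrom_len(ch))
           }, character(1)))
  recs <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    ref <- str_chars(ref_seq(genome, r$chrom, r$start, r$end))
    obs <- str_chars(dna_norm(r$seq))
    mm <- which(ref != obs)
    md <- md_tag(ref, mm)
    len <- r$end - r$start
    paste(r$read_id, if (r$strand == "-") 16L else 0L, r$chrom,
          r$start + 1L, 255L, sprintf("%dM", len), "*", 0L, 0L,
          r$seq, paste(rep("I", len), collapse = ""),
          sprintf("NM:i:%d", length(mm)), sprintf("MD:Z:%s", md),
          sprintf("NH:i:%d", r$n_loc), sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' @noRd
md_tag <- function(ref, mm) {
  if (length(mm) == 0L) return(as.character(length(ref)))
  parts <- character(0)
  prev <- 0L
  for (p in mm) {
    parts <- c(parts, as.character(p - prev - 1L), ref[p])
    prev <- p
  }
  paste0(paste(parts, collapse = ""), length(ref) - prev)
}

#' Write a genome as FASTA
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) {
    genome <- DNAStringSet(genome)
  }
  writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @export
read_genome_fasta <- function(path) {
  dss <- readDNAStringSet(path)
  setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
}

#' Write interaction sites as BED6 plus a statistics TSV
#'
#' The BED score is the site evidence scaled to 0-1000 across the set.
#'
#' @param sites data.frame from [call_sites()].
#' @param bed_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_sites <- function(sites, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    ev <- sites$evidence
    score <- if (nrow(sites) == 0L || diff(range(ev)) == 0) {
      rep(0L, nrow(sites))
    } else {
      as.integer(round(1000 * (ev - min(ev)) / diff(range(ev))))
    }
    bed <- data.frame(sites$chrom, sites$start, sites$end,
                      sprintf("site_%d", seq_len(nrow(sites))), score,
                      sites$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    write.table(sites, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(sites)
}

#' Write a simulated library to disk (FASTA, annotation BED, SAM, truth TSV)
#'
#' @param reference output of [simulate_reference()].
#' @param reads output of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(reference, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(reference$genome, file.path(dir, "genome.fa"))
  ann <- reference$annotation_table
  key <- c(utr3 = "utr3", cds = "cds", utr5 = "utr5", intron = "intron")
  bed <- data.frame(ann$chrom, ann$start, ann$end, key[ann$category], 0L,
                    ann$strand)
  write.table(bed, file.path(dir, "annotation.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_sam(reads, reference$genome, file.path(dir, "reads.sam"))
  write.table(reference$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
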