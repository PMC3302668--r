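# Read preprocessing, mismatch classification, unique-location selection and
# read grouping.
#
# Aligned reads are held in a plain data.frame ("aligned reads" layout) with
# columns: read_id, chrom, strand ("+"/"-"), start, end (0-based half-open,
# reference coordinates), seq (aligned sequence in plus-strand orientation, as
# in SAM), n_loc (number of candidate alignment locations reported by the
# aligner). classify_reads() adds n_conversion, n_other and a conv_offsets
# list-column with 0-based reference offsets of T=>C conversions.

#' Strip 3' adapters and filter raw reads
#'
#' Removes the 3' sequencing adapter from each raw read and discards reads
#' that end up shorter than `min_len` or contain an ambiguous nucleotide.
#' The adapter is located as the leftmost position where the read suffix
#' matches a prefix of the adapter: either the full adapter occurs inside the
#' read, or a read-terminal suffix matches at least `min_overlap` leading
#' adapter bases.
#'
#' @param raw_reads character vector of raw read sequences (ACGTN, or RNA
#'   with U).
#' @param adapter adapter sequence to strip from the 3' end.
#' @param min_len minimum retained read length (default 13 nt).
#' @param min_overlap minimum read-terminal overlap with the adapter prefix
#'   for a partial match to trigger clipping (default 7 nt).
#' @return A list with `reads` (retained insert sequences), and discard
#'   counts `n_short`, `n_ambiguous`, `n_invalid`.
#' @export
preprocess_reads <- function(raw_reads, adapter, min_len = 13L,
                             min_overlap = 7L) {
  stopifnot(nchar(adapter) >= 1L, min_len >= 1L)
  adapter <- dna_norm(adapter)
  n_short <- n_ambig <- n_invalid <- 0L
  out <- character(0)
  for (r in raw_reads) {
    r <- dna_norm(r)
    if (grepl("[^ACGTN]", r)) {
      n_invalid <- n_invalid + 1L
      next
    }
    r <- strip_adapter(r, adapter, min_overlap)
    if (nchar(r) < min_len) {
      n_short <- n_short + 1L
    } else if (grepl("N", r, fixed = TRUE)) {
      n_ambig <- n_ambig + 1L
    } else {
      out <- c(out, r)
    }
  }
  list(reads = out, n_short = n_short, n_ambiguous = n_ambig,
       n_invalid = n_invalid)
}

#' @noRd
strip_adapter <- function(read, adapter, min_overlap) {
  n <- nchar(read)
  alen <- nchar(adapter)
  for (p in seq_len(n)) {
    m <- min(n - p + 1L, alen)
    # full adapter inside the read, or terminal suffix >= min_overlap
    if (m < alen && m < min_overlap) next
    if (substr(read, p, p + m - 1L) == substr(adapter, 1L, m)) {
      return(substr(read, 1L, p - 1L))
    }
  }
  read
}

#' Classify the mismatches of one aligned read
#'
#' A mismatch counts as a crosslink conversion iff, in transcript orientation,
#' the reference base is T and the read base is C. On '-' strand alignments
#' this appears as reference A => read G in plus-strand (SAM) orientation.
#'
#' @param read single-row data.frame (or list) with `chrom`, `strand`,
#'   `start`, `end`, `seq` in the aligned-reads layout.
#' @param genome named `DNAStringSet` or character vector of reference
#'   sequences.
#' @param mismatches optional data.frame with `ref_offset`, `ref_base`,
#'   `read_base` (plus-strand bases) as reported by the aligner. When given,
#'   each `ref_base` is validated against the reference and a disagreement is
#'   an error; when omitted, mismatches are derived by direct comparison of
#'   `seq` with the reference (ungapped alignments).
#' @return list with `n_conversion`, `n_other`, `conv_offsets` (0-based
#'   reference offsets of the conversions).
#' @export
classify_mismatches <- function(read, genome, mismatches = NULL) {
  ref <- str_chars(ref_seq(genome, read$chrom, read$start, read$end))
  obs <- str_chars(dna_norm(read$seq))
  if (length(ref) != length(obs)) {
    stop("read length does not match its reference span (gapped alignment?)")
  }
  if (!is.null(mismatches)) {
    off <- mismatches$ref_offset - read$start + 1L
    if (any(off < 1L | off > length(ref))) {
      stop("mismatch offset outside the alignment span")
    }
    if (any(toupper(mismatches$ref_base) != ref[off])) {
      stop("stated ref_base disagrees with the reference sequence")
    }
    mm_idx <- off
    read_base <- toupper(mismatches$read_base)
  } else {
    mm_idx <- which(ref != obs)
    read_base <- obs[mm_idx]
  }
  conv <- if (read$strand == "+") {
    ref[mm_idx] == "T" & read_base == "C"
  } else {
    ref[mm_idx] == "A" & read_base == "G"
  }
  list(n_conversion = sum(conv),
       n_other = sum(!conv),
       conv_offsets = read$start + mm_idx[conv] - 1L)
}

#' Classify mismatches for a whole table of aligned reads
#'
#' @param reads data.frame in the aligned-reads layout.
#' @inheritParams classify_mismatches
#' @return `reads` with added columns `n_conversion`, `n_other` and
#'   list-column `conv_offsets`.
#' @export
classify_reads <- function(reads, genome) {
  cls <- lapply(seq_len(nrow(reads)), function(i) {
    classify_mismatches(reads[i, , drop = FALSE], genome)
  })
  reads$n_conversion <- vapply(cls, `[[`, integer(1), "n_conversion")
  reads$n_other <- vapply(cls, `[[`, integer(1), "n_other")
  reads$conv_offsets <- lapply(cls, `[[`, "conv_offsets")
  reads
}

#' Select the unique usable alignment of one read
#'
#' A read is retained iff exactly one of its reported alignment locations has
#' zero non-conversion mismatches; reads whose aligner reported more than
#' `max_locations` candidate locations are dropped regardless.
#'
#' @param alignments data.frame of classified alignments for a single read
#'   (same `read_id`, columns `n_other`, `n_loc`).
#' @param max_locations maximum reported alignment locations (default 10).
#' @return A single-row data.frame, or NULL when the read is discarded.
#' @export
select_unique <- function(alignments, max_locations = 10L) {
  if (nrow(alignments) == 0L) return(NULL)
  stopifnot(length(unique(alignments$read_id)) == 1L)
  if (any(alignments$n_loc > max_locations)) return(NULL)
  clean <- which(alignments$n_other == 0L)
  if (length(clean) != 1L) return(NULL)
  alignments[clean, , drop = FALSE]
}

#' Filter a classified alignment table to uniquely-mapped clean reads
#'
#' Applies [select_unique()] per read_id.
#'
#' @inheritParams select_unique
#' @param reads classified alignment data.frame (possibly several rows per
#'   read_id).
#' @return data.frame of retained alignments, one row per retained read.
#' @export
filter_unique_reads <- function(reads, max_locations = 10L) {
  keep <- lapply(split(seq_len(nrow(reads)), reads$read_id), function(idx) {
    sel <- select_unique(reads[idx, , drop = FALSE], max_locations)
    if (is.null(sel)) NULL else sel
  })
  out <- do.call(rbind, keep)
  if (is.null(out)) out <- reads[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group overlapping reads into read groups
#'
#' Reads overlapping by at least one nucleotide (on the same chromosome and
#' strand) are joined into connected components; each component is a read
#' group, the unit of interaction-site calling. Grouping is strand-separated:
#' crosslink chemistry is transcript-strand specific.
#'
#' @param reads data.frame in the aligned-reads layout.
#' @return list with `reads` (input plus a `group_id` column) and `groups`
#'   (data.frame: group_id, chrom, strand, start, end, n_reads).
#' @export
build_read_groups <- function(reads) {
  if (nrow(reads) == 0L) {
    return(list(reads = cbind(reads, group_id = integer(0)),
                groups = data.frame(group_id = integer(0),
                                    chrom = character(0),
                                    strand = character(0),
                                    start = integer(0), end = integer(0),
                                    n_reads = integer(0))))
  }
  gr <- gr0(reads$chrom, reads$start, reads$end, reads$strand)
  # min.gapwidth = 0: merge only true overlaps, abutting reads stay separate
  comp <- reduce(gr, min.gapwidth = 0L)
  hit <- findOverlaps(gr, comp)
  stopifnot(length(hit) == nrow(reads))
  reads$group_id <- subjectHits(hit)
  groups <- data.frame(
    group_id = seq_along(comp),
    chrom = as.character(seqnames(comp)),
    strand = as.character(strand(comp)),
    start = start(comp) - 1L,
    end = end(comp),
    n_reads = as.integer(countOverlaps(comp, gr)),
    stringsAsFactors = FALSE
  )
  list(reads = reads, groups = groups)
}

#' Build an annotation model from per-category intervals
#'
#' @param utr3,cds,utr5,mirna,intron `GRanges` (or NULL) for each transcript
#'   category. Categories may overlap; the query-time priority is
#'   3' UTR > CDS > 5' UTR > miRNA > intron > intergenic.
#' @param repeats optional `GRanges` of repeat intervals (strand ignored).
#' @return object of class `annotation_model`.
#' @export
annotation_model <- function(utr3 = NULL, cds = NULL, utr5 = NULL,
                             mirna = NULL, intron = NULL, repeats = NULL) {
  cats <- list(`3' UTR` = utr3, CDS = cds, `5' UTR` = utr5,
               miRNA = mirna, intron = intron)
  structure(list(categories = cats, repeats = repeats),
            class = "annotation_model")
}

#' Read an annotation model from a 6-column category BED file
#'
#' The BED `name` column carries the category label: one of `3' UTR` (or
#' `utr3`), `CDS` (`cds`), `5' UTR` (`utr5`), `miRNA` (`mirna`), `intron`.
#'
#' @param path BED file path.
#' @param repeats_path optional BED of repeat intervals.
#' @return an `annotation_model`.
#' @export
read_annotation_bed <- function(path, repeats_path = NULL) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  colnames(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  key <- c("utr3" = "3' UTR", "3' utr" = "3' UTR", "cds" = "CDS",
           "utr5" = "5' UTR", "5' utr" = "5' UTR", "mirna" = "miRNA",
           "intron" = "intron")
  lab <- key[tolower(bed$name)]
  if (anyNA(lab)) stop("unknown annotation category: ",
                       paste(unique(bed$name[is.na(lab)]), collapse = ", "))
  mk <- function(cat) {
    sel <- bed[lab == cat, , drop = FALSE]
    if (nrow(sel) == 0L) return(NULL)
    gr0(sel$chrom, sel$start, sel$end, sel$strand)
  }
  reps <- NULL
  if (!is.null(repeats_path)) {
    rb <- read.table(repeats_path, sep = "\t", stringsAsFactors = FALSE)
    reps <- gr0(rb[[1]], rb[[2]], rb[[3]])
  }
  annotation_model(utr3 = mk("3' UTR"), cds = mk("CDS"), utr5 = mk("5' UTR"),
                   mirna = mk("miRNA"), intron = mk("intron"), repeats = reps)
}

#' Annotate a genomic interval by transcript category
#'
#' Returns the highest-priority category whose intervals overlap the query by
#' at least one nucleotide, in the order 3' UTR, CDS, 5' UTR, miRNA, intron;
#' `intergenic` when none overlaps. Category overlap is strand-aware; the
#' repeat flag ignores strand.
#'
#' @param chrom,strand,start,end query interval (0-based half-open). These may
#'   be vectors of equal length.
#' @param model an `annotation_model`.
#' @return data.frame with `annotation` and logical `repeat_flag`.
#' @export
annotate_interval <- function(chrom, strand, start, end, model) {
  stopifnot(inherits(model, "annotation_model"))
  known <- unique(unlist(lapply(c(model$categories, list(model$repeats)),
                                function(g) if (is.null(g)) NULL
                                else as.character(seqnames(g)))))
  bad <- !(chrom %in% known)
  if (any(bad)) {
    warning("query on unannotated chromosome(s): ",
            paste(unique(chrom[bad]), collapse = ", "),
            "; returning intergenic")
  }
  q <- gr0(chrom, start, end, strand)
  ann <- rep("intergenic", length(q))
  for (cat in rev(names(model$categories))) {  # low priority first, overwritten
    g <- model$categories[[cat]]
    if (is.null(g)) next
    # suppress seqlevel chatter for queries on unannotated chromosomes
    ann[suppressWarnings(countOverlaps(q, g)) > 0L] <- cat
  }
  rep_flag <- rep(FALSE, length(q))
  if (!is.null(model$repeats)) {
    rep_flag <- suppressWarnings(
      countOverlaps(q, model$repeats, ignore.strand = TRUE)) > 0L
  }
  data.frame(annotation = ann, repeat_flag = rep_flag,
             stringsAsFactors = FALSE)
}
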