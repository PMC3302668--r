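# Seeded generator of synthetic PAR-CLIP libraries: a reference with labelled
# transcript segments, planted crosslink sites (optionally motif- or
# seed-anchored), and aligned reads carrying T=>C conversions concentrated at
# the crosslink positions plus a low background conversion rate.
#
# Each transcript occupies its own chromosome, flanked by intergenic margins,
# on the '+' or '-' genomic strand; conversions are planted per read
# (independently crosslinked molecules), so per-position conversion fractions
# are binomial as the profile estimators assume.

#' Simulation configuration
#'
#' @param n_transcripts number of transcripts (one per chromosome).
#' @param utr5_len,cds_len,utr3_len,intron_len length ranges (min, max) of
#'   the transcript segments; `intron_len = c(0, 0)` omits the intron.
#' @param flank_len intergenic margin on each side of a transcript.
#' @param n_sites number of planted crosslink sites (at most one per
#'   transcript, in the `site_region` segment).
#' @param site_region segment carrying planted sites (default `"utr3"`).
#' @param mode `"rbp"` plants an IUPAC motif instance downstream of a T-rich
#'   crosslink triplet; `"ago"` plants a miRNA seed-match site with the
#'   crosslink T one nucleotide upstream of the seed and conversions
#'   forbidden inside the seed match (seed protection).
#' @param motif planted motif for `"rbp"` mode (IUPAC; default the Pumilio2
#'   consensus).
#' @param mirnas data.frame (`mirna_id`, `sequence`, `rank`) whose 8mer-m1
#'   sites are planted in `"ago"` mode.
#' @param crosslink_conversion_prob per-read conversion probability at
#'   crosslink-window Ts (default 0.5).
#' @param background_conversion_prob per-read conversion probability at all
#'   other covered Ts (default 0.001).
#' @param crosslink_window half-width (nt) of the crosslink window around the
#'   planted position (default 1; ignored in `"ago"` mode, where conversions
#'   concentrate on the single upstream T).
#' @param depth reads sampled per planted site (default 20).
#' @param read_len read length range (default 20-35 nt; down to 13 for
#'   lenient-mapping experiments).
#' @param background_reads_per_transcript uniformly placed non-site reads per
#'   transcript (default 10).
#' @param frac_minus fraction of transcripts on the genomic '-' strand
#'   (default 0.5).
#' @param rnase_G_bias when TRUE, fragment boundaries preferentially fall
#'   after reference Gs (default FALSE).
#' @param au_enrichment probability that each base of the 10-nt flanks
#'   around a planted site is redrawn from an AU-rich distribution
#'   (default 0, disabled).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 20L,
                       utr5_len = c(60L, 120L), cds_len = c(240L, 480L),
                       utr3_len = c(200L, 400L), intron_len = c(80L, 150L),
                       flank_len = 60L,
                       n_sites = 10L, site_region = "utr3",
                       mode = c("rbp", "ago"), motif = "UGUANAUA",
                       mirnas = NULL,
                       crosslink_conversion_prob = 0.5,
                       background_conversion_prob = 0.001,
                       crosslink_window = 1L,
                       depth = 20L, read_len = c(20L, 35L),
                       background_reads_per_transcript = 10L,
                       frac_minus = 0.5, rnase_G_bias = FALSE,
                       au_enrichment = 0) {
  mode <- match.arg(mode)
  stopifnot(crosslink_conversion_prob >= 0, crosslink_conversion_prob <= 1,
            background_conversion_prob >= 0, background_conversion_prob <= 1,
            crosslink_conversion_prob > background_conversion_prob,
            read_len[1] >= 13L, n_sites <= n_transcripts)
  if (mode == "ago" && is.null(mirnas)) {
    mirnas <- data.frame(mirna_id = "sim-mir-1",
                         sequence = "TAGCAGCACGTAAATATTGGCG", rank = 1L,
                         stringsAsFactors = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @noRd
rand_seq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                              collapse = "")

#' @noRd
rint <- function(range) {
  if (range[1] >= range[2]) range[1]
  else sample(range[1]:range[2], 1L)
}

#' Simulate a reference genome with annotation and planted sites
#'
#' Generates one chromosome per transcript with labelled 5' UTR / CDS /
#' intron / 3' UTR segments and intergenic flanks, plants crosslink sites
#' (with motif or seed-match anchors per the config mode) at recorded
#' positions, and returns the ground truth. Deterministic under `seed`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `genome` (named character vector, plus-strand),
#'   `annotation` (an `annotation_model`), `transcripts` (data.frame) and
#'   `truth` (data.frame: site_id, chrom, strand, crosslink_pos (0-based,
#'   genome), seed/motif anchor span and pattern).
#' @export
simulate_reference <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  site_tx <- sample(cfg$n_transcripts, cfg$n_sites)
  genome <- character(0)
  tx <- list(); ann <- list(); truth <- list()
  for (t in seq_len(cfg$n_transcripts)) {
    chrom <- sprintf("chr%02d", t)
    strand <- if (runif(1) < cfg$frac_minus) "-" else "+"
    l5 <- rint(cfg$utr5_len); lc <- rint(cfg$cds_len)
    li <- if (cfg$intron_len[2] > 0L) rint(cfg$intron_len) else 0L
    l3 <- rint(cfg$utr3_len)
    tx_len <- l5 + lc + li + l3
    seq_tx <- rand_seq(tx_len)  # transcript-sense (pre-mRNA incl. intron)

    # segment offsets within the transcript (transcript orientation)
    half_cds <- lc %/% 2L
    segs <- list(
      utr5 = c(0L, l5),
      cds = rbind(c(l5, l5 + half_cds),
                  c(l5 + half_cds + li, l5 + lc + li)),
      intron = if (li > 0L) c(l5 + half_cds, l5 + half_cds + li) else NULL,
      utr3 = c(l5 + lc + li, tx_len)
    )

    site <- NULL
    if (t %in% site_tx) {
      reg <- segs[[cfg$site_region]]
      if (is.matrix(reg)) reg <- reg[1, ]
      margin <- max(cfg$read_len[2], 40L)
      lo <- reg[1] + margin
      hi <- reg[2] - margin
      if (hi <= lo) stop("infeasible segment lengths for site planting")
      x <- lo + sample.int(hi - lo, 1L) - 1L  # crosslink offset (0-based, tx)
      seq_tx <- plant_site(seq_tx, x, cfg)
      site <- list(tx_offset = x)
    }

    # lay the transcript on the genome
    gstart <- cfg$flank_len
    gseq_tx <- paste0(rand_seq(cfg$flank_len), seq_tx,
                      rand_seq(cfg$flank_len))
    genome[chrom] <- if (strand == "-") revcomp(gseq_tx) else gseq_tx
    chrom_len <- nchar(gseq_tx)

    # map a transcript offset interval [a, b) to genome coordinates
    to_genome <- function(a, b) {
      if (strand == "+") c(gstart + a, gstart + b)
      else c(chrom_len - gstart - b, chrom_len - gstart - a)
    }
    for (cat in names(segs)) {
      sg <- segs[[cat]]
      if (is.null(sg)) next
      if (!is.matrix(sg)) sg <- matrix(sg, nrow = 1)
      for (r in seq_len(nrow(sg))) {
        g <- to_genome(sg[r, 1], sg[r, 2])
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = chrom, start = g[1], end = g[2], category = cat,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    tx[[t]] <- data.frame(chrom = chrom, strand = strand, start = gstart,
                          end = gstart + tx_len, tx_len = tx_len,
                          stringsAsFactors = FALSE)
    if (!is.null(site)) {
      x <- site$tx_offset
      gx <- to_genome(x, x + 1L)[1]
      anchor <- attr(seq_tx, "anchor")
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, strand = strand, tx_offset = x, crosslink_pos = gx,
        anchor_start = x + anchor[1], anchor_end = x + anchor[2],
        pattern = attr(seq_tx, "pattern"), stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, ann)
  model <- annotation_model(
    utr3 = ann_gr(ann, "utr3"), cds = ann_gr(ann, "cds"),
    utr5 = ann_gr(ann, "utr5"), intron = ann_gr(ann, "intron"))
  truth <- if (length(truth) > 0) {
    tdf <- do.call(rbind, truth)
    tdf$site_id <- seq_len(nrow(tdf))
    tdf
  } else {
    data.frame(chrom = character(0), strand = character(0),
               tx_offset = integer(0), crosslink_pos = integer(0),
               anchor_start = integer(0), anchor_end = integer(0),
               pattern = character(0), site_id = integer(0))
  }
  list(genome = genome, annotation = model,
       transcripts = do.call(rbind, tx), truth = truth,
       annotation_table = ann, config = cfg)
}

#' @noRd
ann_gr <- function(ann, cat) {
  sel <- ann[ann$category == cat, , drop = FALSE]
  if (nrow(sel) == 0L) return(NULL)
  gr0(sel$chrom, sel$start, sel$end, sel$strand)
}

#' Write the planted-site context into a transcript sequence
#'
#' rbp mode: a T-rich crosslink triplet at x-1..x+1 followed by a concrete
#' motif instance at x+2. ago mode: a crosslink T at x with the miRNA 8mer-m1
#' seed-match site at x+1..x+8 and AU-enriched flanks when configured.
#' Attributes `anchor` (offsets of the planted anchor relative to x, 0-based
#' half-open) and `pattern` record the plant.
#' @noRd
plant_site <- function(seq_tx, x, cfg) {
  chars <- str_chars(seq_tx)
  if (cfg$mode == "rbp") {
    chars[(x - 1L):(x + 1L) + 1L] <- c("T", "T", "T")
    inst <- sample(expand_iupac(dna_norm(cfg$motif)), 1L)
    w <- nchar(inst)
    chars[(x + 2L):(x + 1L + w) + 1L] <- str_chars(inst)
    anchor <- c(2L, 2L + w)
    pattern <- inst
  } else {
    mir <- cfg$mirnas[sample.int(nrow(cfg$mirnas), 1L), ]
    site8 <- seed_sites(mir$sequence)$site_pattern[1]  # 8mer-m1
    chars[x + 1L] <- "T"
    chars[(x + 1L):(x + 8L) + 1L] <- str_chars(site8)
    if (cfg$au_enrichment > 0) {
      fl <- c((x - 10L):(x - 1L), (x + 9L):(x + 18L)) + 1L
      fl <- fl[fl >= 1L & fl <= length(chars)]
      redraw <- runif(length(fl)) < cfg$au_enrichment
      chars[fl[redraw]] <- sample(c("A", "T"), sum(redraw), replace = TRUE)
      chars[x + 1L] <- "T"  # keep the crosslink T
    }
    anchor <- c(1L, 9L)
    pattern <- site8
  }
  out <- paste(chars, collapse = "")
  attr(out, "anchor") <- anchor
  attr(out, "pattern") <- pattern
  out
}

#' Simulate aligned PAR-CLIP reads from a reference
#'
#' Samples `depth` reads over each planted site (every read covers the
#' crosslink position) and uniform background reads over each transcript.
#' T=>C conversions are drawn per read: crosslink-window Ts convert with
#' `crosslink_conversion_prob`, all other covered transcript Ts with
#' `background_conversion_prob`; in `"ago"` mode positions inside the planted
#' seed match never convert. Reads map to the genomic strand of their
#' transcript and are returned as already-aligned records.
#'
#' @param reference output of [simulate_reference()].
#' @param seed RNG seed.
#' @return data.frame in the aligned-reads layout ([classify_reads()] input).
#' @export
simulate_reads <- function(reference, seed = 1L) {
  set.seed(seed + 1L)
  cfg <- reference$config
  tx <- reference$transcripts
  reads <- list()
  rid <- 0L

  emit <- function(chrom, strand, tx_start_g, tx_len, tx_seq, s, len,
                   hot, protected) {
    # s: transcript-sense read start (0-based within transcript)
    rid <<- rid + 1L
    span <- (s + 1L):(s + len)
    bases <- str_chars(substr(tx_seq, s + 1L, s + len))
    is_t <- bases == "T"
    p <- ifelse((span - 1L) %in% hot, cfg$crosslink_conversion_prob,
                cfg$background_conversion_prob)
    conv <- is_t & !(span - 1L) %in% protected & runif(len) < p
    bases[conv] <- "C"
    rseq <- paste(bases, collapse = "")
    if (strand == "+") {
      gs <- tx_start_g + s
      list(read_id = sprintf("r%06d", rid), chrom = chrom, strand = strand,
           start = gs, end = gs + len, seq = rseq, n_loc = 1L)
    } else {
      chrom_len <- nchar(reference$genome[[chrom]])
      ge <- chrom_len - (tx_start_g - cfg$flank_len) - cfg$flank_len - s
      list(read_id = sprintf("r%06d", rid), chrom = chrom, strand = strand,
           start = ge - len, end = ge, seq = revcomp(rseq), n_loc = 1L)
    }
  }

  pick_start <- function(tx_seq, lo, hi, len) {
    # candidate transcript-sense starts in [lo, hi]; with RNase-G bias,
    # starts preceded by a G are upweighted (cleavage next to Gs)
    cand <- lo:hi
    if (!cfg$rnase_G_bias || length(cand) == 1L) {
      return(cand[sample.int(length(cand), 1L)])
    }
    prev <- ifelse(cand >= 1L,
                   substring(tx_seq, cand, cand), "")
    w <- ifelse(prev == "G", 4, 1)
    cand[sample.int(length(cand), 1L, prob = w)]
  }

  for (t in seq_len(nrow(tx))) {
    chrom <- tx$chrom[t]; strand <- tx$strand[t]
    tx_len <- tx$tx_len[t]
    gseq <- reference$genome[[chrom]]
    tx_seq <- if (strand == "+") {
      substr(gseq, tx$start[t] + 1L, tx$end[t])
    } else {
      revcomp(substr(gseq, cfg$flank_len + 1L, cfg$flank_len + tx_len))
    }
    tsite <- reference$truth[reference$truth$chrom == chrom, , drop = FALSE]
    hot <- integer(0); protected <- integer(0)
    if (nrow(tsite) == 1L) {
      x <- tsite$tx_offset
      if (cfg$mode == "ago") {
        hot <- x
        protected <- tsite$anchor_start:(tsite$anchor_end - 1L)
      } else {
        hot <- (x - cfg$crosslink_window):(x + cfg$crosslink_window)
      }
      for (k in seq_len(cfg$depth)) {
        len <- rint(cfg$read_len)
        lo <- max(0L, x - len + 1L)
        hi <- min(tx_len - len, x)
        s <- pick_start(tx_seq, lo, hi, len)
        reads[[length(reads) + 1L]] <-
          emit(chrom, strand, tx$start[t], tx_len, tx_seq, s, len, hot,
               protected)
      }
    }
    nb <- cfg$background_reads_per_transcript
    if (nb > 0L) {
      for (k in seq_len(nb)) {
        len <- rint(cfg$read_len)
        s <- pick_start(tx_seq, 0L, tx_len - len, len)
        reads[[length(reads) + 1L]] <-
          emit(chrom, strand, tx$start[t], tx_len, tx_seq, s, len, hot,
               protected)
      }
    }
  }
  out <- do.call(rbind, lapply(reads, as.data.frame,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Simulate regions whose evidence is driven by one miRNA's seed matches
#'
#' Draws `n` random sequences; a fraction `target_frac` receives one
#' inserted site of the planted miRNA (seed type `seed_type`, default
#' 7mer-m8) at a random interior position. Evidence is standard-normal noise
#' plus `effect` for every region carrying the planted site pattern.
#'
#' @param n number of regions (default 2000).
#' @param len region length range in nt (default 50-70; variable lengths,
#'   as for real interaction sites, keep the dinucleotide confounders
#'   non-collinear).
#' @param mirna_sequence planted mature miRNA sequence.
#' @param seed_type planted seed-match type (default `"7mer-m8"`).
#' @param target_frac fraction of regions receiving a planted site (default
#'   0.05; the enrichment score is derived for the small-target regime
#'   n_j << n, where the no-intercept indicator coefficient estimates the
#'   planted effect).
#' @param effect additive evidence effect of the planted site (default 1).
#' @param seed RNG seed.
#' @return list with `regions` (an [evidence_regions()] table) and `truth`
#'   (planted region indices and offsets).
#' @export
simulate_seed_regions <- function(n = 2000L, len = c(50L, 70L),
                                  mirna_sequence = "TAGCAGCACGTAAATATTGGCG",
                                  seed_type = "7mer-m8", target_frac = 0.05,
                                  effect = 1, seed = 1L) {
  set.seed(seed)
  defs <- seed_sites(mirna_sequence)
  pat <- defs$site_pattern[defs$seed_type == seed_type]
  stopifnot(length(pat) == 1L)
  w <- nchar(pat)
  lens <- vapply(seq_len(n), function(i) rint(len), integer(1))
  seqs <- vapply(lens, rand_seq, character(1))
  planted <- sort(sample.int(n, round(target_frac * n)))
  offs <- integer(length(planted))
  for (k in seq_along(planted)) {
    i <- planted[k]
    s <- sample.int(lens[i] - w + 1L, 1L)
    seqs[i] <- paste0(substr(seqs[i], 1L, s - 1L), pat,
                      substr(seqs[i], s + w, lens[i]))
    offs[k] <- s
  }
  ev <- rnorm(n) + effect * grepl(pat, seqs, fixed = TRUE)
  list(regions = evidence_regions(seqs, ev),
       truth = data.frame(region = planted, start = offs,
                          pattern = pat, stringsAsFactors = FALSE))
}

#' Simulate evidence-scored regions with a motif planted in high-evidence
#' regions
#'
#' Draws `n` random sequences with standard-normal evidence and writes one
#' concrete instance of `motif` at a random interior position into every
#' region of the top evidence tercile (or the top `plant_frac` fraction).
#'
#' @param n number of regions (default 500).
#' @param len region length range in nt (default 50-70).
#' @param motif planted IUPAC motif (default the Pumilio2 consensus).
#' @param plant_frac fraction of top-evidence regions planted (default 1/3).
#' @param seed RNG seed.
#' @return list with `regions` (an [evidence_regions()] table) and `truth`
#'   (data.frame: region index, plant offset, concrete instance).
#' @export
simulate_evidence_regions <- function(n = 500L, len = c(50L, 70L),
                                      motif = "UGUANAUA", plant_frac = 1 / 3,
                                      seed = 1L) {
  set.seed(seed)
  lens <- vapply(seq_len(n), function(i) rint(len), integer(1))
  seqs <- vapply(lens, rand_seq, character(1))
  ev <- rnorm(n)
  top <- order(ev, decreasing = TRUE)[seq_len(floor(n * plant_frac))]
  w <- nchar(motif)
  truth <- lapply(top, function(i) {
    inst <- sample(expand_iupac(dna_norm(motif)), 1L)
    s <- sample.int(lens[i] - w + 1L, 1L)
    seqs[i] <<- paste0(substr(seqs[i], 1L, s - 1L), inst,
                       substr(seqs[i], s + w, lens[i]))
    data.frame(region = i, start = s, instance = inst,
               stringsAsFactors = FALSE)
  })
  list(regions = evidence_regions(seqs, ev),
       truth = do.call(rbind, truth))
}
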