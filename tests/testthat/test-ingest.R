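test_that("adapter stripping keeps, trims and discards reads correctly", {
  adapter <- "TCGTATGCCGTCTTCTGCTTG"
  insert20 <- "ACGTACGTACGTACGTACGT"
  insert25 <- "ACGTACGTACGTACGTACGTACGTA"

  # no adapter occurrence: read unchanged
  res <- preprocess_reads(insert25, adapter)
  expect_identical(res$reads, insert25)

  # full adapter appended: exactly the insert comes back
  res <- preprocess_reads(paste0(insert20, adapter), adapter)
  expect_identical(res$reads, insert20)

  # partial terminal adapter (>= 7 nt of its prefix) is clipped too
  res <- preprocess_reads(paste0(insert20, substr(adapter, 1, 9)), adapter)
  expect_identical(res$reads, insert20)

  # stripping that leaves 12 nt falls below the 13-nt floor
  res <- preprocess_reads(paste0(substr(insert20, 1, 12), adapter), adapter)
  expect_identical(res$reads, character(0))
  expect_identical(res$n_short, 1L)

  # ambiguous and invalid reads are counted separately
  res <- preprocess_reads(c("ACGTNACGTACGTACGT", "ACXTACGTACGTACGTA"),
                          adapter)
  expect_identical(res$reads, character(0))
  expect_identical(res$n_ambiguous, 1L)
  expect_identical(res$n_invalid, 1L)

  expect_identical(preprocess_reads(character(0), adapter)$reads,
                   character(0))
})

test_that("mismatch classification separates conversions by strand rule", {
  g <- c(chr1 = "AAAATAAAAGAAAAAAAAAA")
  # '+' read: reference T at offset 4 read as C -> one conversion
  r <- make_read(g, "chr1", 0L, 20L)
  r <- mutate_read(r, 5L, "C")
  cls <- classify_mismatches(r, g)
  expect_identical(cls$n_conversion, 1L)
  expect_identical(cls$n_other, 0L)
  expect_identical(cls$conv_offsets, 4L)

  # '-' read: plus-strand reference A read as G is a conversion in
  # transcript orientation
  rm <- make_read(g, "chr1", 0L, 20L, strand = "-")
  rm <- mutate_read(rm, 1L, "G")  # offset 0, ref A
  cls <- classify_mismatches(rm, g)
  expect_identical(cls$n_conversion, 1L)
  expect_identical(cls$n_other, 0L)

  # G/A mismatch is never a conversion
  r2 <- make_read(g, "chr1", 0L, 20L)
  r2 <- mutate_read(r2, 10L, "A")  # ref G -> read A
  cls <- classify_mismatches(r2, g)
  expect_identical(cls$n_conversion, 0L)
  expect_identical(cls$n_other, 1L)

  # an aligner-reported mismatch whose ref_base contradicts the reference
  # is corrupt input
  expect_error(
    classify_mismatches(r, g, mismatches = data.frame(
      ref_offset = 4L, ref_base = "G", read_base = "C")),
    "disagrees")
})

test_that("conversion counts are invariant under reverse-complementing the
           fixture", {
  set.seed(41)
  for (rep in 1:20) {
    g <- random_genome("chr1", 60)
    s <- sample(0:20, 1)
    e <- s + sample(15:30, 1)
    r <- make_read(g, "chr1", s, e)
    # plant conversions at reference-T offsets, noise elsewhere
    ref <- strsplit(substr(g[["chr1"]], s + 1, e), "")[[1]]
    ts <- which(ref == "T")
    for (k in head(ts, 2)) r <- mutate_read(r, k, "C")
    fwd <- classify_mismatches(r, g)

    g2 <- c(chr1 = parclip:::revcomp(g[["chr1"]]))
    L <- nchar(g[["chr1"]])
    r2 <- r
    r2$strand <- "-"
    r2$start <- L - e
    r2$end <- L - s
    r2$seq <- parclip:::revcomp(r$seq)
    rev <- classify_mismatches(r2, g2)
    expect_identical(rev$n_conversion, fwd$n_conversion)
    expect_identical(rev$n_other, fwd$n_other)
  }
})

test_that("unique-location selection enforces the single clean location", {
  base <- data.frame(read_id = "r1", chrom = "chr1", strand = "+",
                     start = 0L, end = 20L, seq = "x", n_loc = 1L,
                     stringsAsFactors = FALSE)
  # one location, two conversions, no other mismatches: retained
  a <- base; a$n_other <- 0L; a$n_conversion <- 2L
  expect_identical(nrow(select_unique(a)), 1L)

  # two clean candidate locations: dropped even if conversion counts differ
  b <- rbind(a, a); b$n_conversion <- c(2L, 0L); b$n_loc <- 2L
  expect_null(select_unique(b))

  # one location with a non-conversion mismatch: dropped
  c1 <- base; c1$n_other <- 1L; c1$n_conversion <- 0L
  expect_null(select_unique(c1))

  # aligner reported too many candidate locations: dropped
  d <- a; d$n_loc <- 11L
  expect_null(select_unique(d))
})

test_that("read grouping matches a brute-force union-find oracle", {
  g <- random_genome("chr1", 100, seed = 7)

  # transitive chain joins into one group
  chain <- rbind(make_read(g, "chr1", 0L, 20L, read_id = "a"),
                 make_read(g, "chr1", 15L, 35L, read_id = "b"),
                 make_read(g, "chr1", 30L, 50L, read_id = "c"))
  res <- build_read_groups(chain)
  expect_identical(nrow(res$groups), 1L)
  expect_identical(res$groups$start, 0L)
  expect_identical(res$groups$end, 50L)

  # abutting half-open intervals share no nucleotide: two groups
  ab <- rbind(make_read(g, "chr1", 0L, 20L, read_id = "a"),
              make_read(g, "chr1", 20L, 40L, read_id = "b"))
  expect_identical(nrow(build_read_groups(ab)$groups), 2L)

  # same coordinates, opposite strands: separate groups
  ss <- rbind(make_read(g, "chr1", 0L, 20L, read_id = "a"),
              make_read(g, "chr1", 0L, 20L, read_id = "b", strand = "-"))
  expect_identical(nrow(build_read_groups(ss)$groups), 2L)

  # property: grouping equals the pairwise union-find components, and
  # partitions the reads
  set.seed(11)
  for (rep in 1:5) {
    n <- 200L
    reads <- data.frame(
      read_id = sprintf("r%03d", 1:n),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = sample(0:500, n, replace = TRUE),
      stringsAsFactors = FALSE)
    reads$end <- reads$start + sample(13:35, n, replace = TRUE)
    reads$seq <- "x"; reads$n_loc <- 1L
    res <- build_read_groups(reads)
    expect_identical(sum(res$groups$n_reads), n)
    expect_false(anyNA(res$reads$group_id))
    oracle <- oracle_groups(reads)
    # identical partitions: same co-membership relation
    expect_identical(outer(res$reads$group_id, res$reads$group_id, "=="),
                     outer(oracle, oracle, "=="))
  }
})

test_that("annotation uses the category priority order", {
  m <- tiny_annotation()
  # overlaps both a 3' UTR and a CDS: 3' UTR wins
  res <- annotate_interval("chr1", "+", 160L, 190L, m)
  expect_identical(res$annotation, "3' UTR")
  # CDS-only region
  expect_identical(annotate_interval("chr1", "+", 250L, 260L, m)$annotation,
                   "CDS")
  # nothing: intergenic
  expect_identical(annotate_interval("chr1", "+", 600L, 620L, m)$annotation,
                   "intergenic")
  # intron + repeat: intron with the repeat flag set
  res <- annotate_interval("chr1", "+", 460L, 470L, m)
  expect_identical(res$annotation, "intron")
  expect_true(res$repeat_flag)
  # wrong strand does not pick up stranded annotation
  expect_identical(annotate_interval("chr1", "-", 160L, 190L, m)$annotation,
                   "intergenic")
  # unknown chromosome: intergenic with a warning
  expect_warning(res <- annotate_interval("chrX", "+", 0L, 10L, m),
                 "unannotated")
  expect_identical(res$annotation, "intergenic")
})

test_that("SAM round-trip preserves aligned reads and their conversions", {
  cfg <- sim_config(n_transcripts = 4L, n_sites = 2L, depth = 8L,
                    background_reads_per_transcript = 5L)
  ref <- simulate_reference(cfg, seed = 20)
  rd <- simulate_reads(ref, seed = 20)
  sam <- tempfile(fileext = ".sam")
  write_sam(rd, ref$genome, sam)
  back <- read_parclip_sam(sam)
  expect_identical(nrow(back), nrow(rd))
  o1 <- rd[order(rd$read_id), c("read_id", "chrom", "strand", "start",
                                "end", "seq", "n_loc")]
  o2 <- back[order(back$read_id), colnames(o1)]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o2, o1)
  # classification agrees after the round trip
  c1 <- classify_reads(o1, ref$genome)
  c2 <- classify_reads(o2, ref$genome)
  expect_identical(c2$n_conversion, c1$n_conversion)
})
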