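test_that("conversion profiles tally events per offset", {
  g <- c(chr1 = "AAAATAAAAAAAATAAAAAA")  # Ts at offsets 4 and 13
  reads <- do.call(rbind, lapply(1:5, function(i) {
    make_read(g, "chr1", 0L, 20L, read_id = sprintf("r%d", i))
  }))
  reads$seq[1] <- sub("^(.{4})T", "\\1C", reads$seq[1])  # convert offset 4
  reads <- classify_reads(reads, g)
  prof <- build_profile(reads, g)
  expect_identical(prof$L, 20L)
  expect_identical(prof$x_tc[5], 1L)   # offset 4, 1-based index 5
  expect_identical(prof$x_tt[5], 4L)
  expect_identical(prof$depth[5], 5L)
  expect_identical(prof$x_tt[14], 5L)
  expect_identical(prof$n_tc, 1L)
  expect_identical(sum(prof$x_tc + prof$x_tt > 0), 2L)

  # every read converting the same T: one conversion location, count 5
  reads2 <- reads
  reads2$seq <- sub("^(.{4})T", "\\1C", make_read(g, "chr1", 0L, 20L)$seq)
  reads2 <- classify_reads(reads2, g)
  prof2 <- build_profile(reads2, g)
  expect_identical(prof2$x_tc[5], 5L)
  expect_identical(sum(prof2$x_tc > 0), 1L)

  # no transcript-T positions at all
  g0 <- c(chr1 = paste(rep("ACG", 10), collapse = ""))
  r0 <- classify_reads(make_read(g0, "chr1", 0L, 15L), g0)
  p0 <- build_profile(r0, g0)
  expect_identical(p0$n_tc + p0$n_tt, 0L)

  expect_error(build_profile(reads[0, ], g), "empty")
})

test_that("kernel densities are normalised, symmetric, and have the exact
           Gaussian ratio", {
  prof <- structure(list(L = 11L, chrom = "c", strand = "+", start = 0L,
                         x_tc = as.integer(c(0,0,0,0,1,0,0,0,0,0,0)),
                         x_tt = integer(11), depth = rep(5L, 11),
                         is_t = rep(TRUE, 11), n_tc = 1L, n_tt = 0L),
                    class = "conversion_profile")
  d <- estimate_densities(prof, lambda = 3)
  expect_equal(sum(d$k_tc), 1, tolerance = 1e-12)
  expect_identical(which.max(d$k_tc), 5L)
  # single-kernel symmetry about the event (within the untruncated core)
  expect_equal(d$k_tc[4], d$k_tc[6], tolerance = 1e-12)
  # ratio of Gaussian kernels: k(5)/k(2) = exp(9 / (2 * 9)) = exp(0.5)
  expect_equal(d$k_tc[5] / d$k_tc[2], exp(0.5), tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:10) {
    p <- random_profile()
    d <- estimate_densities(p)
    expect_equal(sum(d$k_tc), 1, tolerance = 1e-9)
    if (p$n_tt > 0) expect_equal(sum(d$k_tt), 1, tolerance = 1e-9)
    expect_true(all(d$k_tc >= 0) && all(d$k_tt >= 0))
  }
})

test_that("position classification matches the naive-loop oracle", {
  # conversion mass on the left, non-conversion on the right: one left
  # anchored signal run with a single crossover
  L <- 40L
  prof <- structure(list(L = L, chrom = "c", strand = "+", start = 0L,
                         x_tc = as.integer(c(3, 2, 3, rep(0, L - 3))),
                         x_tt = as.integer(c(rep(0, L - 3), 3, 2, 3)),
                         depth = rep(6L, L), is_t = rep(TRUE, L),
                         n_tc = 8L, n_tt = 8L),
                    class = "conversion_profile")
  d <- estimate_densities(prof)
  sig <- classify_positions(prof, d)
  expect_identical(sig, oracle_classify(prof))
  expect_true(1L %in% sig)
  expect_identical(sig, seq_len(max(sig)))  # contiguous, left-anchored

  # no non-conversion events: every depth-qualified offset is signal
  p2 <- prof; p2$x_tt <- integer(L); p2$n_tt <- 0L
  p2$depth[10] <- 2L
  d2 <- estimate_densities(p2)
  expect_identical(classify_positions(p2, d2), setdiff(1:L, 10L))

  # depth below the floor excludes an offset whose densities favour signal
  p3 <- prof
  p3$depth[2] <- 4L
  expect_false(2L %in% classify_positions(p3, estimate_densities(p3)))
  expect_true(2L %in% classify_positions(prof, d))
})

test_that("site extension respects mode and the depth floor", {
  L <- 30L
  mkprof <- function(depth) {
    structure(list(L = L, chrom = "c", strand = "+", start = 100L,
                   x_tc = as.integer(c(rep(0, 11), 2, 2, 2, rep(0, 16))),
                   x_tt = integer(L), depth = depth, is_t = rep(TRUE, L),
                   n_tc = 6L, n_tt = 0L), class = "conversion_profile")
  }
  # depth ample on [6,20] (1-based): fixed5 grows the core by 5 per side
  depth <- rep(2L, L); depth[6:20] <- 6L
  expect_identical(extend_site(c(11L, 15L), mkprof(depth), mode = "fixed5"),
                   c(6L, 20L))
  # depth cliff on the left: extension halts where depth < 5
  depth2 <- rep(2L, L); depth2[9:15] <- 6L
  expect_identical(extend_site(c(11L, 15L), mkprof(depth2), mode = "fixed5"),
                   c(9L, 15L))
  # by_read reaches the distal ends of conversion-bearing overlapping reads
  depth3 <- rep(6L, L)
  reads <- data.frame(read_id = "r", chrom = "c", strand = "+",
                      start = 102L, end = 128L, seq = "x", n_loc = 1L,
                      n_conversion = 1L, n_other = 0L,
                      stringsAsFactors = FALSE)
  expect_identical(
    extend_site(c(11L, 15L), mkprof(depth3), reads, mode = "by_read"),
    c(3L, 28L))
  # a conversion-free read does not extend the span
  reads0 <- reads; reads0$n_conversion <- 0L
  expect_identical(
    extend_site(c(11L, 15L), mkprof(depth3), reads0, mode = "by_read"),
    c(11L, 15L))
})

test_that("overlapping extended spans merge and recompute statistics", {
  g <- c(chr1 = paste(rep("AT", 30), collapse = ""))
  reads <- do.call(rbind, lapply(1:6, function(i) {
    make_read(g, "chr1", 0L, 60L, read_id = sprintf("r%d", i))
  }))
  reads <- classify_reads(reads, g)
  prof <- build_profile(reads, g)
  # chained overlaps collapse to a single span; disjoint spans stay apart
  m <- merge_sites(list(c(1L, 10L), c(10L, 20L), c(18L, 30L)), prof, reads)
  expect_identical(nrow(m), 1L)
  expect_identical(c(m$start, m$end), c(0L, 30L))
  m2 <- merge_sites(list(c(1L, 10L), c(12L, 20L)), prof, reads)
  expect_identical(nrow(m2), 2L)
  # abutting spans (no shared nucleotide) are not merged
  m3 <- merge_sites(list(c(1L, 10L), c(11L, 20L)), prof, reads)
  expect_identical(nrow(m3), 2L)
})

test_that("the caller enforces group filters and splits multi-site groups", {
  # groups below the read or conversion-location floor yield nothing
  g <- c(chr1 = paste(rep("AATT", 25), collapse = ""))
  four <- do.call(rbind, lapply(1:4, function(i) {
    mutate_read(make_read(g, "chr1", 0L, 30L, read_id = sprintf("r%d", i)),
                3L, "C")
  }))
  four <- classify_reads(four, g)
  expect_identical(nrow(call_sites(four, g)), 0L)

  five_one_loc <- do.call(rbind, lapply(1:5, function(i) {
    mutate_read(make_read(g, "chr1", 0L, 30L, read_id = sprintf("r%d", i)),
                3L, "C")
  }))
  five_one_loc <- classify_reads(five_one_loc, g)
  expect_identical(nrow(call_sites(five_one_loc, g)), 0L)

  # two crosslink hotspots 40 nt apart in one read group give two sites
  cfg <- sim_config(n_transcripts = 1L, n_sites = 1L, depth = 15L,
                    utr3_len = c(300L, 300L),
                    background_reads_per_transcript = 0L, frac_minus = 0)
  ref <- simulate_reference(cfg, seed = 9)
  rd1 <- simulate_reads(ref, seed = 9)
  ref2 <- ref
  ref2$truth$tx_offset <- ref2$truth$tx_offset + 40L
  ref2$truth$crosslink_pos <- ref2$truth$crosslink_pos + 40L
  # force Ts at the shifted crosslink too
  ch <- ref2$truth$chrom
  x <- ref2$truth$crosslink_pos
  s <- ref2$genome[[ch]]
  substr(s, x, x + 2) <- "TTT"
  ref2$genome[ch] <- s
  rd2 <- simulate_reads(ref2, seed = 10)
  both <- rbind(rd1, rd2)
  both$read_id <- sprintf("r%04d", seq_len(nrow(both)))
  both <- classify_reads(both, ref2$genome)
  grp <- build_read_groups(both)
  sites <- call_sites(both, ref2$genome, mode = "fixed5")
  if (nrow(grp$groups) == 1L) {
    expect_gte(nrow(sites), 2L)
  }
  # every site lies inside its group span with positive depth
  for (i in seq_len(nrow(sites))) {
    grow <- grp$groups[grp$groups$group_id == sites$group_id[i], ]
    expect_gte(sites$start[i], grow$start)
    expect_lte(sites$end[i], grow$end)
  }
})

test_that("raising group floors never increases the number of sites", {
  cfg <- sim_config(n_transcripts = 10L, n_sites = 6L, depth = 12L)
  ref <- simulate_reference(cfg, seed = 13)
  rd <- classify_reads(simulate_reads(ref, seed = 13), ref$genome)
  n_base <- nrow(call_sites(rd, ref$genome, min_reads = 5L,
                            min_conversion_locations = 2L))
  for (mr in c(8L, 12L, 20L)) {
    expect_lte(nrow(call_sites(rd, ref$genome, min_reads = mr)), n_base)
  }
  for (mc in c(4L, 8L)) {
    expect_lte(nrow(call_sites(rd, ref$genome,
                               min_conversion_locations = mc)), n_base)
  }
})

test_that("planted-site recovery is stable across kernel bandwidths", {
  cfg <- sim_config(n_transcripts = 12L, n_sites = 8L, depth = 20L)
  ref <- simulate_reference(cfg, seed = 23)
  rd <- classify_reads(simulate_reads(ref, seed = 23), ref$genome)
  for (lam in c(2, 3, 4, 5)) {
    sites <- call_sites(rd, ref$genome, lambda = lam)
    hit <- vapply(seq_len(nrow(ref$truth)), function(i) {
      sel <- sites$chrom == ref$truth$chrom[i]
      any(sel) && min(abs((sites$start[sel] + sites$end[sel] - 1) / 2 -
                            ref$truth$crosslink_pos[i])) <= 2
    }, logical(1))
    expect_gte(mean(hit), 0.85)
  }
})

test_that("crosslink-centered regions are fixed-width windows at the
           conversion-fraction maximum", {
  cfg <- sim_config(n_transcripts = 6L, n_sites = 4L, depth = 10L)
  ref <- simulate_reference(cfg, seed = 31)
  rd <- classify_reads(simulate_reads(ref, seed = 31), ref$genome)
  ccrs <- ccr_regions(rd, ref$genome)
  expect_true(all(ccrs$end - ccrs$start == 41L))
  expect_gt(nrow(ccrs), 0L)
})
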