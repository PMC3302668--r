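# Evidence-ranked motif scoring and greedy IUPAC motif search.
#
# Regions (interaction sites) carry a quantitative binding evidence
# y* = log2(#conversions) (or log2(#reads)), mean-centered across the region
# set. A motif's target set is the regions it matches; its score is the
# adjusted t-like statistic S = A * e / (sigma/sqrt(n_j)) with e the mean
# centered evidence over targets, sigma^2 the sample variance of the centered
# evidence over all regions, and A = sqrt(1 - n_j/n) an adjustment that tends
# to 1 for small target sets.

#' Assemble an evidence-region table
#'
#' @param sequences character vector of transcript-sense region sequences.
#' @param evidence numeric binding evidence per region (e.g. log2 conversion
#'   counts); mean-centered across the set to give `y_star`.
#' @param region_id optional ids (default: names of `sequences` or index).
#' @return data.frame with `region_id`, `sequence` and centered `y_star`.
#' @export
evidence_regions <- function(sequences, evidence, region_id = NULL) {
  stopifnot(length(sequences) == length(evidence), all(nchar(sequences) > 0))
  if (is.null(region_id)) {
    region_id <- if (!is.null(names(sequences))) names(sequences)
                 else as.character(seq_along(sequences))
  }
  data.frame(region_id = region_id, sequence = dna_norm(sequences),
             y_star = evidence - mean(evidence), stringsAsFactors = FALSE)
}

#' Evidence-ranked enrichment score of one motif
#'
#' @param regions evidence-region table from [evidence_regions()].
#' @param pattern IUPAC motif.
#' @param adjustment adjustment factor A as a function of (n_j, n); the
#'   default sqrt(1 - n_j/n) tends to 1 when the target set is small relative
#'   to the region set.
#' @return list with `pattern`, `n_targets`, `e` (mean target evidence),
#'   `se`, `A` and `score`; or NULL when the motif matches no region.
#' @export
cermit_score <- function(regions, pattern,
                         adjustment = function(n_j, n) sqrt(1 - n_j / n)) {
  x <- vapply(regions$sequence, function(s) {
    length(iupac_scan(s, pattern)) > 0L
  }, logical(1), USE.NAMES = FALSE)
  score_target_set(regions$y_star, which(x), pattern, adjustment)
}

#' @noRd
score_target_set <- function(y_star, targets, pattern, adjustment) {
  n <- length(y_star)
  n_j <- length(targets)
  if (n_j == 0L) return(NULL)
  sigma2 <- var(y_star)
  e <- mean(y_star[targets])
  se <- sqrt(sigma2 / n_j)
  A <- adjustment(n_j, n)
  score <- if (se == 0) 0 else A * e / se
  list(pattern = pattern, n_targets = n_j, e = e, se = se, A = A,
       score = score)
}

#' Greedy evidence-ranked motif search
#'
#' Enumerates all non-degenerate k-mers of length `k_start` that reach the
#' minimum target-set size, then hill-climbs from the best starting seeds
#' over single-symbol degeneracy substitutions and single-position
#' extensions/contractions (lengths `lengths[1]`..`lengths[2]`), accepting
#' the best strictly score-improving move at each step.
#'
#' @inheritParams cermit_score
#' @param k_start starting oligomer length (default 7).
#' @param min_target_frac minimum target-set size as a fraction of the region
#'   set (default 0.05).
#' @param max_degenerate maximum number of degenerate positions in a motif
#'   (default 3).
#' @param lengths allowed motif length range (default 6 to 10).
#' @param n_starts number of top starting seeds expanded (default 50).
#' @return list with `motifs` (data.frame ranked by score), `pfm` (position
#'   frequency matrix of the top motif's match instances) and `occurrences`
#'   (per-region matches of the top motif, in decreasing order of evidence).
#' @export
cermit_search <- function(regions, k_start = 7L, min_target_frac = 0.05,
                          max_degenerate = 3L, lengths = c(6L, 10L),
                          n_starts = 50L,
                          adjustment = function(n_j, n) sqrt(1 - n_j / n)) {
  n <- nrow(regions)
  if (n < 20L) stop("motif search needs at least 20 regions")
  min_n <- ceiling(min_target_frac * n)
  y <- regions$y_star
  idx <- lapply(lengths[1]:lengths[2], function(k) {
    kmer_region_index(regions$sequence, k)
  })
  names(idx) <- as.character(lengths[1]:lengths[2])

  targets_of <- function(motif) {
    k <- nchar(motif)
    tab <- idx[[as.character(k)]]
    hits <- unlist(tab[expand_iupac(motif)], use.names = FALSE)
    if (is.null(hits)) integer(0) else unique(hits)
  }
  cache <- new.env(parent = emptyenv())
  score_of <- function(motif) {
    if (!is.null(cache[[motif]])) return(cache[[motif]])
    tg <- targets_of(motif)
    sc <- if (length(tg) < min_n) NULL
          else score_target_set(y, tg, motif, adjustment)
    val <- if (is.null(sc)) -Inf else sc$score
    cache[[motif]] <- val
    val
  }

  # starting seeds: all concrete k_start-mers occurring in the regions
  start_tab <- idx[[as.character(k_start)]]
  start_n <- lengths(start_tab)
  cand <- names(start_tab)[start_n >= min_n]
  if (length(cand) == 0L) {
    warning("no starting oligomer reaches the minimum target-set size")
    return(list(motifs = data.frame(), pfm = NULL, occurrences = data.frame()))
  }
  start_scores <- vapply(cand, score_of, numeric(1))
  seeds <- cand[order(start_scores, decreasing = TRUE)]
  seeds <- head(seeds, n_starts)

  finals <- character(0)
  for (seed in seeds) {
    cur <- seed
    cur_s <- score_of(cur)
    for (iter in 1:30) {
      moves <- propose_moves(cur, max_degenerate, lengths)
      ms <- vapply(moves, score_of, numeric(1))
      if (length(ms) == 0L || max(ms) <= cur_s) break
      cur <- moves[[which.max(ms)]]
      cur_s <- max(ms)
    }
    finals <- c(finals, cur)
  }
  # an N at either end constrains nothing but the match room; trim it
  finals <- sub("^N+", "", sub("N+$", "", finals))
  finals <- unique(finals[nchar(finals) >= lengths[1]])
  fs <- vapply(finals, function(m) {
    sc <- score_target_set(y, targets_of(m), m, adjustment)
    sc$score
  }, numeric(1))
  ord <- order(fs, decreasing = TRUE)
  motifs <- do.call(rbind, lapply(finals[ord], function(m) {
    sc <- score_target_set(y, targets_of(m), m, adjustment)
    data.frame(pattern = m, n_targets = sc$n_targets, e = sc$e,
               score = sc$score, stringsAsFactors = FALSE)
  }))
  top <- motifs$pattern[1]
  occ <- motif_occurrences(regions, top)
  list(motifs = motifs, pfm = occurrence_pfm(occ), occurrences = occ)
}

#' @noRd
kmer_region_index <- function(seqs, k) {
  pairs <- lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    n <- nchar(s)
    if (n < k) return(NULL)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  reg <- rep.int(seq_along(seqs), vapply(pairs, length, integer(1)))
  split(reg, unlist(pairs))
}

#' All concrete expansions of an IUPAC motif
#' @noRd
expand_iupac <- function(motif) {
  classes <- IUPAC_CLASSES[str_chars(motif)]
  if (anyNA(names(classes))) stop("invalid IUPAC symbol in motif: ", motif)
  do.call(paste0, do.call(expand.grid,
                          c(classes, stringsAsFactors = FALSE)))
}

#' Single-step neighbourhood of a motif in the search space
#' @noRd
propose_moves <- function(motif, max_degenerate, lengths) {
  chars <- str_chars(motif)
  L <- length(chars)
  syms <- names(IUPAC_CLASSES)
  degen <- setdiff(syms, DNA_BASES)
  n_degen <- sum(chars %in% degen)
  moves <- character(0)
  for (p in seq_len(L)) {
    for (s in setdiff(syms, chars[p])) {
      adds <- (s %in% degen) - (chars[p] %in% degen)
      if (n_degen + adds > max_degenerate) next
      m <- chars; m[p] <- s
      moves <- c(moves, paste(m, collapse = ""))
    }
  }
  if (L < lengths[2]) {
    ext <- if (n_degen < max_degenerate) syms else DNA_BASES
    moves <- c(moves, paste0(motif, ext), paste0(ext, motif))
  }
  if (L > lengths[1]) {
    moves <- c(moves, substr(motif, 2L, L), substr(motif, 1L, L - 1L))
  }
  unique(moves)
}

#' Per-region match instances of a motif, in decreasing evidence order
#' @noRd
motif_occurrences <- function(regions, motif) {
  out <- lapply(order(regions$y_star, decreasing = TRUE), function(i) {
    st <- iupac_scan(regions$sequence[i], motif)
    if (length(st) == 0L) return(NULL)
    data.frame(region_id = regions$region_id[i],
               y_star = regions$y_star[i], start = st,
               instance = substring(regions$sequence[i], st,
                                    st + nchar(motif) - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(region_id = character(0), y_star = numeric(0),
                      start = integer(0), instance = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Position frequency matrix of match instances
#' @noRd
occurrence_pfm <- function(occ) {
  if (nrow(occ) == 0L) return(NULL)
  L <- nchar(occ$instance[1])
  pfm <- matrix(0L, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  for (inst in occ$instance) {
    b <- str_chars(inst)
    for (k in seq_len(L)) pfm[b[k], k] <- pfm[b[k], k] + 1L
  }
  pfm
}

#' Write a position frequency matrix in MEME-minimal text format
#'
#' @param pfm 4 x L count matrix (rows A, C, G, T).
#' @param path output file.
#' @param name motif name recorded in the file.
#' @export
write_pfm_meme <- function(pfm, path, name = "motif1") {
  probs <- sweep(pfm, 2, pmax(colSums(pfm), 1L), "/")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
                       ncol(pfm), max(colSums(pfm)))), con)
  for (j in seq_len(ncol(probs))) {
    writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                       probs[1, j], probs[2, j], probs[3, j], probs[4, j]),
               con)
  }
}
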