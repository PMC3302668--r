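# Seed-restricted miRNA enrichment regression (mEAT): evidence is regressed
# on a seed-match indicator plus 16 standardized dinucleotide-count
# confounders, one fit per canonical seed type; the miRNA score averages the
# positively scoring seed types and is tested against a Gaussian fit to a
# permutation null.

#' Overlapping dinucleotide counts per sequence
#'
#' @param sequences character vector (ACGT/U).
#' @return n x 16 integer matrix, columns AA, AC, ..., TT.
#' @export
dinucleotide_counts <- function(sequences) {
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  out <- t(vapply(dna_norm(sequences), function(s) {
    n <- nchar(s)
    d <- substring(s, 1:(n - 1L), 2:n)
    tabulate(factor(d, levels = dinucs), nbins = 16L)
  }, integer(16), USE.NAMES = FALSE))
  colnames(out) <- dinucs
  out
}

#' Standardized confounder matrix for the enrichment regression
#'
#' Dinucleotide counts, mean-centered and scaled to unit sample standard
#' deviation; zero-variance columns are dropped with a warning.
#'
#' @param regions evidence-region table from [evidence_regions()].
#' @return numeric matrix with attribute `dropped` naming removed columns.
#' @export
meat_design <- function(regions) {
  counts <- dinucleotide_counts(regions$sequence)
  sds <- apply(counts, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping zero-variance confounder column(s): ",
            paste(colnames(counts)[!keep], collapse = ", "))
  }
  z <- scale(counts[, keep, drop = FALSE])
  attr(z, "dropped") <- colnames(counts)[!keep]
  z
}

#' OLS t-statistic of the first design column, vectorised over responses
#'
#' Fits Y = Z b + e without intercept for each column of `Y` and returns the
#' coefficient of the first column of `Z` divided by its estimated standard
#' error. Rank-deficient designs drop pivoted-out trailing covariates; an
#' indicator column lost to collinearity yields NA.
#'
#' @param Z n x p design (first column = seed indicator).
#' @param Y n-vector or n x B matrix of (centered) responses.
#' @return numeric vector of length ncol(Y).
#' @noRd
ols_first_tstat <- function(Z, Y) {
  ols_fit_first(Z, Y)$tstat
}

#' OLS of the first design column: coefficient, SE and t, vectorised over
#' response columns; rank-deficient designs drop pivoted-out covariates.
#' @noRd
ols_fit_first <- function(Z, Y) {
  Y <- as.matrix(Y)
  B <- ncol(Y)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    keep <- sort(qz$pivot[seq_len(qz$rank)])
    if (!(1L %in% keep)) {
      na <- rep(NA_real_, B)
      return(list(coef = na, se = na, tstat = na))
    }
    Z <- Z[, keep, drop = FALSE]
  }
  C <- chol2inv(chol(crossprod(Z)))
  zty <- crossprod(Z, Y)
  beta <- C %*% zty
  rss <- colSums(Y^2) - colSums(zty * beta)
  df <- nrow(Z) - ncol(Z)
  sigma2 <- pmax(rss, 0) / df
  se1 <- sqrt(sigma2 * C[1, 1])
  list(coef = beta[1, ], se = se1,
       tstat = ifelse(se1 > 0, beta[1, ] / se1, NA_real_))
}

#' mEAT score of one miRNA over a region set
#'
#' For each of the seven canonical seed types, the (centered) evidence is
#' regressed on the seed-match indicator plus the standardized dinucleotide
#' confounders; the per-type score is the indicator coefficient divided by
#' its standard error, and the miRNA score is the mean over positively
#' scoring types (0 when no type scores positively). Seed types matching no
#' region (or every region) are excluded as undefined.
#'
#' @param regions evidence-region table from [evidence_regions()].
#' @param mirna_sequence mature miRNA sequence (5' to 3').
#' @param design optional precomputed confounder matrix from [meat_design()].
#' @param indicators optional precomputed n x 7 indicator matrix (columns in
#'   seed-type order) to reuse across permutations.
#' @return list with `per_type` (data.frame: seed_type, site_pattern,
#'   n_targets, score, coefficient, se), `s_reg` and `targets` (region row
#'   indices matched by any seed type).
#' @export
meat_score <- function(regions, mirna_sequence, design = NULL,
                       indicators = NULL) {
  if (is.null(design)) design <- meat_design(regions)
  defs <- seed_sites(mirna_sequence)
  if (is.null(indicators)) {
    indicators <- seed_indicators(regions$sequence, defs)
  }
  y <- regions$y_star
  per <- lapply(seq_len(nrow(defs)), function(j) {
    x <- indicators[, j]
    n_t <- sum(x)
    if (n_t == 0L || n_t == nrow(regions)) {
      return(data.frame(seed_type = defs$seed_type[j],
                        site_pattern = defs$site_pattern[j], n_targets = n_t,
                        score = NA_real_, coefficient = NA_real_,
                        se = NA_real_, stringsAsFactors = FALSE))
    }
    fit <- ols_fit_first(cbind(x, design), y)
    data.frame(seed_type = defs$seed_type[j],
               site_pattern = defs$site_pattern[j], n_targets = n_t,
               score = fit$tstat, coefficient = fit$coef, se = fit$se,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  s <- per$score[!is.na(per$score) & per$score > 0]
  list(per_type = per, s_reg = if (length(s) > 0) mean(s) else 0,
       targets = which(rowSums(indicators) > 0))
}

#' @noRd
seed_indicators <- function(sequences, defs) {
  sequences <- dna_norm(sequences)
  vapply(defs$site_pattern, function(p) {
    grepl(p, sequences, fixed = TRUE)
  }, logical(length(sequences)))
}

#' Permutation significance of mEAT scores
#'
#' Recomputes the miRNA score on `B` permutations of the binding evidence
#' (one shared permutation stream for all seed types and miRNAs), fits a
#' Gaussian to the null scores, and calls a score significant when it exceeds
#' the null mean by more than `sd_threshold` standard deviations. The
#' reported p-value is the upper Gaussian tail at the observed score.
#'
#' @inheritParams meat_score
#' @param mirnas data.frame with `mirna_id`, `sequence` and optional `rank`.
#' @param B number of evidence permutations (default 100).
#' @param sd_threshold significance threshold in null standard deviations
#'   (default 3).
#' @param seed RNG seed for the permutation stream.
#' @return data.frame ranked by score: `mirna_id`, `seed8` (8mer-m1 site
#'   pattern), `score`, `null_mean`, `null_sd`, `p_value`, `significant`,
#'   `n_targets`, plus a `targets` list-column of matched region indices.
#' @export
meat_significance <- function(regions, mirnas, B = 100L, sd_threshold = 3,
                              seed = NULL) {
  stopifnot(B >= 10L)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(regions)
  design <- meat_design(regions)
  perm <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  Yp <- matrix(regions$y_star[perm], nrow = n)

  rows <- lapply(seq_len(nrow(mirnas)), function(i) {
    defs <- seed_sites(mirnas$sequence[i])
    ind <- seed_indicators(regions$sequence, defs)
    obs <- meat_score(regions, mirnas$sequence[i], design = design,
                      indicators = ind)
    # null: per seed type, t-statistics for all B permuted responses at once
    null_t <- vapply(seq_len(ncol(ind)), function(j) {
      n_t <- sum(ind[, j])
      if (n_t == 0L || n_t == n) return(rep(NA_real_, B))
      ols_first_tstat(cbind(ind[, j], design), Yp)
    }, numeric(B))
    null_s <- apply(null_t, 1, function(tt) {
      pos <- tt[!is.na(tt) & tt > 0]
      if (length(pos) > 0) mean(pos) else 0
    })
    mu <- mean(null_s)
    sdv <- stats::sd(null_s)
    if (sdv > 0) {
      p <- pnorm(obs$s_reg, mean = mu, sd = sdv, lower.tail = FALSE)
      sig <- obs$s_reg > mu + sd_threshold * sdv
    } else {
      p <- if (obs$s_reg > mu) 0 else if (obs$s_reg == mu) 0.5 else 1
      sig <- obs$s_reg > mu
      warning("degenerate (zero-variance) permutation null for ",
              mirnas$mirna_id[i])
    }
    df <- data.frame(mirna_id = mirnas$mirna_id[i],
                     seed8 = obs$per_type$site_pattern[1],
                     score = obs$s_reg, null_mean = mu, null_sd = sdv,
                     p_value = p, significant = sig,
                     n_targets = length(obs$targets),
                     stringsAsFactors = FALSE)
    df$targets <- list(obs$targets)
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$score, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster ranked miRNAs by seed similarity
#'
#' Greedy clustering around centers: the top-scoring miRNA founds the first
#' cluster; each subsequent miRNA joins the first existing center whose
#' canonical seed-site string shares an identical substring of at least
#' `min_share` consecutive nucleotides with its own, and founds a new cluster
#' otherwise.
#'
#' @param patterns character vector of canonical seed-site strings (e.g. the
#'   8mer-m1 patterns), ordered by decreasing score.
#' @param min_share minimum shared substring length (default 7).
#' @return integer vector of cluster ids (1 = top cluster).
#' @export
cluster_seeds <- function(patterns, min_share = 7L) {
  centers <- character(0)
  out <- integer(length(patterns))
  for (i in seq_along(patterns)) {
    hit <- 0L
    for (k in seq_along(centers)) {
      if (shares_substring(patterns[i], centers[k], min_share)) {
        hit <- k
        break
      }
    }
    if (hit == 0L) {
      centers <- c(centers, patterns[i])
      hit <- length(centers)
    }
    out[i] <- hit
  }
  out
}

#' @noRd
shares_substring <- function(a, b, k) {
  a <- dna_norm(a); b <- dna_norm(b)
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  subs <- substring(a, 1:(nchar(a) - k + 1L), k:nchar(a))
  any(vapply(subs, function(s) grepl(s, b, fixed = TRUE), logical(1)))
}

#' Ranked, clustered miRNA enrichment report
#'
#' Runs [meat_significance()] and adds seed clustering plus cumulative
#' distinct-target counts down the ranking.
#'
#' @inheritParams meat_significance
#' @return data.frame with `cluster`, `mirna_id`, `seed8`, `score`,
#'   `p_value`, `significant`, `n_targets`, `cumulative_targets`.
#' @export
meat_enrichment <- function(regions, mirnas, B = 100L, sd_threshold = 3,
                            seed = NULL) {
  res <- meat_significance(regions, mirnas, B = B,
                           sd_threshold = sd_threshold, seed = seed)
  res$cluster <- cluster_seeds(res$seed8)
  seen <- integer(0)
  cum <- integer(nrow(res))
  for (i in seq_len(nrow(res))) {
    seen <- union(seen, res$targets[[i]])
    cum[i] <- length(seen)
  }
  res$cumulative_targets <- cum
  res[, c("cluster", "mirna_id", "seed8", "score", "p_value", "significant",
          "n_targets", "cumulative_targets")]
}
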