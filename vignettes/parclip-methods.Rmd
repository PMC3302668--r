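---
title: "Interaction site calling and motif enrichment for PAR-CLIP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction site calling and motif enrichment for PAR-CLIP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parclip)
```

## The problem

PAR-CLIP libraries are short-read sequencing libraries of RNA fragments
crosslinked to an immunoprecipitated RNA-binding protein (RBP). Cells are
cultured with 4-thiouridine; during cDNA synthesis the crosslinked
nucleoside preferentially pairs with guanine, so a reference thymine is read
as cytosine at the site of protein-RNA contact. The T=>C conversion is
therefore a positional signature of binding, distinct from coverage alone,
and the analytical task is to separate conversion-driven signal from the
non-converted background *within* each pile-up of reads.

`parclip` implements this separation, plus the downstream analyses a
PAR-CLIP study needs: motif and miRNA seed-match scanning over called
sites, signal-to-noise estimation against expressed-gene backgrounds,
evidence-ranked de novo motif discovery, and a seed-restricted miRNA
enrichment regression. A seeded simulator generates complete synthetic
libraries so every stage can be exercised and validated offline.

## Read ingestion

Raw reads are stripped of the 3' adapter (leftmost occurrence of the full
adapter, or of at least 7 nt of its prefix at the read end), and reads
shorter than 13 nt or containing an ambiguous base are discarded. Aligned
reads are consumed from SAM/BAM as ungapped records; mismatches are derived
by direct comparison against the reference FASTA. A mismatch is a
*conversion* iff, in transcript orientation, the reference base is T and
the read base is C (reference A => read G in plus-strand coordinates for
'-' alignments). After subtracting conversions from the mismatch count,
only reads with exactly one candidate location with zero remaining
mismatches are kept (up to 2 mismatches per read by default, all
conversions; aligners reporting more than 10 candidate locations drop the
read).

Retained reads overlapping by at least one nucleotide on the same
chromosome and strand form *read groups*, the unit of site calling.
Grouping is strand-separated: the crosslink chemistry acts on the
transcript strand and annotation is stranded, so merging opposite-strand
pile-ups would conflate independent transcripts. Groups and sites are
annotated by the priority order 3' UTR > CDS > 5' UTR > miRNA > intron >
intergenic, using any-overlap at query time; coordinates are 0-based
half-open (BED convention) throughout.

## The kernel-density classifier

For a read group of length $L$, let $x_{TC}(i)$ and $x_{TT}(i)$,
$i \in \{1..L\}$, be the number of conversion and non-conversion events at
offset $i$, with totals $n_{TC}$ and $n_{TT}$. Each class $c$ is smoothed
with a Gaussian kernel of scale $\lambda$ (default 3 nt):

$$f_c(j) = \sum_{i=1}^{L} \frac{x_c(i)}{n_c}\,
  e^{-\frac{(i-j)^2}{2\lambda^2}}, \qquad
  k_c(j) = \frac{f_c(j)}{\sum_{j'} f_c(j')}$$

Since $k_c$ is renormalised over $j$, any constant kernel prefactor
cancels; the implementation therefore omits it. Offsets where
$k_{TC}(j) > k_{TT}(j)$ (strict; ties are background) at read depth of at
least 5 are classified as signal. Only groups with at least 5 reads and at
least 2 distinct conversion locations are classified at all: fewer reads
cannot support the density estimates, and a single conversion location is
indistinguishable from a sequencing artefact. Two degenerate cases are
handled explicitly: a group with $n_{TT} = 0$ classifies every
depth-qualified offset as signal (the $k_{TT} \to 0$ limit), and
classification is skipped for empty profiles.

Maximal runs of signal offsets become candidate sites, which are extended
in one of two modes:

* **fixed5** — grow up to 5 nt per side while depth stays at or above the
  floor. Suited to RBPs that crosslink directly at the motif (e.g.
  Pumilio2).
* **by_read** — grow to the most distal ends of conversion-bearing reads
  that overlap the core by at least one nucleotide, truncated at the first
  position where depth falls below the floor. Suited to factors whose
  binding site is protected from conversion (Argonaute seed matches, QKI,
  IGF2BP1), since the protected site lies within the reads but outside the
  conversion peak. Extension is a single pass from the core: reads
  recruited only by the extension do not extend further.

Extended spans that overlap are merged and statistics recomputed on the
merged span; the per-position depth floor is not re-checked after merging
(the merge is a pure interval union). Each site carries the binding
evidence $y^* = \log_2(\#\text{conversions})$; $\log_2(\#\text{reads})$ is
available as an option for CLIP-seq-style input where conversions are not
informative. A 41-nt fixed window baseline re-centered on the offset with
the highest conversion fraction (`ccr_regions()`) is provided for
benchmarking only.

Setting `min_depth = 1` gives the relaxed variant that requires five reads
per group but no per-position floor.

## Motif and seed matching

`iupac_scan()` matches degenerate IUPAC patterns (U and T equivalent) on
transcript-sense sequence, reporting all overlapping offsets; '-' strand
regions are reverse-complemented before scanning. Presets for PUM2
(`UGUANAUA`), QKI (`AUUAAY`, `ACUAAY`) and IGF2BP1 (`CAUU`, `CUUU`) are
exposed as configuration entries via `motif_presets()`.

For miRNAs, `seed_sites()` derives the seven canonical seed-match site
patterns from the mature sequence: `8mer-m1` (pairs miRNA nucleotides 1-8),
`8mer-A1` (nucleotides 2-8 with an A opposite position 1), `7mer-m1`,
`7mer-A1`, `7mer-m8`, `6mer2-7` and `6mer3-8`. For the A1 types the site's
3'-most base is the literal A, replacing position-1 pairing, as in the
standard seed-type nomenclature. `nonredundant_seed_scan()` assigns matches
greedily — longest type first in the stated preference order, ties at a
position credited to the most highly expressed miRNA, and any match
overlapping an accepted longer match suppressed.

`conversion_likelihood_profile()` aggregates, over all matches of equal
length, the per-offset probability of conversion given a reference T
(conversions over conversions plus non-conversions from all overlapping
reads — deliberately not normalised per match), alongside a per-match
nucleotide composition matrix relative to a uniform background and the
background conversion probability over all Ts of a reference region set.

## Signal-to-noise and positional statistics

`signal_to_noise()` is the ratio of matches per foreground nucleotide to
matches per background nucleotide. Foreground counts come from called
sites; the background set is built from expressed genes only, using the
longest transcript (or longest 3' UTR) per gene. Genes are called expressed
when their value exceeds the 80th percentile of background (gene-free)
probes, averaging replicate probe measurements and taking the per-gene
maximum probe; the percentile uses the linear-interpolation convention with
a strict inequality at the threshold (the convention is not dictated by the
statistic, so the common empirical-quantile default is used). Display
rounding is half-even to two decimals.

Positions along 3' UTRs are reported as the site midpoint fraction of the
UTR, scaled to 100% for genes with one annotated polyadenylation site and
200% for two or more. Per-miRNA ratios along the expression ranking are
smoothed with a centered 21-rank moving average (partial windows at the
edges; a window at least as long as the list collapses to the global mean).

## Evidence-ranked motif discovery

Regions (called sites) carry centered evidence $y^*_i$. For a motif with
target set $T_j$ of size $n_j$ out of $n$ regions:

$$e_j = \frac{1}{n_j}\sum_{i \in T_j} y^*_i,\qquad
  \hat\sigma_j = \sqrt{\hat\sigma^2 / n_j},\qquad
  S_j = A_j\, e_j / \hat\sigma_j$$

with $\hat\sigma^2$ the unbiased sample variance of the centered evidence
over all regions. The adjustment $A_j$ is implemented as
$\sqrt{1 - n_j/n}$ — it tends to 1 as $n_j/n \to 0$, matching the stated
small-target behaviour of the original enrichment score, and is exposed as
a pluggable function since its exact published form lives in the upstream
motif-discovery literature rather than in the enrichment model itself.
Evidence is mean-centered before scoring; this is what makes the
no-intercept regression formulation below coherent.

`cermit_search()` enumerates all non-degenerate 7-mers present in the
regions that reach a minimum target-set size of 5% of the regions, then
hill-climbs from the 50 best seeds over single-symbol degeneracy
substitutions and single-position extensions/contractions (lengths 6-10,
at most 3 degenerate positions), accepting the best strictly improving
move. The move set and acceptance rule are this package's choices. Ns at
motif ends constrain nothing and are trimmed from final motifs. Matching
during the search uses a k-mer-to-region index over the concrete
expansions of the degenerate motif, which is exactly equivalent to the
general scanner (a property the tests assert). The search returns motifs
ranked by score, the position frequency matrix of the top motif's match
instances, and the matches in decreasing order of region evidence.

## The miRNA enrichment regression

For Argonaute libraries the motif space is restricted to the seed types of
a supplied miRNA list. For seed type $j$ with indicator $x_j$ the model is

$$Y^* = Z_j\beta_j + \varepsilon,\qquad Z_j = (x_j, c_1, \dots, c_{16})$$

with the 16 overlapping dinucleotide counts per region, mean-centered and
scaled to unit sample standard deviation, as confounders — these absorb the
locally elevated AU content around genuine miRNA target sites that would
otherwise inflate seed scores. The fit is ordinary least squares without
intercept (evidence centered, confounders centered); the per-type score is
the indicator coefficient over its standard error, and the miRNA score
$S^{REG}$ is the mean over positively scoring types (0 when none is
positive; types matching no region, or every region, are excluded as
undefined). Rank-deficient designs drop the pivoted-out covariates with a
warning. Note that with a binary uncentered indicator the no-intercept
coefficient estimates $(1-p)\beta$ where $p = n_j/n$; the model is meant
for, and is tested in, the small-target regime where this distinction
vanishes.

Significance uses a permutation null: the evidence vector is permuted $B$
times (default 100; one permutation stream shared across seed types and
miRNAs for a fixed seed, making reruns byte-identical), $S^{REG}$ is
recomputed for each permutation, a Gaussian is fitted to the null scores,
and a miRNA is significant when its observed score exceeds the null mean
by more than 3 null SDs. Reported p-values are upper Gaussian tail values;
a zero-variance null degrades to a sign test and is flagged with a
warning. Ranked miRNAs are clustered greedily around centers: a miRNA
joins the first existing center whose canonical seed-site string shares an
identical substring of at least 7 nt, otherwise it founds a new cluster.
Scores are computed per miRNA and clustered afterwards.

## The simulator

`simulate_reference()` lays one transcript per chromosome (5' UTR, split
CDS with an intron, 3' UTR, intergenic flanks), on either genomic strand,
and plants crosslink sites at recorded positions: in `rbp` mode a T-rich
triplet at the crosslink followed by a concrete instance of the configured
motif; in `ago` mode a miRNA 8mer-m1 seed-match site with the crosslink T
one nucleotide upstream and conversions forbidden inside the seed
(seed protection), optionally with AU-enriched flanks.
`simulate_reads()` samples a configured number of reads over every planted
site (each read covers the crosslink; lengths uniform on 20-35 nt,
configurable down to the 13-nt mapping floor) plus uniform background
reads, and draws conversions *per read*: crosslink-window Ts convert with
probability 0.5 by default, all other covered Ts with 0.001. Because
molecules crosslink independently, per-position conversion fractions are
binomial — the estimator the profile machinery assumes. An optional RNase
bias upweights fragment boundaries that fall next to reference Gs. The
published protocol does not report a per-read crosslink conversion rate;
0.5 was fixed once as a realistic strong-crosslinking value and is
config-exposed.

Region-level generators (`simulate_evidence_regions()`,
`simulate_seed_regions()`) produce evidence-scored sequence sets for the
discovery models: standard-normal evidence with a motif planted across the
top-evidence tercile, or an additive seed effect on 5% of regions. The 5%
default matches the small-target regime the enrichment score is derived
for; region lengths are variable (50-70 nt) because fixed-length regions
make the dinucleotide counts exactly collinear (they sum to length minus
one).

What the simulator does *not* emulate: sequencing base-call errors, PCR
duplication, multimapping reads, RNA secondary structure, and transcript
expression heterogeneity. Passing the recovery tests therefore shows the
statistical machinery is correct under the generative model the method
assumes, not that every real library will behave as cleanly.

## Numerical choices and test scales

* $\lambda$ is the Gaussian kernel scale (SD) in nucleotides; planted-site
  recovery is stable for $\lambda \in \{2,3,4,5\}$ (asserted in the tests).
* Ties $k_{TC} = k_{TT}$ are background; signal runs separated by one or
  more background offsets become separate candidate sites before extension
  and merging.
* Density normalisation holds to $10^{-9}$; the classifier agrees exactly
  with a naive double-loop evaluation on randomly generated profiles up to
  $L = 200$.
* Test problem sizes: 50 transcripts / 30 planted sites at depth 20 for
  caller recovery; 500 regions for motif recovery; 2,000 regions, 100
  permutations and 6 decoy miRNAs for the seed regression; 200 noise
  replicates for coefficient coverage. These sizes give stable
  pass/fail behaviour at interactive runtimes.

## Known limitations

Site calling assumes ungapped, mismatch-only alignments; indels are
rejected at ingest. The by_read extension is non-iterative by design. The
percentile convention for expression thresholds and the exact adjustment
factor $A_j$ are this package's documented choices where the published
descriptions are silent or live upstream. Whether the original grouping
merged reads across strands is not documented; strand separation is this
package's position, for the chemistry reasons above.
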