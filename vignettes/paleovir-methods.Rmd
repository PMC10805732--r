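---
title: "Methods and design notes for paleovir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for paleovir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleovir)
```

`paleovir` analyses bacteriophage genomes recovered from ancient gut
metagenomes. This vignette documents the statistical models, the tunable
parameters, the synthetic-data generator that backs the test suite, and the
design decisions taken where the underlying methodology left genuine
choices.

## 1. Deamination damage model and authentication

Post-mortem cytosine deamination converts C to U (read as T) preferentially
at fragment ends, so reads from genuinely ancient templates show an excess of
C→T mismatches at their 5'-terminal positions. For one contig,
`compute_damage_profile()` tallies, for each read position
$i = 1, \dots, P$ (default $P = 20$, in read coordinates from the 5' end),
the number of positions whose aligned reference base is cytosine
($n_i$) and the subset read as thymine ($k_i$). Reverse-complement-flagged
reads are profiled from their own 5' end with both bases complemented, so a
C→T on the read strand is counted from a reference G→A; the reference FASTA
is authoritative and MD tags are ignored.

`fit_damage_model()` fits

$$d(i) = b + (d_1 - b)\, e^{-\lambda (i-1)},$$

by maximising $\sum_i \log \mathrm{Binom}(k_i \mid n_i, d(i))$ over
$(d_1, \lambda, b)$, against a null of constant $d(i) = b$. Parameters and
their meaning:

| parameter | meaning | default / bounds |
|---|---|---|
| $d_1$ | C→T probability at position 1 | fitted in $[10^{-6}, 0.99]$, $d_1 \ge b$ by construction |
| $\lambda$ | decay per position | fitted in $[10^{-3}, 10]$ |
| $b$ | background C→T probability | fitted in $[10^{-6}, 0.5]$ |
| `min_first_pos` | empirical freq[1] cut-off | 0.01 |

Optimisation uses L-BFGS-B with an analytic gradient from five fixed starting
points (ties broken by the first); a second pass from the best optimum
polishes convergence, which matters when per-position counts reach $10^6$
and the log-likelihood surface is extremely sharp.

The likelihood-ratio statistic is referred to $\chi^2_2$ and the
authentication score is $1 - p$. Two caveats are deliberate:

* Under the null, $d_1 = b$ lies on the boundary of the parameter space and
  $\lambda$ becomes unidentifiable, so the $\chi^2_2$ reference is
  *conservative*: null p-values concentrate near 1 rather than being
  uniform. This only makes the ancient call stricter; the test suite asserts
  the conservative direction rather than uniformity.
* The score threshold is not fixed but chosen from the score distribution by
  the Kneedle rule (`kneedle_threshold()`): normalise the sorted score curve
  to the unit square and return the score at maximum deviation from the
  chord; a curve within tolerance of the chord has no knee and `NULL` is
  returned (callers fall back to 0.5). The additional empirical
  `freq[1] >= 0.01` rule filters weakly damaged contigs whose signal could
  be sequencing noise; the cut-off is applied to the *empirical* frequency,
  not the fitted $d_1$, because the filter is meant to guard against model
  optimism on thin data.

## 2. Genome conservation probability

For a genome of $n$ sites evolving $t$ years at $r$ alterations per site per
year, each site is altered independently with probability
$p_t = 1 - (1-r)^t$ (compounded; a linear variant $p_t = \min(rt, 1)$ is
available and differs by under $3\times10^{-4}$ at $r \approx 10^{-4}$,
$t = 200$). The probability of remaining at least a fraction $q$ identical is

$$P\left(X \le \lfloor n(1-q)\rfloor\right), \qquad X \sim \mathrm{Binom}(n, p_t).$$

`prob_conserved()` sums the log binomial terms with a log-sum-exp
accumulator, so values far below double-precision underflow are reported via
`log10_prob` (at $n = 36{,}630$, $q = 0.977$, $r = 1.154\times10^{-4}$,
$t = 1300$ the result is $\sim 10^{-1313}$). `years_to_threshold()` exploits
monotonicity in $t$ and locates the smallest integer year by doubling plus
bisection; "approaches zero" is operationalised as probability $< 10^{-3}$.
The derived cut-off $m = \lfloor n(1-q) \rfloor$ is computed with a $10^{-9}$
tolerance because $1-q$ is not exactly representable in binary for common
thresholds (e.g. $q = 0.8$).

The model treats literature rates (including recombination-inclusive rates
for lytic phages) as i.i.d. per-site alteration probabilities and assumes a
direct ancestor–descendant relationship; both assumptions make it an upper
bound on the plausibility of long-term conservation under continuous
divergence.

## 3. ANI, AAI and clustering

**Fragment ANI** (`pairwise_ani()`): the shorter genome (ties broken
lexicographically by ID, which makes the result exactly symmetric) is cut
into 500-bp fragments, each locally aligned to the longer genome with
match 2 / mismatch −3 / gap open 5 / gap extend 2. A fragment counts as
aligned when the alignment covers at least 80 % of it; ANI is the
alignment-length-weighted mean identity over aligned fragments, and the
aligned fraction is reported against the shorter genome. The fragment size
and the 80 % rule are configuration, not dogma (`votu_config()`): they are
chosen to behave well from a few kb up to full phage genomes. For speed,
each fragment is first located on the subject by an exact 16-mer seed and
aligned within a ±300-bp window; if no seed matches or the windowed
alignment fails the coverage rule, the fragment is re-aligned against the
full subject, so the heuristic only short-circuits unambiguous placements.
Local alignment trims terminal mismatches, which biases ANI upward by about
+0.02 percentage points at 2–3 % divergence — negligible against the
sampling spread of the divergence process itself.

**vOTU clustering** (`votu_cluster()`): genomes sorted by length
(descending, ties by ID) join the first centroid with ANI ≥ 95 and aligned
fraction ≥ 85 (inclusive thresholds), else found a new cluster. The greedy
trace is deterministic and the output is always a total partition.

**AAI** (`pairwise_aai()`): all-vs-all local protein alignments (BLOSUM62,
gap open 11 / extend 1); hits need ≥30 % identity over ≥50 % of the shorter
protein, reciprocal best hits define shared genes, AAI is the unweighted
mean RBH identity, and the shared fraction is relative to the smaller
proteome (the convention used by modern gut-virome catalogues). The hit
filter replaces an e-value cut-off, which is not portable across aligners;
both knobs are exposed.

**Markov clustering** (`mcl_cluster()`): canonical MCL on the
column-stochastic matrix with self-loops set to each node's maximum incident
edge weight (1 for isolated nodes), expansion 2, inflation per rank
(family 1.2, genus 2.0), pruning at $10^{-8}$, convergence when the matrix
changes by less than $10^{-6}$. Graph edges require *strictly* greater AAI
and shared-gene percentages (matching the ">" phrasing of the rank
thresholds), whereas vOTU thresholds are inclusive (the "95 % ANI"
recommendation is a floor). Attractor supports are merged into a partition;
non-convergence within `max_iter` returns the current interpretation with a
warning.

## 4. Pair analysis of an ancient and a modern genome

`align_pair()` produces an optimal global alignment under the BLAST-style
scheme above, implemented in C++ (Gotoh three-state DP) with an optional
diagonal band; a 36-kb pair aligns in seconds at band 500–1000, while the
unbanded matrix is quadratic and guarded against absurd allocations. Banded
and unbanded alignments of substitution-only pairs agree in identity to
within 0.05 %.

Downstream consumers operate on alignment columns:

* `trim_flanks()` separates a prophage core from host-derived flanks as the
  largest contiguous query interval aligned in at least `min_presence`
  relatives. Co-optimal gap placements occasionally drop single columns from
  one relative's alignment, so a majority rule (`min_presence` below the
  total) is the robust choice when three or more relatives are available.
* `call_snvs()` reports one SNV per double-non-gap mismatch column
  (coordinates on the query's ungapped positions) and collapses maximal
  one-row gap runs into single indel events positioned at the last
  preceding query base.
* `window_identity()` tiles the alignment (window 100, step 50 columns) and
  flags windows below `mean − 3·sd` of all window identities: a localized
  diversity-generating-retroelement footprint stands out this way against a
  near-identical backbone, without any annotation input. The rule is a
  statistical convention, not a DGR detector.
* `per_gene_identity()` computes nucleotide identity over gene columns or,
  at the amino-acid level, re-aligns the translated gene pair locally
  (BLOSUM62, open 10 / extend 0.5, EMBOSS-like) and averages genes
  *unweighted*, so one divergent gene is visible against the mean rather
  than being swamped by genome length.

## 5. Microdiversity

`build_pileup()` attributes read bases to reference sites through a strict
M/I/D/S CIGAR walk (anything else is an error naming the record — silent
skipping hides data problems). Per-site diversity uses the unbiased
pairwise-difference form $\pi = 1 - \sum_a \binom{c_a}{2} / \binom{c}{2}$
over sites with coverage ≥ `min_cov` (default 5), and a site is *divergent*
when a non-reference allele reaches frequency ≥ 0.05 with count ≥ 2 — the
count floor suppresses singleton sequencing errors. Mapping-quality,
base-quality and read-pair filters of production strain profilers are
intentionally not reproduced; the definitions here are count-based and fully
configurable, which makes them exactly testable against closed forms.

## 6. What the simulator emulates — and what it does not

The generator exists so that every downstream stage has planted truth:

* `simulate_genome()`: i.i.d. bases at a given GC content.
* `evolve_genome()`: i.i.d. per-site substitutions at $p_t$ derived from
  $(r, t)$, uniform choice among the three alternative bases (no
  transition/transversion bias — no substitution matrix is assumed), no
  indels. The truth table lists every altered site; tests assert the
  mismatch count equals it exactly.
* `simulate_reads()`: fragment lengths from a normal distribution truncated
  to [20 bp, genome length] (mean 60 bp, sd 10 by default — short, as
  expected for degraded templates), uniform placement on both strands,
  damage applied in read orientation so the 5' pattern is strand-correct,
  then sequencing errors; Q37 flat qualities. Defaults of 30× coverage and
  60-bp reads are stand-ins for typical ancient-library behaviour, not a
  reconstruction of any particular library.
* `make_community()`: declared clusters share a simulated ancestor; each
  member diverges by $(100 - \mathrm{ANI})/200$ per site so expected
  pairwise member identity matches the declared within-cluster ANI. Ancient
  members receive damaged reads, modern members flat-background reads
  (default 0.002, the modern-control noise floor).

Not emulated: indel evolution, circular-genome read wrap-around,
quality-score error profiles, strand-specific library chemistry, reference
bias from a real mapper, environmental contamination mixtures. Passing tests
on these fixtures therefore demonstrate correctness of the statistics and
algorithms, not robustness to every artefact of real ancient libraries.

## 7. Reproducibility and problem sizes

Every stochastic operation takes an explicit integer seed and is
bit-reproducible; `run_end_to_end()` writes a JSON manifest of all
parameters and seeds, and re-running a configuration reproduces every output
byte for byte. The test suite works at deliberately modest sizes — read sets
of 10⁴–10⁵ for recovery checks (binomial standard errors a few 10⁻³),
genomes of 2–37 kb, twenty replicate communities for classifier operating
characteristics — chosen so the full suite completes in a few minutes while
keeping every assertion's sampling band well separated from its threshold.
`scripts/acceptance.R` recomputes the headline quantities at 36,630 sites
and 2×10⁵–10⁶ reads in about a minute.

## 8. Known limitations

* The likelihood-ratio score is not calibrated to PyDamage's trained
  "predicted accuracy"; thresholds learned for that tool do not transfer.
* ANI at very high divergence (<80 % identity) is reported as 0 when no
  fragment passes the coverage rule — the estimator is designed for the
  clustering regime, not for distant homology detection.
* `trim_flanks()` consumes pairwise alignments in a star layout; it does
  not build a multiple alignment.
* CheckV-style completeness tiers are consumed as an input column only and
  never recomputed.
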