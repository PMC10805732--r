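# paleovir

Reconstruction of bacteriophage genomes from ancient metagenomes (palaeofaeces
and gut-content samples) poses two linked questions: *is a contig genuinely
ancient*, and *how does an ancient genome relate to its modern relatives*?
`paleovir` implements the computational core of that analysis for R users
working in ancient-DNA metagenomics:

* **Deamination authentication** (`compute_damage_profile()`,
  `fit_damage_model()`, `kneedle_threshold()`, `authenticate_contigs()`).
  Ancient DNA carries cytosine deamination concentrated at 5' read ends,
  observed as C→T mismatches whose frequency decays into the read. The
  per-position frequency `d(i) = b + (d1 − b)·e^(−λ(i−1))` is fitted by
  maximum likelihood against a flat-background null; contigs pass when their
  likelihood-ratio score clears a knee-point (Kneedle) threshold **and** the
  empirical first-position frequency is at least 0.01.
* **Viral genome clustering** (`pairwise_ani()`, `votu_cluster()`,
  `pairwise_aai()`, `similarity_graph()`, `mcl_cluster()`). Species-level
  vOTUs use fragment-based ANI with the MIUViG thresholds (≥95 % ANI over
  ≥85 % of the shorter genome, greedy length-sorted centroids). Genus- and
  family-rank groups come from Markov clustering of reciprocal-best-hit AAI
  graphs (edges at >50 % AAI / >20 % shared genes with inflation 2 for
  genera; >20 % / >10 % with inflation 1.2 for families).
* **Genome conservation model** (`prob_conserved()`,
  `years_to_threshold()`). For a genome of *n* sites evolving at *r*
  alterations/site/year, the probability of retaining at least a fraction
  *q* of sites unaltered after *t* years is
  `P(X ≤ ⌊n(1−q)⌋)`, `X ~ Binomial(n, 1−(1−r)^t)`, evaluated in log space so
  that astronomically small probabilities remain reportable.
* **Ancient-vs-modern pair analysis** (`align_pair()`, `trim_flanks()`,
  `call_snvs()`, `window_identity()`, `per_gene_identity()`): banded global
  alignment, prophage core/host-flank separation, SNV and indel-event
  calling, sliding-window identity for hypervariable (DGR-type) regions, and
  per-gene amino-acid identity.
* **Microdiversity** (`build_pileup()`, `nucleotide_diversity()`,
  `divergent_sites()`): per-site nucleotide diversity
  `π = 1 − Σ_a C(c_a,2)/C(c,2)` and divergent-site counts from read pileups.
* **A truth-tracked simulator** (`simulate_genome()`, `evolve_genome()`,
  `simulate_reads()`, `plant_genes()`, `make_community()`) generating
  genomes, evolved descendants, damaged/undamaged read sets (FASTA / FASTQ /
  SAM / GFF3) with exact substitution and damage truth tables, so the whole
  pipeline is testable without downloads.

## Worked example

Simulate a six-genome community (three ancient genomes with damage amplitude
0.042, three modern controls at background 0.002), profile the damage and
authenticate:

```r
library(paleovir)

com <- make_community(
  n_ancient = 3, n_modern = 3,
  rp = read_sim_params(coverage = 120, seed = 1),
  dp = damage_params(d1 = 0.042, lam = 0.3, background = 0.001),
  genome_length = 5000L, seed = 42)

profiles <- lapply(com$genomes, function(g)
  compute_damage_profile(com$reads[com$reads$rname == g$id, ], g))
fits   <- lapply(profiles, fit_damage_model)
scores <- vapply(fits, `[[`, 1, "score")
thr    <- kneedle_threshold(scores)
authenticate_contigs(fits, profiles, if (is.null(thr)) 0.5 else thr)
```

```
    contig_id passed                                            reasons       freq1
1 g01_ancient   TRUE                                                    0.033830044
2 g02_ancient   TRUE                                                    0.029996104
3 g03_ancient   TRUE                                                    0.044806517
4  g04_modern  FALSE below_score_threshold;first_position_below_minimum 0.002350176
5  g05_modern  FALSE below_score_threshold;first_position_below_minimum 0.002427184
6  g06_modern  FALSE below_score_threshold;first_position_below_minimum 0.001543210
```

All six contigs are labelled correctly: the ancient genomes show empirical
first-position C→T frequencies of 0.030–0.045 (scattered around the planted
0.042) and significant damage fits, while the modern controls sit at their
~0.002 noise floor, below both the score threshold and the 0.01 first-position
cut-off.

How plausible is it that a 36,630-bp phage genome stays ≥97.7 % identical
over 1300 years, at the lowest (temperate-phage) substitution rate reported
for phages?

```r
p <- conservation_params(n = 36630, q = 0.977, rate = 1.154e-4, years = 1300)
prob_conserved(p)
#> $prob        0
#> $log10_prob  -1313.284
#> $p_site      0.1394
#> $m           842

years_to_threshold(36630, 0.977, 1.154e-4, prob_target = 1e-3)
#> [1] 224
```

The retention probability is ~10^-1313 at 1300 years and already falls below
10^-3 after 224 years — two nearly identical genomes a millennium apart are
essentially impossible under continuous independent divergence, pointing at a
conserved prophage lifestyle.

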