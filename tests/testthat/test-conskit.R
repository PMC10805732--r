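test_that("global alignment matches an exhaustive DP oracle on toy strings", {
  al <- align_pair("ACGT", "ACGT")
  expect_equal(al$aligned_a, "ACGT")
  expect_equal(al$aligned_b, "ACGT")
  expect_equal(al$score, 8)

  al2 <- align_pair("ACGT", "AGT")
  s2 <- call_snvs(al2)
  expect_equal(nrow(s2$snvs), 0)
  expect_equal(s2$indel_events$kind, "deletion")
  expect_equal(s2$indel_events$length, 1)
  expect_equal(al2$score, oracle_align_score("ACGT", "AGT"))

  withr::with_seed(5, {
    for (k in 1:10) {
      a <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), TRUE), collapse = "")
      expect_equal(align_pair(a, b)$score, oracle_align_score(a, b))
      # global symmetric scoring: score invariant under swapping inputs
      expect_equal(align_pair(a, b)$score, align_pair(b, a)$score)
    }
  })
})

test_that("banded and unbanded alignment agree on diverged genome pairs", {
  g <- simulate_genome(5000, 0.5, seed = 31)
  ev <- evolve_genome(g, evolution_params(0.023, 1, "linear", seed = 32))
  full <- align_pair(g, ev$genome)
  band <- align_pair(g, ev$genome, band = 500)
  ident <- function(al) 100 * mean(al$chars_a == al$chars_b & al$chars_a != "-")
  expect_lt(abs(ident(full) - ident(band)), 0.05)
  expect_equal(full$score, band$score)
  expect_error(align_pair(strrep("A", 1000), strrep("A", 100), band = 500),
               "band infeasible")
})

test_that("flank trimming recovers planted host flanks around a shared core", {
  core <- simulate_genome(2000, 0.5, seed = 41)$seq
  query <- genome_record("q", paste0(
    simulate_genome(241, 0.5, seed = 42)$seq, core,
    simulate_genome(119, 0.5, seed = 43)$seq))
  rels <- lapply(44:46, function(s)
    evolve_genome(genome_record("rel", core),
                  evolution_params(0.01, 1, "linear", seed = s))$genome)
  alns <- lapply(rels, function(r) align_pair(query, r))
  tf <- trim_flanks(alns, min_presence = 3)
  expect_lt(abs(tf$left_flank - 241), 3)
  expect_lt(abs(tf$right_flank - 119), 3)

  noflank <- trim_flanks(list(align_pair(genome_record("a", core),
                                         genome_record("b", core))))
  expect_equal(noflank$core_start, 1)
  expect_equal(noflank$core_end, nchar(core))
  expect_error(trim_flanks(alns, min_presence = 5), "exceeds")
})

test_that("SNV calling is exact on planted substitutions and indels", {
  g <- simulate_genome(6000, 0.5, seed = 51)
  for (k in c(0, 1, 5, 50, 842)) {
    x <- strsplit(g$seq, "")[[1]]
    idx <- withr::with_seed(52 + k, sample(6000, k))
    x[idx] <- vapply(x[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
    aln <- pairwise_alignment(g$seq, paste(x, collapse = ""))
    out <- call_snvs(aln)
    expect_equal(nrow(out$snvs), k)
    expect_equal(nrow(out$indel_events), 0)
    if (k > 0) expect_setequal(out$snvs$position_ref, idx)
  }

  # planted substitutions plus one 3-bp deletion, built column by column
  a <- "ACGTACGTACGTACGTACGT"
  b <- "ACCTACGTA---ACGAAGGT"
  aln <- pairwise_alignment(a, b)
  out <- call_snvs(aln)
  expect_equal(out$indel_events,
               data.frame(position_ref = 9L, length = 3L, kind = "deletion"))
  expect_equal(nrow(out$snvs), sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]] &
                                     strsplit(b, "")[[1]] != "-"))
  expect_true(all(out$snvs$base_a != out$snvs$base_b))
})

test_that("window identity flags only the planted hypervariable region", {
  g <- simulate_genome(8000, 0.5, seed = 61)
  ident <- window_identity(pairwise_alignment(g$seq, g$seq))
  expect_true(all(ident$identity == 100))
  expect_false(any(ident$flagged))

  x <- strsplit(g$seq, "")[[1]]
  region <- 4001:4600
  hit <- withr::with_seed(62, region[runif(600) < 0.2])
  x[hit] <- vapply(x[hit], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  # sprinkle light background divergence (~0.5%)
  bg <- withr::with_seed(63, setdiff(which(runif(8000) < 0.005), region))
  x[bg] <- vapply(x[bg], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  wi <- window_identity(pairwise_alignment(g$seq, paste(x, collapse = "")))
  flagged <- wi[wi$flagged, ]
  expect_gt(nrow(flagged), 0)
  expect_true(all(flagged$window_end >= 4001 & flagged$window_start <= 4600))

  short <- window_identity(pairwise_alignment(strrep("A", 80), strrep("A", 80)))
  expect_equal(nrow(short), 1)
  expect_equal(short$window_end, 80)
})

test_that("per-gene identity is exact and the mean is unweighted", {
  g <- simulate_genome(3000, 0.5, seed = 71)
  pg <- plant_genes(g, 2, 300, seed = 72)
  self <- per_gene_identity(pairwise_alignment(pg$genome$seq, pg$genome$seq),
                            pg$genes, level = "amino_acid")
  expect_true(all(self$per_gene$identity == 100))
  expect_equal(self$mean_identity, 100)

  # recode 2 amino acids of gene 1 (interior, both codon positions 1 -> new aa)
  x <- strsplit(pg$genome$seq, "")[[1]]
  s1 <- pg$genes$start[1]
  for (codon in c(40, 60)) {
    p <- s1 + 3 * (codon - 1)  # first base of that codon
    x[p:(p + 2)] <- c("T", "G", "G")  # tryptophan
  }
  mutated <- paste(x, collapse = "")
  res <- per_gene_identity(pairwise_alignment(pg$genome$seq, mutated),
                           pg$genes, level = "amino_acid")
  # gene 1: 100-aa protein with at most 2 changed residues -> >= 98.0
  expect_gte(res$per_gene$identity[1], 98.0)
  expect_lte(res$per_gene$identity[1], 100)
  expect_equal(res$per_gene$identity[2], 100)
  expect_equal(res$mean_identity, mean(res$per_gene$identity))

  # unweighted mean: short gene with 1 aa change vs long identical gene
  gg <- simulate_genome(2000, 0.5, seed = 73)
  pg2 <- plant_genes(gg, 2, 150, seed = 74)
  nt <- per_gene_identity(pairwise_alignment(pg2$genome$seq, pg2$genome$seq),
                          pg2$genes, level = "nucleotide")
  expect_equal(nt$mean_identity, 100)
})

test_that("fully deleted genes are reported missing and excluded", {
  a <- paste0(strrep("ACGT", 30), strrep("GGCA", 30))  # 240 bp
  genes <- data.frame(gene_id = c("g1", "g2"), start = c(1L, 121L),
                      end = c(120L, 240L), strand = "+")
  aligned_b <- paste0(substr(a, 1, 120), strrep("-", 120))
  aln <- pairwise_alignment(a, aligned_b)
  res <- per_gene_identity(aln, genes, level = "nucleotide")
  expect_true(res$per_gene$missing[2])
  expect_equal(res$mean_identity, res$per_gene$identity[1])
  expect_error(per_gene_identity(aln, data.frame(gene_id = "bad", start = 1L,
                                                 end = 999L, strand = "+")),
               "bounds")
})

test_that("conservation probabilities match closed forms and the pbinom oracle", {
  expect_equal(prob_conserved(conservation_params(100, 0.9, 0, 500))$prob, 1)
  expect_equal(prob_conserved(conservation_params(100, 0.9, 1e-3, 0))$prob, 1)

  toy <- prob_conserved(conservation_params(10, 0.8, 0.1, 1, "linear"))
  expect_equal(toy$prob, 0.9^10 + 10 * 0.1 * 0.9^9 + 45 * 0.01 * 0.9^8,
               tolerance = 1e-12)

  # log-space agreement with R's own binomial CDF across a parameter grid
  for (n in c(10, 100, 1000)) for (r in c(1e-4, 1e-3, 1e-2)) for (t in c(50, 500)) {
    p <- conservation_params(n, 0.95, r, t)
    mine <- prob_conserved(p)
    orac <- pbinom(p$m, n, alteration_prob(r, t), log.p = TRUE) / log(10)
    expect_equal(mine$log10_prob, orac, tolerance = 1e-10)
  }

  deep <- prob_conserved(conservation_params(36630, 0.977, 1.154e-4, 1300))
  expect_lt(deep$log10_prob, -300)

  # strictly decreasing in t and in r
  probs_t <- vapply(c(50, 100, 200, 400), function(t)
    prob_conserved(conservation_params(5000, 0.98, 2e-4, t))$log10_prob, 1)
  expect_true(all(diff(probs_t) < 0))
  probs_r <- vapply(c(1e-4, 2e-4, 4e-4), function(r)
    prob_conserved(conservation_params(5000, 0.98, r, 200))$log10_prob, 1)
  expect_true(all(diff(probs_r) < 0))
})

test_that("years_to_threshold agrees with a direct scan and handles edge cases", {
  expect_equal(years_to_threshold(1000, 0.99, 0), Inf)
  expect_equal(years_to_threshold(1000, 0.99, 1e-4, prob_target = 1), 0L)

  yt <- years_to_threshold(2000, 0.99, 5e-4, prob_target = 0.01)
  scan <- which(vapply(1:200, function(t)
    prob_conserved(conservation_params(2000, 0.99, 5e-4, t))$prob < 0.01,
    TRUE))[1]
  expect_equal(yt, scan)

  phage_scale <- years_to_threshold(36630, 0.977, 1.154e-4, prob_target = 1e-3)
  expect_gte(phage_scale, 201)
  expect_lte(phage_scale, 260)
})

test_that("compound and linear clocks differ negligibly at phage scales", {
  d <- abs(alteration_prob(1.154e-4, 200, "compound") -
             alteration_prob(1.154e-4, 200, "linear"))
  expect_lt(d, 3e-4)
})
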