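test_that("fragment ANI recovers identity on planted genome pairs", {
  g <- simulate_genome(10000, 0.5, seed = 1)
  self <- pairwise_ani(g, g)
  expect_equal(self$ani, 100)
  expect_equal(self$af_shorter, 100)

  # exactly 300 planted substitutions -> global identity 97.0
  x <- strsplit(g$seq, "")[[1]]
  idx <- withr::with_seed(2, sample(10000, 300))
  x[idx] <- vapply(x[idx], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  mut <- genome_record("mut", paste(x, collapse = ""))
  r <- pairwise_ani(g, mut)
  expect_lt(abs(r$ani - 97.0), 0.3)
  expect_gt(r$af_shorter, 99)
})

test_that("unrelated genomes fall below the alignment-fraction threshold", {
  for (s in 1:3) {
    a <- simulate_genome(10000, 0.5, seed = 100 + s)
    b <- simulate_genome(10000, 0.5, seed = 200 + s, id = "b")
    r <- pairwise_ani(a, b)
    expect_lt(r$af_shorter, 85)
  }
})

test_that("ANI is exactly symmetric, including equal-length ties", {
  a <- simulate_genome(4000, 0.5, seed = 11, id = "aa")
  ev <- evolve_genome(a, evolution_params(0.02, 1, "linear", seed = 12), id = "zz")
  r1 <- pairwise_ani(a, ev$genome)
  r2 <- pairwise_ani(ev$genome, a)
  expect_identical(r1$ani, r2$ani)
  expect_identical(r1$af_shorter, r2$af_shorter)
})

test_that("greedy vOTU clustering follows the documented trace", {
  fake <- function(id, len) genome_record(id, strrep("A", len))
  res <- function(a, b, ani, af)
    data.frame(id_a = a, id_b = b, ani = ani, af_shorter = af)

  g2 <- list(fake("A", 12000), fake("B", 10000))
  cs <- votu_cluster(g2, res("A", "B", 96, 90))
  expect_equal(length(unique(cs$membership)), 1)
  cs2 <- votu_cluster(g2, res("A", "B", 94, 90))
  expect_equal(length(unique(cs2$membership)), 2)

  # chain: B joins centroid A; C fails against centroid A and founds its own
  g3 <- list(fake("A", 12000), fake("B", 10000), fake("C", 8000))
  r3 <- rbind(res("A", "B", 96, 90), res("B", "C", 96, 90), res("A", "C", 92, 90))
  cs3 <- membership_of(votu_cluster(g3, r3))
  expect_identical(cs3[["A"]], cs3[["B"]])
  expect_false(cs3[["C"]] == cs3[["A"]])

  single <- votu_cluster(list(fake("solo", 5000)),
                         res("solo", "solo", 100, 100))
  expect_equal(unname(single$membership), "solo")
  expect_error(votu_cluster(list(fake("X", 100), fake("X", 100)),
                            res("X", "X", 100, 100)), "duplicate")
})

test_that("vOTU clustering recovers planted community partitions exactly", {
  for (s in 1:5) {
    com <- make_community(
      6, 0,
      cluster_spec = list(list(members = 2, within_ani = 97),
                          list(members = 2, within_ani = 97),
                          list(members = 2, within_ani = 97)),
      rp = read_sim_params(coverage = 0.1, seed = 1),
      genome_length = 3000, seed = 300 + s)
    cs <- votu_cluster(com$genomes)
    truth <- setNames(com$truth$labels$cluster_id, com$truth$labels$genome_id)
    got <- membership_of(cs)[names(truth)]
    expect_equal(ari(got, truth), 1.0)
    # every output is a total partition
    expect_setequal(names(cs$membership), names(truth))
    expect_false(anyNA(cs$membership))
  }
})

test_that("AAI of identical, nested and mutated proteomes matches definitions", {
  g <- simulate_genome(6000, 0.5, seed = 21)
  prot <- plant_genes(g, 10, 450, seed = 22)$proteins

  full <- pairwise_aai(prot, prot)
  expect_equal(full$aai, 100)
  expect_equal(full$shared_fraction, 100)

  nested <- pairwise_aai(prot, prot[1:5])
  expect_equal(nested$shared_fraction, 100)  # denominator: smaller proteome
  expect_equal(nested$aai, 100)

  # one 100-aa pair with exactly 2 interior mismatches + one identical 50-aa pair
  p100 <- random_protein(100, seed = 23)
  p50 <- random_protein(50, seed = 24)
  mut <- p100
  for (pos in 40:41) {
    repl <- if (substr(p100, pos, pos) == "W") "G" else "W"
    substr(mut, pos, pos) <- repl
  }
  r <- pairwise_aai(c(x = p100, y = p50), c(x2 = mut, y2 = p50))
  expect_equal(r$n_shared, 2)
  expect_equal(r$aai, (98 + 100) / 2)

  expect_error(pairwise_aai(character(), prot), "empty")
})

test_that("similarity graph applies strict threshold semantics", {
  fam <- taxon_level_config("family")
  res <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                    aai = c(20.0, 55, 21), shared_fraction = c(50, 25, 9))
  g <- similarity_graph(res, fam)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)           # only a-c: 55 > 20 and 25 > 10
  expect_equal(igraph::E(g)$weight, 55)

  gen <- taxon_level_config("genus")
  g2 <- similarity_graph(res, gen)
  expect_equal(igraph::ecount(g2), 1)          # a-c again: 55 > 50, 25 > 20

  g0 <- similarity_graph(res[0, ], fam)
  expect_equal(igraph::ecount(g0), 0)
})

test_that("MCL handles cliques, barbells and edgeless graphs", {
  two <- igraph::disjoint_union(igraph::make_full_graph(4),
                                igraph::make_full_graph(4))
  igraph::V(two)$name <- letters[1:8]
  for (infl in c(1.2, 2, 4)) {
    m <- membership_of(mcl_cluster(two, infl))
    expect_equal(length(unique(m)), 2)
    expect_equal(length(unique(m[1:4])), 1)
  }

  barbell <- igraph::disjoint_union(igraph::make_full_graph(5),
                                    igraph::make_full_graph(5))
  igraph::V(barbell)$name <- letters[1:10]
  igraph::E(barbell)$weight <- 50
  barbell <- igraph::add_edges(barbell, c(5, 6), weight = 5)
  n2 <- length(unique(mcl_cluster(barbell, 2)$membership))
  n12 <- length(unique(mcl_cluster(barbell, 1.2)$membership))
  expect_equal(n2, 2)
  expect_lte(n12, 2)                          # coarser or equal at low inflation

  empty7 <- igraph::make_empty_graph(7, directed = FALSE)
  igraph::V(empty7)$name <- paste0("n", 1:7)
  expect_equal(length(unique(mcl_cluster(empty7, 2)$membership)), 7)
})

test_that("MCL agrees with an independent reference implementation", {
  withr::with_seed(42, {
    for (rep in 1:8) {
      n <- sample(5:10, 1)
      adj <- matrix(0, n, n)
      # planted two-block structure with sparse noise
      split_at <- sample(2:(n - 1), 1)
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        same <- (i <= split_at) == (j <= split_at)
        w <- if (same && runif(1) < 0.9) runif(1, 20, 60)
             else if (!same && runif(1) < 0.15) runif(1, 1, 5) else 0
        adj[i, j] <- adj[j, i] <- w
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               weighted = TRUE)
      igraph::V(g)$name <- paste0("v", seq_len(n))
      mine <- membership_of(mcl_cluster(g, 2))[paste0("v", seq_len(n))]
      ref <- oracle_mcl(adj, 2)
      expect_equal(ari(mine, ref), 1.0)
    }
  })
})

test_that("MCL never merges disconnected components", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      g1 <- igraph::sample_gnp(5, 0.7)
      g2 <- igraph::sample_gnp(5, 0.7)
      g <- igraph::disjoint_union(g1, g2)
      igraph::V(g)$name <- paste0("v", 1:10)
      comp <- igraph::components(g)$membership
      m <- membership_of(mcl_cluster(g, 1.2))[paste0("v", 1:10)]
      for (cl in unique(m))
        expect_equal(length(unique(comp[m == cl])), 1)
    }
  })
})

test_that("MCL cluster count is non-decreasing in inflation on clique chains", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  igraph::V(g)$name <- paste0("v", 1:12)
  igraph::E(g)$weight <- 40
  g <- igraph::add_edges(g, c(4, 5, 8, 9), weight = 8)  # weak bridges
  counts <- vapply(c(1.2, 1.5, 2, 3, 5), function(i)
    length(unique(mcl_cluster(g, i)$membership)), 1)
  expect_true(all(diff(counts) >= 0))
})
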