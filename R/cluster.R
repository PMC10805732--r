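#' Configuration for species-level (vOTU) clustering
#'
#' Genomes are grouped at the species rank when they share at least
#' `ani_min` % average nucleotide identity over at least `af_min` % of the
#' shorter genome. ANI is computed CheckV-style: the shorter genome is cut
#' into `fragment_len` windows, each locally aligned to the longer genome;
#' fragments whose alignment covers at least `min_fragment_cov` of their
#' length count as aligned.
#'
#' @param ani_min,af_min Percentage thresholds (inclusive).
#' @param fragment_len Fragment size in bp.
#' @param min_fragment_cov Minimum fraction of a fragment that must be
#'   aligned for the fragment to count.
#' @return A list of class `votu_config`.
#' @export
votu_config <- function(ani_min = 95, af_min = 85, fragment_len = 500L,
                        min_fragment_cov = 0.8) {
  stopifnot(ani_min > 0, ani_min <= 100, af_min > 0, af_min <= 100,
            fragment_len >= 100, min_fragment_cov > 0, min_fragment_cov <= 1)
  structure(list(ani_min = ani_min, af_min = af_min,
                 fragment_len = as.integer(fragment_len),
                 min_fragment_cov = min_fragment_cov),
            class = "votu_config")
}

#' Configuration for genus/family AAI clustering
#'
#' Edges are kept between genome pairs with AAI strictly above `aai_min` %
#' and shared-gene fraction strictly above `shared_min` %; Markov clustering
#' then partitions the graph with the given inflation. Defaults follow the
#' MGV-lineage convention: family 20/10 at inflation 1.2, genus 50/20 at
#' inflation 2.
#'
#' @param level `"family"` or `"genus"`.
#' @return A list of class `taxon_level_config`.
#' @export
taxon_level_config <- function(level = c("family", "genus")) {
  level <- match.arg(level)
  if (level == "family")
    structure(list(level = level, aai_min = 20, shared_min = 10,
                   inflation = 1.2), class = "taxon_level_config")
  else
    structure(list(level = level, aai_min = 50, shared_min = 20,
                   inflation = 2.0), class = "taxon_level_config")
}

.pv_cache <- new.env(parent = emptyenv())

nuc_mat <- function() {
  if (is.null(.pv_cache$nuc))
    .pv_cache$nuc <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                              mismatch = -3,
                                                              baseOnly = TRUE)
  .pv_cache$nuc
}

blosum62 <- function() {
  if (is.null(.pv_cache$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pv_cache$b62 <- get("BLOSUM62", envir = e)
  }
  .pv_cache$b62
}

# locate a fragment on the subject by exact k-mer seeding; returns a subject
# window [lo, hi] or NULL when no seed matches
seed_window <- function(frag, subject, k = 16L, margin = 300L) {
  fl <- nchar(frag)
  if (fl < k) return(NULL)
  offs <- unique(pmax(1L, as.integer(round(c(0, 0.25, 0.5, 0.75, 1) * (fl - k))) + 1L))
  for (o in offs) {
    hits <- Biostrings::matchPattern(substr(frag, o, o + k - 1L), subject)
    if (length(hits) >= 1L) {
      s <- Biostrings::start(hits)[1]
      lo <- max(1L, s - o + 1L - margin)
      hi <- min(length(subject), s - o + fl + margin)
      return(c(lo, hi))
    }
  }
  NULL
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' The shorter genome (ties broken by lexicographic ID) is cut into
#' consecutive fragments which are locally aligned to the longer genome
#' (match 2, mismatch -3, gap open 5, gap extend 2). A fragment counts as
#' aligned when its alignment covers at least the configured fraction of
#' the fragment. ANI is the alignment-length-weighted mean percent identity
#' over aligned fragments; the aligned fraction is reported relative to the
#' shorter genome. An exact k-mer seed localises each fragment on the
#' subject before alignment; fragments with no seed, or whose windowed
#' alignment falls below the coverage rule, fall back to a full-subject
#' alignment, so the heuristic only accelerates the common case.
#'
#' @param a,b [genome_record()]s.
#' @param cfg A [votu_config()].
#' @return One-row data.frame with `id_a`, `id_b`, `ani`, `af_shorter` (both
#'   percentages; `ani` is 0 when nothing aligns).
#' @export
pairwise_ani <- function(a, b, cfg = votu_config()) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"),
            inherits(cfg, "votu_config"))
  # the shorter genome is always the fragmented one; ties by lexicographic id
  swap <- (a$length > b$length) || (a$length == b$length && a$id > b$id)
  short <- if (swap) b else a
  long  <- if (swap) a else b

  fl <- cfg$fragment_len
  starts <- seq(1L, short$length, by = fl)
  frags <- substring(short$seq, starts, pmin(starts + fl - 1L, short$length))
  subject <- Biostrings::DNAString(long$seq)

  tot_id <- 0; tot_len <- 0; tot_cov <- 0
  for (fr in frags) {
    flen <- nchar(fr)
    if (flen < 20L) next
    win <- seed_window(fr, subject)
    res <- NULL
    if (!is.null(win)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(fr), subject[win[1]:win[2]], type = "local",
        substitutionMatrix = nuc_mat(), gapOpening = 5, gapExtension = 2)
      cov <- Biostrings::width(Biostrings::pattern(al)@range) / flen
      if (cov >= cfg$min_fragment_cov) res <- al
    }
    if (is.null(res)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(fr), subject, type = "local",
        substitutionMatrix = nuc_mat(), gapOpening = 5, gapExtension = 2)
      cov <- Biostrings::width(Biostrings::pattern(al)@range) / flen
      if (cov >= cfg$min_fragment_cov) res <- al
    }
    if (is.null(res)) next
    aln_len <- nchar(as.character(Biostrings::pattern(res)))
    tot_id <- tot_id + Biostrings::pid(res, type = "PID1") * aln_len
    tot_len <- tot_len + aln_len
    tot_cov <- tot_cov + Biostrings::width(Biostrings::pattern(res)@range)
  }
  ani <- if (tot_len > 0) tot_id / tot_len else 0
  af <- min(100, 100 * tot_cov / short$length)
  data.frame(id_a = a$id, id_b = b$id, ani = ani, af_shorter = af,
             stringsAsFactors = FALSE)
}

#' Cluster set
#'
#' A disjoint, total partition of genome IDs.
#'
#' @param membership Named character vector mapping `genome_id` to
#'   `cluster_id`.
#' @param centroids Optional character vector of centroid genome IDs (vOTU
#'   mode).
#' @return An object of class `cluster_set`.
#' @export
cluster_set <- function(membership, centroids = NULL) {
  stopifnot(is.character(membership), !is.null(names(membership)),
            !anyNA(membership), !any(duplicated(names(membership))))
  structure(list(membership = membership, centroids = centroids),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d genomes in %d clusters\n",
              length(x$membership), length(unique(x$membership))))
  invisible(x)
}

#' @export
as.data.frame.cluster_set <- function(x, ...) {
  data.frame(genome_id = names(x$membership),
             cluster_id = unname(x$membership),
             centroid = names(x$membership) %in% (x$centroids %||% character()),
             stringsAsFactors = FALSE, row.names = NULL)
}

ani_key <- function(a, b) paste(a, b, sep = "\r")

#' Greedy species-level (vOTU) clustering
#'
#' Genomes are sorted by length (descending; ties by ID) and each genome
#' joins the first existing centroid with `ani >= ani_min` and
#' `af_shorter >= af_min`, otherwise it founds a new cluster. Missing pairs
#' are computed on demand with [pairwise_ani()].
#'
#' @param genomes List of [genome_record()]s (unique IDs).
#' @param results Optional precomputed data.frame of [pairwise_ani()] rows.
#' @param cfg A [votu_config()].
#' @return A [cluster_set()] with centroids flagged.
#' @export
votu_cluster <- function(genomes, results = NULL, cfg = votu_config()) {
  ids <- vapply(genomes, `[[`, "", "id")
  if (any(duplicated(ids))) stopf("duplicate genome IDs")
  names(genomes) <- ids
  lens <- vapply(genomes, `[[`, 1L, "length")
  ord <- order(-lens, ids)

  cache <- new.env(parent = emptyenv())
  if (!is.null(results)) {
    for (r in seq_len(nrow(results))) {
      v <- results[r, c("ani", "af_shorter")]
      assign(ani_key(results$id_a[r], results$id_b[r]), v, envir = cache)
      assign(ani_key(results$id_b[r], results$id_a[r]), v, envir = cache)
    }
  }
  get_ani <- function(ga, gb) {
    key <- ani_key(ga$id, gb$id)
    if (!exists(key, envir = cache)) {
      v <- pairwise_ani(ga, gb, cfg)[, c("ani", "af_shorter")]
      assign(key, v, envir = cache)
      assign(ani_key(gb$id, ga$id), v, envir = cache)
    }
    get(key, envir = cache)
  }

  centroids <- character()
  membership <- setNames(character(length(ids)), ids[ord])
  for (id in ids[ord]) {
    placed <- FALSE
    for (cid in centroids) {
      v <- get_ani(genomes[[id]], genomes[[cid]])
      if (v$ani >= cfg$ani_min && v$af_shorter >= cfg$af_min) {
        membership[id] <- cid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, id)
      membership[id] <- id
    }
  }
  cluster_set(membership[ids], centroids)
}

#' Average amino-acid identity between two proteomes
#'
#' All-vs-all local protein alignment (BLOSUM62, gap open 11 / extend 1).
#' Hits require at least `min_identity` % identity over at least
#' `min_coverage` % of the shorter protein; reciprocal best hits (by
#' alignment score, ties to the first protein) define shared genes. AAI is
#' the unweighted mean identity over RBH pairs and the shared fraction is
#' reported relative to the smaller proteome.
#'
#' @param proteome_a,proteome_b Named character vectors of amino-acid
#'   sequences (or `AAStringSet`).
#' @param min_identity,min_coverage Hit filter (percent).
#' @return One-row data.frame with `id_a`, `id_b` (attr-less placeholder
#'   names when unnamed), `aai`, `shared_fraction`, `n_shared`.
#' @export
pairwise_aai <- function(proteome_a, proteome_b, min_identity = 30,
                         min_coverage = 50) {
  pa <- as.character(proteome_a); pb <- as.character(proteome_b)
  if (!length(pa) || !length(pb)) stopf("empty proteome")
  na <- length(pa); nb <- length(pb)
  score <- pid <- cov <- matrix(0, na, nb)
  paset <- Biostrings::AAStringSet(pa)
  B62 <- blosum62()
  for (j in seq_len(nb)) {
    al <- Biostrings::pairwiseAlignment(
      paset, Biostrings::AAString(pb[j]), type = "local",
      substitutionMatrix = B62, gapOpening = 11, gapExtension = 1)
    score[, j] <- Biostrings::score(al)
    pid[, j] <- Biostrings::pid(al, type = "PID1")
    alen <- Biostrings::width(Biostrings::pattern(al)@range)
    cov[, j] <- 100 * alen / pmin(nchar(pa), nchar(pb[j]))
  }
  ok <- pid >= min_identity & cov >= min_coverage
  score[!ok] <- -Inf

  best_ab <- apply(score, 1L, function(r) if (all(!is.finite(r))) NA_integer_ else which.max(r))
  best_ba <- apply(score, 2L, function(c) if (all(!is.finite(c))) NA_integer_ else which.max(c))
  rbh_a <- which(!is.na(best_ab) & best_ba[best_ab] == seq_len(na))
  rbh_b <- best_ab[rbh_a]

  n_shared <- length(rbh_a)
  aai <- if (n_shared) mean(pid[cbind(rbh_a, rbh_b)]) else 0
  data.frame(id_a = attr(proteome_a, "genome_id") %||% "a",
             id_b = attr(proteome_b, "genome_id") %||% "b",
             aai = aai,
             shared_fraction = 100 * n_shared / min(na, nb),
             n_shared = n_shared, stringsAsFactors = FALSE)
}

#' Build the AAI similarity graph for one taxonomic level
#'
#' Nodes are all genomes mentioned in `results`; an undirected edge with
#' weight `aai` joins a pair iff `aai > aai_min` and
#' `shared_fraction > shared_min` (strict inequalities).
#'
#' @param results data.frame of [pairwise_aai()] rows (`id_a`, `id_b`,
#'   `aai`, `shared_fraction`).
#' @param cfg A [taxon_level_config()].
#' @return An undirected `igraph` graph with edge attribute `weight`.
#' @export
similarity_graph <- function(results, cfg) {
  stopifnot(inherits(cfg, "taxon_level_config"))
  nodes <- unique(c(results$id_a, results$id_b))
  keep <- !is.na(results$aai) & results$aai > cfg$aai_min &
    results$shared_fraction > cfg$shared_min & results$id_a != results$id_b
  edges <- results[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) data.frame(from = edges$id_a, to = edges$id_b,
                                weight = edges$aai)
    else data.frame(from = character(), to = character(), weight = numeric()),
    directed = FALSE, vertices = data.frame(name = nodes))
  igraph::simplify(g, edge.attr.comb = list(weight = "max"))
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Canonical MCL on the column-stochastic transition matrix with self-loops
#' (weight equal to the node's maximum incident edge weight, or 1 for
#' isolated nodes): alternate expansion (matrix power) and inflation
#' (elementwise power with column renormalisation), pruning entries below
#' `prune`, until the matrix changes by less than `tol` or `max_iter` is
#' reached (in which case the current interpretation is returned with a
#' warning). Clusters are read off attractor rows; overlapping attractor
#' supports are merged so the output is always a partition.
#'
#' @param graph An undirected `igraph` (edge attribute `weight` optional).
#' @param inflation Inflation exponent (> 1).
#' @param expansion Expansion power (integer >= 2).
#' @param tol Convergence tolerance on the max absolute matrix change.
#' @param max_iter Iteration cap.
#' @param prune Entries below this value are set to zero each iteration.
#' @return A [cluster_set()]; attribute `converged` is `FALSE` when the
#'   iteration cap was hit.
#' @export
mcl_cluster <- function(graph, inflation, expansion = 2L, tol = 1e-6,
                        max_iter = 200L, prune = 1e-8) {
  stopifnot(inflation > 1)
  n <- igraph::vcount(graph)
  ids <- igraph::V(graph)$name %||% as.character(seq_len(n))
  if (n == 0L) return(cluster_set(setNames(character(), character())))
  A <- igraph::as_adjacency_matrix(graph, attr =
    if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
    sparse = FALSE)
  A <- (A + t(A)) / 2  # symmetrise defensively
  loop <- apply(A, 1L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  normalise <- function(M) sweep(M, 2L, colSums(M), "/")
  M <- normalise(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mx <- M
    for (e in seq_len(expansion - 1L)) Mx <- Mx %*% M
    Mx <- Mx ^ inflation
    Mx[Mx < prune] <- 0
    zero <- colSums(Mx) == 0
    if (any(zero)) Mx[cbind(which(zero), which(zero))] <- 1
    Mx <- normalise(Mx)
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within max_iter; returning current state")

  attractors <- which(diag(M) > sqrt(prune))
  if (!length(attractors)) attractors <- which(diag(M) > 0)
  supports <- lapply(attractors, function(i) which(M[i, ] > sqrt(prune)))
  # merge overlapping attractor systems into clusters
  assign_id <- rep(NA_integer_, n)
  cl <- 0L
  for (k in seq_along(attractors)) {
    sup <- union(supports[[k]], attractors[k])
    hit <- unique(assign_id[sup])
    hit <- hit[!is.na(hit)]
    if (length(hit)) {
      tgt <- min(hit)
      assign_id[assign_id %in% hit] <- tgt
      assign_id[sup] <- tgt
    } else {
      cl <- cl + 1L
      assign_id[sup] <- cl
    }
  }
  # any node not reached by an attractor joins the cluster with most mass
  for (i in which(is.na(assign_id))) {
    j <- which.max(M[, i])
    assign_id[i] <- if (is.na(assign_id[j])) {cl <- cl + 1L; cl} else assign_id[j]
  }
  # relabel deterministically by first member
  first <- vapply(split(seq_len(n), assign_id), min, 1L)
  lab <- sprintf("mcl%03d", rank(first, ties.method = "first"))
  membership <- setNames(lab[match(assign_id, as.integer(names(first)))], ids)
  out <- cluster_set(membership)
  attr(out, "converged") <- converged
  out
}
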