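#' Genome record
#'
#' Lightweight container for a single genome sequence. Sequences are plain
#' upper-case character strings over the alphabet A, C, G, T; the simulator
#' never emits ambiguity codes.
#'
#' @param id Character scalar, genome identifier.
#' @param seq Character scalar, DNA sequence (A/C/G/T only, non-empty).
#' @param circular Logical flag; reads are never simulated across the origin,
#'   the flag is carried as metadata.
#' @return An object of class `genome_record` with fields `id`, `seq`,
#'   `circular` and `length`.
#' @export
genome_record <- function(id, seq, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stopf("genome '%s': sequence is empty", id)
  if (grepl("[^ACGT]", seq)) stopf("genome '%s': alphabet restricted to A,C,G,T", id)
  structure(list(id = id, seq = seq, circular = isTRUE(circular),
                 length = nchar(seq)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp%s\n", x$id, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Simulate a random genome
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc`, split evenly between G and
#' C (and between A and T).
#'
#' @param length Genome length in bp (>= 1).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed; all stochastic operations take an explicit seed.
#' @param id Identifier for the record.
#' @return A [genome_record()].
#' @examples
#' g <- simulate_genome(1000, gc = 0.5, seed = 1)
#' @export
simulate_genome <- function(length, gc = 0.5, seed, id = "genome") {
  if (!is_count(length) || length < 1) stopf("length must be a positive integer")
  if (!is_prob(gc)) stopf("gc must lie in [0, 1]")
  stopifnot(is_count(seed) || is.numeric(seed))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- withr::with_seed(seed,
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = ""))
  genome_record(id, seq)
}

#' Evolution parameters
#'
#' Maps a substitution rate `r` (alterations per site per year) and elapsed
#' time `t` (years) to a per-site alteration probability. Under
#' `compounding = "compound"` (default) `p_t = 1 - (1 - r)^t`; under
#' `"linear"` `p_t = min(r * t, 1)`. At the rates relevant for phage genomes
#' the two differ by well under 0.001 over centuries.
#'
#' @param rate Substitutions per site per year (>= 0).
#' @param years Elapsed time in years (>= 0).
#' @param compounding `"compound"` or `"linear"`.
#' @param seed Integer seed used by [evolve_genome()].
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(rate, years, compounding = c("compound", "linear"),
                             seed = 1L) {
  compounding <- match.arg(compounding)
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  stopifnot(is.numeric(years), length(years) == 1L, years >= 0)
  p <- alteration_prob(rate, years, compounding)
  if (is.na(p) || p < 0 || p > 1) stopf("per-site alteration probability outside [0, 1]")
  structure(list(rate = rate, years = years, compounding = compounding,
                 seed = seed, p_site = p),
            class = "evolution_params")
}

#' Per-site alteration probability
#'
#' @inheritParams evolution_params
#' @return Probability that a given site has been altered after `years` years.
#' @export
alteration_prob <- function(rate, years, compounding = c("compound", "linear")) {
  compounding <- match.arg(compounding)
  if (compounding == "compound") {
    # expm1/log1p keep precision at small rates
    -expm1(years * log1p(-rate))
  } else {
    min(rate * years, 1)
  }
}

#' Evolve a genome under an i.i.d. per-site substitution model
#'
#' Each site is independently altered with probability `p_t`; an altered site
#' receives a base chosen uniformly among the three alternatives (no
#' transition/transversion bias). No indels are introduced.
#'
#' @param genome A [genome_record()].
#' @param params An [evolution_params()].
#' @param id Identifier for the descendant (default `<ancestor>_desc`).
#' @return A list with `genome` (the descendant [genome_record()]) and
#'   `substitutions`, a data.frame of the exact altered positions
#'   (`pos` 1-based, `from`, `to`).
#' @export
evolve_genome <- function(genome, params, id = NULL) {
  stopifnot(inherits(genome, "genome_record"), inherits(params, "evolution_params"))
  id <- id %||% paste0(genome$id, "_desc")
  p <- params$p_site
  x <- chars(genome$seq)
  subs <- withr::with_seed(params$seed, {
    hit <- which(runif(length(x)) < p)
    if (length(hit)) {
      from <- x[hit]
      # uniform choice among the 3 alternative bases
      pick <- sample.int(3L, length(hit), replace = TRUE)
      alt <- matrix(c("C", "G", "T",   # A ->
                      "A", "G", "T",   # C ->
                      "A", "C", "T",   # G ->
                      "A", "C", "G"),  # T ->
                    nrow = 4L, byrow = TRUE,
                    dimnames = list(DNA_BASES, NULL))
      to <- alt[cbind(match(from, DNA_BASES), pick)]
      data.frame(pos = hit, from = from, to = to, stringsAsFactors = FALSE)
    } else {
      data.frame(pos = integer(), from = character(), to = character(),
                 stringsAsFactors = FALSE)
    }
  })
  if (nrow(subs)) x[subs$pos] <- subs$to
  list(genome = genome_record(id, paste(x, collapse = ""), genome$circular),
       substitutions = subs)
}

#' Damage parameters for the deamination model
#'
#' Terminal cytosine deamination is modelled as an exponentially decaying
#' C-to-T probability along the read from its 5' end:
#' `d(i) = b + (d1 - b) * exp(-lam * (i - 1))`, so `d(1) = d1` exactly and
#' `d(i) -> b` deep inside the read.
#'
#' @param d1 C-to-T probability at read position 1 (in `[0, 1]`).
#' @param lam Exponential decay constant per position (> 0).
#' @param background Baseline C-to-T probability `b` (in `[0, 1]`).
#' @param mirror_3prime If `TRUE`, apply the mirrored G-to-A pattern at the
#'   3' end (off by default; 5' C-to-T is the authentication signal).
#' @return A list of class `damage_params`.
#' @export
damage_params <- function(d1, lam = 0.3, background = 0.001,
                          mirror_3prime = FALSE) {
  stopifnot(is_prob(d1), is_prob(background))
  stopifnot(is.numeric(lam), length(lam) == 1L, lam > 0)
  if (d1 < background) stopf("d1 must be >= background")
  structure(list(d1 = d1, lam = lam, background = background,
                 mirror_3prime = isTRUE(mirror_3prime)),
            class = "damage_params")
}

#' Damage probability curve d(i)
#'
#' @param dp A [damage_params()].
#' @param positions Number of read positions to evaluate.
#' @return Numeric vector `d(1..positions)`.
#' @export
damage_curve <- function(dp, positions) {
  stopifnot(inherits(dp, "damage_params"))
  i <- seq_len(positions)
  dp$background + (dp$d1 - dp$background) * exp(-dp$lam * (i - 1))
}

#' Read-simulation parameters
#'
#' Fragment lengths are drawn from a normal distribution truncated to
#' `[20, genome length]`; reads lie fully within the (linear) source genome.
#'
#' @param coverage Mean fold-coverage (> 0).
#' @param frag_len_mean,frag_len_sd Fragment-length distribution (bp);
#'   `frag_len_mean >= 20`.
#' @param seq_error Per-base sequencing error rate, applied after damage.
#' @param seed Integer seed.
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(coverage, frag_len_mean = 60, frag_len_sd = 10,
                            seq_error = 0, seed = 1L) {
  stopifnot(is.numeric(coverage), coverage > 0)
  stopifnot(frag_len_mean >= 20, frag_len_sd >= 0, is_prob(seq_error))
  structure(list(coverage = coverage, frag_len_mean = frag_len_mean,
                 frag_len_sd = frag_len_sd, seq_error = seq_error,
                 seed = seed),
            class = "read_sim_params")
}

# draw truncated-normal fragment lengths in [lo, hi] by redrawing
rtrunc_lens <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(as.integer(pmin(pmax(round(mean), lo), hi)), n))
  out <- as.integer(round(rnorm(n, mean, sd)))
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad) && guard < 50L) {
    out[bad] <- as.integer(round(rnorm(length(bad), mean, sd)))
    bad <- bad[out[bad] < lo | out[bad] > hi]
    guard <- guard + 1L
  }
  if (length(bad)) out[bad] <- as.integer(pmin(pmax(round(mean), lo), hi))
  out
}

#' Simulate a damaged (or undamaged) short-read set from one genome
#'
#' Fragments are sampled uniformly along the genome on both strands. For each
#' read, cytosines at read offset `i` (1-based from the 5' end, in read
#' coordinates) are converted to thymine with probability `d(i)`; the damage
#' is applied in read orientation, so the 5'-terminal pattern is preserved on
#' both strands. Sequencing errors are applied after damage. True alignments
#' are recorded as a minimal SAM record set (FLAG 0/16, single-M CIGAR).
#'
#' @param genome A [genome_record()].
#' @param rp A [read_sim_params()].
#' @param dp A [damage_params()] or `NULL` for undamaged reads.
#' @return A list with
#'   `reads`: data.frame with SAM-style columns `qname`, `flag` (0/16),
#'     `rname`, `pos` (1-based leftmost), `mapq`, `cigar`, `seq` (reference
#'     orientation, as stored in SAM), `qual`, plus `read_seq` (5'->3' read
#'     orientation) and `len`;
#'   `truth`: list with `damage` and `errors`, per-read integer vectors of
#'     altered offsets in read coordinates (named by qname).
#' @export
simulate_reads <- function(genome, rp, dp = NULL) {
  stopifnot(inherits(genome, "genome_record"), inherits(rp, "read_sim_params"))
  if (!is.null(dp)) stopifnot(inherits(dp, "damage_params"))
  L <- genome$length
  if (L < rp$frag_len_mean) stopf("genome shorter than mean fragment length")
  n <- max(1L, as.integer(round(rp$coverage * L / rp$frag_len_mean)))

  withr::with_seed(rp$seed, {
    lens <- rtrunc_lens(n, rp$frag_len_mean, rp$frag_len_sd, 20L, L)
    starts <- 1L + as.integer(floor(runif(n) * (L - lens + 1)))
    flags <- sample(c(0L, 16L), n, replace = TRUE)
    frags <- substring(genome$seq, starts, starts + lens - 1L)
    # read orientation: reverse-strand reads are the reverse complement
    rev <- flags == 16L
    reads <- frags
    if (any(rev)) reads[rev] <- revcomp_chr(frags[rev])

    cc <- chars(paste(reads, collapse = ""))
    offs <- sequence(lens)                 # offset within each read, 5' based
    ridx <- rep.int(seq_len(n), lens)
    dmg_hit <- logical(length(cc))

    if (!is.null(dp)) {
      d <- damage_curve(dp, max(lens))
      hit5 <- cc == "C" & runif(length(cc)) < d[offs]
      cc[hit5] <- "T"
      dmg_hit <- hit5
      if (dp$mirror_3prime) {
        offs3 <- lens[ridx] - offs + 1L
        hit3 <- cc == "G" & runif(length(cc)) < d[offs3]
        cc[hit3] <- "A"
        dmg_hit <- dmg_hit | hit3
      }
    }

    err_hit <- logical(length(cc))
    if (rp$seq_error > 0) {
      err_hit <- runif(length(cc)) < rp$seq_error
      if (any(err_hit)) {
        alt <- matrix(c("C", "G", "T",
                        "A", "G", "T",
                        "A", "C", "T",
                        "A", "C", "G"),
                      nrow = 4L, byrow = TRUE,
                      dimnames = list(DNA_BASES, NULL))
        w <- which(err_hit)
        cc[w] <- alt[cbind(match(cc[w], DNA_BASES),
                           sample.int(3L, length(w), replace = TRUE))]
      }
    }

    collapsed <- paste(cc, collapse = "")
    ends <- cumsum(lens)
    begs <- ends - lens + 1L
    read_seq <- substring(collapsed, begs, ends)
    seq_sam <- read_seq
    if (any(rev)) seq_sam[rev] <- revcomp_chr(read_seq[rev])

    qname <- sprintf("%s_r%06d", genome$id, seq_len(n))
    reads_df <- data.frame(
      qname = qname, flag = flags, rname = genome$id, pos = starts,
      mapq = 60L, cigar = paste0(lens, "M"), seq = seq_sam,
      qual = strrep("F", lens), read_seq = read_seq, len = lens,
      stringsAsFactors = FALSE)

    truth <- list(
      damage = setNames(unname(split(offs[dmg_hit], factor(ridx[dmg_hit], levels = seq_len(n)))), qname),
      errors = setNames(unname(split(offs[err_hit], factor(ridx[err_hit], levels = seq_len(n)))), qname))
    list(reads = reads_df, truth = truth)
  })
}

#' Simulate a multi-genome community with known truth
#'
#' Ancient genomes receive damaged read sets, modern genomes undamaged
#' (background-only) read sets. `cluster_spec` declares groups of related
#' genomes: each group shares a simulated ancestor and every member is an
#' evolved copy whose per-site divergence is `(100 - within_ani) / 200`, so
#' that the expected pairwise identity between members matches the declared
#' within-cluster ANI. Genomes outside any declared cluster are independent
#' simulations (singleton clusters).
#'
#' @param n_ancient,n_modern Number of ancient / modern genomes.
#' @param cluster_spec Optional list of `list(members =, within_ani =)`;
#'   members are taken from the community in order and must not exceed its
#'   size. `within_ani` is a percentage in `(0, 100]`.
#' @param rp A [read_sim_params()] used for every genome.
#' @param dp A [damage_params()] for ancient genomes.
#' @param modern_dp A [damage_params()] for modern genomes; the default is a
#'   flat 0.002 C-to-T background mirroring present-day gut-virome controls.
#' @param genome_length,gc Genome simulation parameters.
#' @param seed Integer master seed; all per-genome seeds derive from it.
#' @param outdir Optional directory: writes `genomes.fasta`, `reads.fastq`,
#'   `alignments.sam` and truth TSVs.
#' @return A list with `genomes` (list of [genome_record()]), `reads`
#'   (combined SAM-style data.frame), `truth` (per-genome `labels`
#'   data.frame with `genome_id`, `label`, `cluster_id`; `read_truth`;
#'   `substitutions`) and `files` (paths written, or `NULL`).
#' @export
make_community <- function(n_ancient, n_modern, cluster_spec = NULL,
                           rp = read_sim_params(coverage = 30, seed = 1L),
                           dp = damage_params(d1 = 0.042),
                           modern_dp = damage_params(d1 = 0.002, lam = 1,
                                                     background = 0.002),
                           genome_length = 5000L, gc = 0.5, seed = 1L,
                           outdir = NULL) {
  stopifnot(is_count(n_ancient), is_count(n_modern))
  n_tot <- n_ancient + n_modern
  if (n_tot < 1L) stopf("empty community")
  if (!is.null(cluster_spec)) {
    memb <- vapply(cluster_spec, function(cs) cs$members, numeric(1))
    ani  <- vapply(cluster_spec, function(cs) cs$within_ani, numeric(1))
    stopifnot(all(memb >= 1), sum(memb) <= n_tot, all(ani > 0 & ani <= 100))
  }

  seeds <- withr::with_seed(seed, sample.int(2^30, 3L * n_tot + 64L))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  labels <- rep(c("ancient", "modern"), c(n_ancient, n_modern))
  ids <- sprintf("g%02d_%s", seq_len(n_tot), labels)

  genomes <- vector("list", n_tot)
  cluster_id <- character(n_tot)
  substitutions <- list()
  gi <- 0L
  ci <- 0L
  for (cs in cluster_spec %||% list()) {
    ci <- ci + 1L
    anc <- simulate_genome(genome_length, gc, seed = next_seed(),
                           id = sprintf("anc%02d", ci))
    p_div <- (100 - cs$within_ani) / 200
    for (k in seq_len(cs$members)) {
      gi <- gi + 1L
      ev <- evolve_genome(anc, evolution_params(rate = p_div, years = 1,
                                                compounding = "linear",
                                                seed = next_seed()),
                          id = ids[gi])
      genomes[[gi]] <- ev$genome
      substitutions[[ids[gi]]] <- ev$substitutions
      cluster_id[gi] <- sprintf("cluster%02d", ci)
    }
  }
  while (gi < n_tot) {
    gi <- gi + 1L
    ci <- ci + 1L
    genomes[[gi]] <- simulate_genome(genome_length, gc, seed = next_seed(),
                                     id = ids[gi])
    cluster_id[gi] <- sprintf("cluster%02d", ci)
  }

  read_sets <- vector("list", n_tot)
  read_truth <- list()
  for (i in seq_len(n_tot)) {
    rp_i <- rp
    rp_i$seed <- next_seed()
    dp_i <- if (labels[i] == "ancient") dp else modern_dp
    rs <- simulate_reads(genomes[[i]], rp_i, dp_i)
    read_sets[[i]] <- rs$reads
    read_truth[[ids[i]]] <- rs$truth
  }
  reads <- do.call(rbind, read_sets)
  truth <- list(
    labels = data.frame(genome_id = ids, label = labels,
                        cluster_id = cluster_id, stringsAsFactors = FALSE),
    read_truth = read_truth,
    substitutions = substitutions)

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      genomes = file.path(outdir, "genomes.fasta"),
      reads = file.path(outdir, "reads.fastq"),
      alignments = file.path(outdir, "alignments.sam"),
      labels = file.path(outdir, "truth_labels.tsv"))
    write_fasta(genomes, files[["genomes"]])
    write_fastq(reads, files[["reads"]])
    write_sam(reads, genomes, files[["alignments"]])
    write_tsv(truth$labels, files[["labels"]])
  }

  list(genomes = genomes, reads = reads, truth = truth, files = files)
}

#' Plant non-overlapping protein-coding genes in a genome
#'
#' Gene lengths are drawn around `mean_len`, rounded to multiples of 3, and
#' placed left to right on the forward strand with random intergenic gaps.
#' In-frame stop codons inside planted genes are recoded (third codon base
#' set to C), so the returned genome differs from the input at those sites;
#' translations use the standard genetic code and contain no stop character.
#'
#' @param genome A [genome_record()].
#' @param n_genes Number of genes to plant.
#' @param mean_len Mean gene length in bp (coding part; multiple of 3 after
#'   rounding).
#' @param seed Integer seed.
#' @param len_sd Standard deviation of gene lengths in bp (default 0: every
#'   gene is exactly `mean_len` long).
#' @return A list with `genome` (recoded [genome_record()]), `genes`
#'   (data.frame: `gene_id`, `start`, `end`, `strand`, `length`; 1-based
#'   fully-closed coordinates) and `proteins` (named character vector of
#'   amino-acid sequences).
#' @export
plant_genes <- function(genome, n_genes, mean_len, seed, len_sd = 0) {
  stopifnot(inherits(genome, "genome_record"), is_count(n_genes), n_genes >= 1)
  L <- genome$length
  mean_len <- as.integer(round(mean_len / 3)) * 3L
  if (n_genes * mean_len > L) stopf("infeasible packing: n_genes * mean_len > genome length")

  withr::with_seed(seed, {
    lens <- as.integer(round(rnorm(n_genes, mean_len, len_sd) / 3)) * 3L
    lens <- pmax(lens, 30L)
    if (sum(lens) > L) lens <- rep(mean_len, n_genes)
    slack <- L - sum(lens)
    gaps <- as.integer(stats::rmultinom(1L, slack, rep(1, n_genes + 1L)))
    starts <- cumsum(gaps[seq_len(n_genes)]) +
      c(0L, cumsum(lens[-n_genes])) + 1L
    ends <- starts + lens - 1L

    x <- chars(genome$seq)
    for (g in seq_len(n_genes)) {
      cod3 <- seq(starts[g] + 2L, ends[g], by = 3L)  # third base of each codon
      codons <- paste0(x[cod3 - 2L], x[cod3 - 1L], x[cod3])
      stop_i <- codons %in% c("TAA", "TAG", "TGA")
      if (any(stop_i)) x[cod3[stop_i]] <- "C"        # TAA/TAG -> TAC, TGA -> TGC
    }
    seq2 <- paste(x, collapse = "")
    gene_id <- sprintf("%s_gene%03d", genome$id, seq_len(n_genes))
    cds <- substring(seq2, starts, ends)
    prot <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds)))
    names(prot) <- gene_id
    list(genome = genome_record(genome$id, seq2, genome$circular),
         genes = data.frame(gene_id = gene_id, start = starts, end = ends,
                            strand = "+", length = lens,
                            stringsAsFactors = FALSE),
         proteins = prot)
  })
}
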