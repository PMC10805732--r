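#' Pairwise alignment container
#'
#' Equal-length gapped strings plus column-to-position coordinate maps
#' (1-based ungapped positions; `NA` at gap columns). No column may carry a
#' gap in both rows.
#'
#' @param aligned_a,aligned_b Gapped sequences of equal length.
#' @param id_a,id_b Sequence identifiers.
#' @param score Optional alignment score.
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(aligned_a, aligned_b, id_a = "a", id_b = "b",
                               score = NA_real_) {
  stopifnot(is.character(aligned_a), is.character(aligned_b),
            length(aligned_a) == 1L, length(aligned_b) == 1L)
  ca <- chars(toupper(aligned_a)); cb <- chars(toupper(aligned_b))
  if (length(ca) != length(cb)) stopf("aligned strings have different lengths")
  ga <- ca == "-"; gb <- cb == "-"
  if (any(ga & gb)) stopf("column with gaps in both rows")
  pos_a <- ifelse(ga, NA_integer_, cumsum(!ga))
  pos_b <- ifelse(gb, NA_integer_, cumsum(!gb))
  structure(list(id_a = id_a, id_b = id_b,
                 aligned_a = paste(ca, collapse = ""),
                 aligned_b = paste(cb, collapse = ""),
                 chars_a = ca, chars_b = cb,
                 pos_a = pos_a, pos_b = pos_b, score = score,
                 ncol = length(ca)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  ident <- 100 * mean(x$chars_a == x$chars_b & x$chars_a != "-")
  cat(sprintf("<pairwise_alignment> %s vs %s: %d columns, %.2f%% identity\n",
              x$id_a, x$id_b, x$ncol, ident))
  invisible(x)
}

#' Global pairwise genome alignment
#'
#' Optimal global (Needleman-Wunsch) alignment under a BLAST-style scheme
#' (defaults: match 2, mismatch -3, gap open 5, gap extend 2, i.e. a gap of
#' length k costs `5 + 2k`), optionally restricted to a diagonal band. The
#' full matrix is quadratic in memory, so genome-scale pairs should supply a
#' band a few hundred columns wider than the expected indel offset.
#'
#' @param a,b [genome_record()]s or plain character sequences.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @param band Band half-width in columns (`NULL` for unbanded); requires
#'   `|len(a) - len(b)| < band`.
#' @return A [pairwise_alignment()].
#' @export
align_pair <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                       gap_ext = 2, band = NULL) {
  ga <- if (inherits(a, "genome_record")) a else genome_record("a", a)
  gb <- if (inherits(b, "genome_record")) b else genome_record("b", b)
  if (!is.null(band)) {
    band <- as.integer(band)
    if (abs(ga$length - gb$length) >= band)
      stopf("band infeasible: |len(a) - len(b)| = %d >= band = %d",
            abs(ga$length - gb$length), band)
  }
  res <- .band_align_cpp(ga$seq, gb$seq, match, mismatch, gap_open, gap_ext,
                         if (is.null(band)) -1L else band)
  pairwise_alignment(res$aligned_a, res$aligned_b, ga$id, gb$id, res$score)
}

#' Separate the shared core of a query genome from its unique flanks
#'
#' Given pairwise alignments of one query against each of `k` relatives
#' (star layout), returns the largest contiguous query interval whose
#' positions are aligned (non-gap on both rows) in at least `min_presence`
#' relatives. Flanking host sequence around an integrated prophage is absent
#' from the relatives and is trimmed away by this rule.
#'
#' @param alignments List of [pairwise_alignment()]s, query as sequence A in
#'   each.
#' @param min_presence Minimum number of relatives covering a position
#'   (default all of them).
#' @return A list with `core_start`, `core_end` (1-based on the query),
#'   `left_flank`, `right_flank` (lengths in bp) and `query_length`.
#' @export
trim_flanks <- function(alignments, min_presence = length(alignments)) {
  stopifnot(length(alignments) >= 1L)
  if (min_presence > length(alignments))
    stopf("min_presence (%d) exceeds the number of relatives (%d)",
          min_presence, length(alignments))
  qlen <- max(vapply(alignments, function(al) max(al$pos_a, na.rm = TRUE), 1L))
  presence <- integer(qlen)
  for (al in alignments) {
    covered <- al$pos_a[!is.na(al$pos_a) & !is.na(al$pos_b)]
    presence[covered] <- presence[covered] + 1L
  }
  ok <- presence >= min_presence
  if (!any(ok)) stopf("no query position is present in %d relatives", min_presence)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  list(core_start = starts[best], core_end = ends[best],
       left_flank = starts[best] - 1L, right_flank = qlen - ends[best],
       query_length = qlen)
}

#' Call SNVs and indel events from a pairwise alignment
#'
#' A SNV is a column where both rows carry different bases (no gap); maximal
#' runs of gap columns in one row collapse to a single indel event. SNV
#' positions are reported on sequence A's ungapped 1-based coordinates;
#' indel events are positioned at the last preceding A base (0 when the run
#' starts the alignment). A gap run in row A is an insertion (B carries
#' extra sequence), a run in row B a deletion.
#'
#' @param aln A [pairwise_alignment()].
#' @return A list with `snvs` (data.frame `position_ref`, `base_a`,
#'   `base_b`) and `indel_events` (data.frame `position_ref`, `length`,
#'   `kind`).
#' @export
call_snvs <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  ca <- aln$chars_a; cb <- aln$chars_b
  both <- ca != "-" & cb != "-"
  mm <- both & ca != cb
  snvs <- data.frame(position_ref = aln$pos_a[mm], base_a = ca[mm],
                     base_b = cb[mm], stringsAsFactors = FALSE)

  indel_runs <- function(is_gap, kind) {
    if (!any(is_gap))
      return(data.frame(position_ref = integer(), length = integer(),
                        kind = character(), stringsAsFactors = FALSE))
    r <- rle(is_gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    pos <- vapply(starts[gi], function(s) {
      prev <- aln$pos_a[seq_len(s - 1L)]
      prev <- prev[!is.na(prev)]
      if (length(prev)) tail(prev, 1L) else 0L
    }, 1L)
    data.frame(position_ref = pos, length = r$lengths[gi], kind = kind,
               stringsAsFactors = FALSE)
  }
  ev <- rbind(indel_runs(ca == "-", "insertion"),
              indel_runs(cb == "-", "deletion"))
  ev <- ev[order(ev$position_ref), , drop = FALSE]
  rownames(ev) <- NULL
  list(snvs = snvs, indel_events = ev)
}

#' Sliding-window identity track with hypervariable-window flagging
#'
#' Windows tile the alignment columns with the given step; per-window
#' identity is the fraction of matching columns (gap columns count against
#' identity). A window is flagged hypervariable when its identity falls
#' below `mean - flag_k * sd` of all window identities — localised
#' diversity such as a DGR-targeted variable region stands out against an
#' otherwise near-identical genome pair.
#'
#' @param aln A [pairwise_alignment()].
#' @param window,step Window size and step in alignment columns.
#' @param flag_k Flagging multiplier (default 3).
#' @return A data.frame with `window_start`, `window_end` (alignment
#'   columns), `identity` (percent) and `flagged`.
#' @export
window_identity <- function(aln, window = 100L, step = 50L, flag_k = 3) {
  stopifnot(inherits(aln, "pairwise_alignment"), window >= 10L, step >= 1L)
  n <- aln$ncol
  match_col <- aln$chars_a == aln$chars_b & aln$chars_a != "-"
  if (n <= window) {
    ident <- 100 * mean(match_col)
    return(data.frame(window_start = 1L, window_end = n, identity = ident,
                      flagged = FALSE))
  }
  starts <- seq(1L, n - window + 1L, by = step)
  cs <- c(0L, cumsum(match_col))
  ident <- 100 * (cs[starts + window] - cs[starts]) / window
  mu <- mean(ident); s <- sd(ident)
  flagged <- if (is.na(s) || s == 0) rep(FALSE, length(ident))
             else ident < mu - flag_k * s
  data.frame(window_start = starts, window_end = starts + window - 1L,
             identity = ident, flagged = flagged)
}

#' Per-gene identity between an aligned genome pair
#'
#' Genes are annotated on sequence A (1-based fully-closed intervals). At
#' the nucleotide level, identity is computed over the alignment columns the
#' gene spans. At the amino-acid level, both sides of the gene are extracted
#' via the coordinate maps, translated, and locally re-aligned (BLOSUM62,
#' gap open 10 / extend 0.5, EMBOSS-style); identity is
#' matches / alignment length. Genes fully deleted from B are reported as
#' missing and excluded from the unweighted mean.
#'
#' @param aln A [pairwise_alignment()].
#' @param genes Gene table (`gene_id`, `start`, `end`, `strand`).
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @return A list with `per_gene` (data.frame `gene_id`, `identity`,
#'   `missing`) and `mean_identity`.
#' @export
per_gene_identity <- function(aln, genes, level = c("nucleotide", "amino_acid")) {
  level <- match.arg(level)
  stopifnot(inherits(aln, "pairwise_alignment"))
  alen <- max(aln$pos_a, na.rm = TRUE)
  if (any(genes$start < 1L | genes$end > alen))
    stopf("gene interval outside sequence A bounds")
  seq_b <- gsub("-", "", aln$aligned_b, fixed = TRUE)

  rows <- lapply(seq_len(nrow(genes)), function(g) {
    cols <- which(!is.na(aln$pos_a) & aln$pos_a >= genes$start[g] &
                    aln$pos_a <= genes$end[g])
    bpos <- aln$pos_b[cols]
    bpos <- bpos[!is.na(bpos)]
    if (!length(cols) || !length(bpos))
      return(data.frame(gene_id = genes$gene_id[g], identity = NA_real_,
                        missing = TRUE, stringsAsFactors = FALSE))
    if (level == "nucleotide") {
      ident <- 100 * mean(aln$chars_a[cols] == aln$chars_b[cols] &
                            aln$chars_a[cols] != "-")
    } else {
      a_nt <- paste(aln$chars_a[cols][aln$chars_a[cols] != "-"], collapse = "")
      b_nt <- substr(seq_b, min(bpos), max(bpos))
      if (genes$strand[g] == "-") {
        a_nt <- revcomp_chr(a_nt); b_nt <- revcomp_chr(b_nt)
      }
      trim3 <- function(s) substr(s, 1L, (nchar(s) %/% 3L) * 3L)
      a_aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(trim3(a_nt)), no.init.codon = TRUE))
      b_aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(trim3(b_nt)), no.init.codon = TRUE))
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(gsub("\\*", "X", a_aa)),
        Biostrings::AAString(gsub("\\*", "X", b_aa)),
        type = "local", substitutionMatrix = blosum62(),
        gapOpening = 10, gapExtension = 0.5)
      ident <- Biostrings::pid(al, type = "PID1")
    }
    data.frame(gene_id = genes$gene_id[g], identity = ident, missing = FALSE,
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  list(per_gene = per_gene,
       mean_identity = mean(per_gene$identity[!per_gene$missing]))
}

#' Conservation-model parameters
#'
#' Parameters of the binomial genome-conservation model: a genome of `n`
#' sites accumulates alterations independently at per-site probability
#' `p_t` derived from rate `r` and elapsed years `t`; the genome is deemed
#' conserved when at most `m = floor(n (1 - q))` sites are altered, i.e. at
#' least a fraction `q` of sites is unaltered.
#'
#' @param n Genome length in sites.
#' @param q Identity threshold fraction in `(0, 1]` (e.g. 0.977).
#' @param rate Alterations per site per year.
#' @param years Elapsed years.
#' @param compounding As in [evolution_params()].
#' @return A list of class `conservation_params` (with derived `m`).
#' @export
conservation_params <- function(n, q, rate, years,
                                compounding = c("compound", "linear")) {
  compounding <- match.arg(compounding)
  stopifnot(is_count(n), n >= 1, q > 0, q <= 1, rate >= 0, years >= 0)
  # tolerance absorbs binary representation error in 1 - q (e.g. q = 0.8)
  structure(list(n = as.integer(n), q = q, rate = rate, years = years,
                 compounding = compounding, m = floor(n * (1 - q) + 1e-9)),
            class = "conservation_params")
}

#' Probability that a genome stays conserved
#'
#' Computes `P(X <= m)` for `X ~ Binomial(n, p_t)` in log space by exact
#' summation of the log binomial terms with stable accumulation, so
#' probabilities far below double underflow are still reported through
#' their log10 value.
#'
#' @param p A [conservation_params()].
#' @return A list with `prob`, `log10_prob`, `p_site` and `m`.
#' @export
prob_conserved <- function(p) {
  stopifnot(inherits(p, "conservation_params"))
  p_t <- alteration_prob(p$rate, p$years, p$compounding)
  if (p_t == 0 || p$m >= p$n)
    return(list(prob = 1, log10_prob = 0, p_site = p_t, m = p$m))
  if (p_t == 1)
    return(list(prob = 0, log10_prob = -Inf, p_site = p_t, m = p$m))
  k <- 0:p$m
  logterms <- lchoose(p$n, k) + k * log(p_t) + (p$n - k) * log1p(-p_t)
  ll <- logsumexp(logterms)
  list(prob = exp(ll), log10_prob = ll / log(10), p_site = p_t, m = p$m)
}

#' Years until the conservation probability drops below a target
#'
#' Smallest integer `t` with `prob_conserved < prob_target`, found by
#' doubling then bisection (the probability is non-increasing in `t`).
#' Returns `Inf` ("never") when the rate is 0 or the threshold tolerates
#' every site being altered.
#'
#' @inheritParams conservation_params
#' @param prob_target Target probability in `(0, 1)`; values `>= 1` return 0.
#' @return Integer number of years (or `Inf`).
#' @export
years_to_threshold <- function(n, q, rate, prob_target = 1e-3,
                               compounding = c("compound", "linear")) {
  compounding <- match.arg(compounding)
  if (prob_target >= 1) return(0L)
  stopifnot(prob_target > 0)
  if (rate == 0 || floor(n * (1 - q) + 1e-9) >= n) return(Inf)
  pr <- function(t) prob_conserved(conservation_params(n, q, rate, t,
                                                       compounding))$log10_prob
  target <- log10(prob_target)
  hi <- 1
  while (pr(hi) >= target) {
    hi <- hi * 2
    if (hi > 2^40) return(Inf)
  }
  lo <- hi %/% 2
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (pr(mid) < target) hi <- mid else lo <- mid
  }
  if (pr(lo) < target) lo else hi
}
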