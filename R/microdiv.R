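#' Diversity configuration
#'
#' @param min_cov Minimum per-site coverage for a site to be considered
#'   (default 5; sites below coverage 2 are never informative for pairwise
#'   differences).
#' @param min_allele_freq Minimum minor-allele frequency for a divergent
#'   site (default 0.05).
#' @return A list of class `diversity_config`.
#' @export
diversity_config <- function(min_cov = 5L, min_allele_freq = 0.05) {
  stopifnot(min_cov >= 1, min_allele_freq > 0, min_allele_freq <= 0.5)
  structure(list(min_cov = as.integer(min_cov),
                 min_allele_freq = min_allele_freq),
            class = "diversity_config")
}

#' Build a per-site allele-count pileup from alignments
#'
#' Read bases are attributed to reference sites by walking the CIGAR
#' (M/I/D/S): deletions contribute nothing, inserted and soft-clipped bases
#' are skipped. SAM stores SEQ in reference orientation, so no strand
#' handling is needed.
#'
#' @param records SAM-style data.frame for one contig.
#' @param reference The contig as a [genome_record()].
#' @return An object of class `pileup`: `counts` (L x 4 integer matrix,
#'   columns A/C/G/T), `coverage`, `ref` (reference base per site),
#'   `contig_id`.
#' @export
build_pileup <- function(records, reference) {
  stopifnot(inherits(reference, "genome_record"))
  L <- reference$length
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  rec <- records[!bitwAnd(records$flag, 4L), , drop = FALSE]
  if (nrow(rec)) {
    bad <- grepl("[^0-9MIDS]", rec$cigar)
    if (any(bad))
      stopf("unsupported CIGAR operation in record '%s' (cigar '%s')",
            rec$qname[bad][1], rec$cigar[bad][1])
    simple <- grepl("^[0-9]+M$", rec$cigar)

    add_bases <- function(refpos, base) {
      keep <- refpos >= 1L & refpos <= L & base %in% DNA_BASES
      idx <- (match(base[keep], DNA_BASES) - 1L) * L + refpos[keep]
      tab <- tabulate(idx, nbins = 4L * L)
      counts <<- counts + matrix(tab, nrow = L, ncol = 4L,
                                 dimnames = dimnames(counts))
    }
    if (any(simple)) {
      s <- rec[simple, , drop = FALSE]
      lens <- nchar(s$seq)
      offs <- sequence(lens)
      refpos <- rep.int(s$pos, lens) + offs - 1L
      base <- chars(paste(s$seq, collapse = ""))
      add_bases(refpos, base)
    }
    if (any(!simple)) {
      g <- rec[!simple, , drop = FALSE]
      rp_all <- integer(0); b_all <- character(0)
      for (k in seq_len(nrow(g))) {
        len <- nchar(g$seq[k])
        map <- cigar_ref_map(g$cigar[k], g$pos[k], len)
        keep <- !is.na(map)
        rp_all <- c(rp_all, map[keep])
        b_all <- c(b_all, chars(g$seq[k])[keep])
      }
      if (length(rp_all)) add_bases(rp_all, b_all)
    }
  }
  structure(list(contig_id = reference$id, counts = counts,
                 coverage = as.integer(rowSums(counts)),
                 ref = chars(reference$seq)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d sites, mean coverage %.1f\n", x$contig_id,
              length(x$coverage), mean(x$coverage)))
  invisible(x)
}

# per-site unbiased nucleotide diversity: 1 - sum_a C(c_a,2) / C(c,2)
site_pi <- function(counts) {
  cov <- rowSums(counts)
  num <- rowSums(counts * (counts - 1)) / 2
  den <- cov * (cov - 1) / 2
  ifelse(den > 0, 1 - num / den, NA_real_)
}

#' Per-site and mean nucleotide diversity (pi)
#'
#' For each site with coverage `c >= min_cov`,
#' `pi = 1 - sum_a C(c_a, 2) / C(c, 2)` — the unbiased probability that two
#' reads drawn without replacement carry different alleles. The mean is
#' taken over considered sites (reported as `NA` when none qualify).
#'
#' @param pileup A [build_pileup()] result.
#' @param cfg A [diversity_config()].
#' @return A list with `sites_considered`, `mean_pi` and `per_site`
#'   (data.frame `pos`, `coverage`, `pi`, `considered`).
#' @export
nucleotide_diversity <- function(pileup, cfg = diversity_config()) {
  stopifnot(inherits(pileup, "pileup"), inherits(cfg, "diversity_config"))
  cov <- pileup$coverage
  considered <- cov >= max(cfg$min_cov, 2L)
  pi <- site_pi(pileup$counts)
  list(sites_considered = sum(considered),
       mean_pi = if (any(considered)) mean(pi[considered]) else NA_real_,
       per_site = data.frame(pos = seq_along(cov), coverage = cov, pi = pi,
                             considered = considered))
}

#' Divergent-site detection
#'
#' A site is divergent when its coverage is at least `min_cov` and at least
#' one non-reference allele reaches frequency `min_allele_freq` with an
#' absolute count of at least 2 (singletons are suppressed as likely
#' sequencing errors).
#'
#' @inheritParams nucleotide_diversity
#' @return A list with `divergent` (data.frame `pos`, `ref`, `allele`,
#'   `count`, `coverage`, `freq` for qualifying sites), `count` and
#'   `fraction` (relative to considered sites).
#' @export
divergent_sites <- function(pileup, cfg = diversity_config()) {
  stopifnot(inherits(pileup, "pileup"), inherits(cfg, "diversity_config"))
  cov <- pileup$coverage
  considered <- cov >= cfg$min_cov
  alt <- pileup$counts
  alt[cbind(seq_len(nrow(alt)), match(pileup$ref, DNA_BASES))] <- 0L
  freq <- alt / pmax(cov, 1L)
  qual <- alt >= 2L & freq >= cfg$min_allele_freq & considered
  hit <- which(qual, arr.ind = TRUE)
  divergent <- data.frame(
    pos = hit[, 1L], ref = pileup$ref[hit[, 1L]],
    allele = DNA_BASES[hit[, 2L]],
    count = alt[hit], coverage = cov[hit[, 1L]], freq = freq[hit],
    stringsAsFactors = FALSE)
  divergent <- divergent[order(divergent$pos), , drop = FALSE]
  rownames(divergent) <- NULL
  n_div <- length(unique(divergent$pos))
  list(divergent = divergent, count = n_div,
       fraction = if (sum(considered)) n_div / sum(considered) else NA_real_)
}

#' Microdiversity summary for one contig
#'
#' Convenience wrapper combining [nucleotide_diversity()] and
#' [divergent_sites()] into the summary row used in reports.
#'
#' @inheritParams nucleotide_diversity
#' @return One-row data.frame with `contig_id`, `sites_considered`,
#'   `mean_pi`, `divergent_count`, `divergent_fraction`.
#' @export
microdiv_summary <- function(pileup, cfg = diversity_config()) {
  nd <- nucleotide_diversity(pileup, cfg)
  dv <- divergent_sites(pileup, cfg)
  data.frame(contig_id = pileup$contig_id,
             sites_considered = nd$sites_considered, mean_pi = nd$mean_pi,
             divergent_count = dv$count, divergent_fraction = dv$fraction,
             stringsAsFactors = FALSE)
}
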