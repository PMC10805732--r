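#' Read and write FASTA genome files
#'
#' Thin wrappers around Biostrings. `read_fasta()` returns a list of
#' [genome_record()]s; `write_fasta()` accepts a list of records, a named
#' character vector, or a `DNAStringSet`.
#'
#' @param path File path.
#' @param genomes Sequences to write.
#' @return `read_fasta()`: named list of [genome_record()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i)
    genome_record(sub("\\s.*$", "", names(ss)[i]), as.character(ss[[i]])))
  setNames(out, vapply(out, `[[`, "", "id"))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (is.list(genomes)) {
    seqs <- vapply(genomes, `[[`, "", "seq")
    names(seqs) <- vapply(genomes, `[[`, "", "id")
  } else seqs <- genomes
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read and write FASTQ read files
#'
#' Reads are written in read orientation (5' to 3') with Sanger Phred+33
#' qualities.
#'
#' @param reads A data.frame as returned by [simulate_reads()] (columns
#'   `qname`, `read_seq`, `qual`), or a named character vector.
#' @param path File path.
#' @return `read_fastq()`: data.frame with `qname`, `read_seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  if (is.data.frame(reads)) {
    qname <- reads$qname; seqs <- reads$read_seq; qual <- reads$qual
  } else {
    qname <- names(reads); seqs <- unname(reads); qual <- strrep("F", nchar(seqs))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", qname, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # the reader notes that quality metadata moves to its own slot; harmless
  ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  seqs <- as.character(ss)
  data.frame(qname = sub("\\s.*$", "", names(ss)),
             read_seq = seqs,
             qual = as.character(Biostrings::quality(ss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

#' Read a SAM file (supported dialect)
#'
#' The package consumes a defined SAM subset: single-segment reads, FLAG 0,
#' 4 or 16, 1-based POS and CIGAR strings using only M, I, D and S
#' operations. Records outside this dialect raise an error naming the
#' offending read rather than being silently skipped.
#'
#' @param path File path.
#' @return A list with `header` (character vector of header lines) and
#'   `records` (data.frame with the 11 mandatory SAM columns; `flag`, `pos`,
#'   `mapq` integer).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(body))
    return(list(header = hdr,
                records = data.frame(matrix(nrow = 0, ncol = 11,
                                            dimnames = list(NULL, SAM_COLS)))))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) stopf("SAM record %d has fewer than 11 fields", which(nf < 11L)[1])
  take <- function(i) vapply(parts, `[[`, "", i)
  rec <- data.frame(qname = take(1), flag = as.integer(take(2)),
                    rname = take(3), pos = as.integer(take(4)),
                    mapq = as.integer(take(5)), cigar = take(6),
                    rnext = take(7), pnext = take(8), tlen = take(9),
                    seq = take(10), qual = take(11), stringsAsFactors = FALSE)
  bad_flag <- !(rec$flag %in% c(0L, 4L, 16L))
  if (any(bad_flag))
    stopf("unsupported FLAG %d in record '%s' (dialect allows 0/4/16)",
          rec$flag[bad_flag][1], rec$qname[bad_flag][1])
  mapped <- !bitwAnd(rec$flag, 4L)
  bad_cig <- mapped & grepl("[^0-9MIDS]", rec$cigar)
  if (any(bad_cig))
    stopf("unsupported CIGAR operation in record '%s' (cigar '%s')",
          rec$qname[bad_cig][1], rec$cigar[bad_cig][1])
  list(header = hdr, records = rec)
}

#' Write a SAM file for simulated true alignments
#'
#' @param reads A data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual` (e.g. from [simulate_reads()]).
#' @param genomes Reference genomes (list of [genome_record()]) for the
#'   `@SQ` header lines.
#' @param path File path.
#' @export
write_sam <- function(reads, genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(genomes, function(g)
             sprintf("@SQ\tSN:%s\tLN:%d", g$id, g$length), ""))
  body <- paste(reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
                reads$cigar, "*", 0L, 0L, reads$seq, reads$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write gene annotations (GFF3)
#'
#' `write_gff3()` emits one `CDS` feature per gene with an `ID` attribute;
#' `read_gff3()` parses via rtracklayer and returns the same gene table
#' shape used across the package (1-based fully-closed coordinates).
#'
#' @param genes Gene table (`gene_id`, `start`, `end`, `strand`).
#' @param seqid Sequence identifier the genes live on.
#' @param path File path.
#' @return `read_gff3()`: data.frame with `gene_id`, `seqid`, `start`,
#'   `end`, `strand`, `length`.
#' @export
write_gff3 <- function(genes, seqid, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tpaleovir\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     seqid, genes$start, genes$end, genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("read_gff3() requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(gene_id = as.character(gr$ID),
             seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             length = GenomicRanges::width(gr),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read and write tab-separated report tables
#'
#' All TSV reports use 1-based fully-closed coordinates and are written
#' without quoting or row names so outputs are byte-stable.
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `read_tsv()`: a data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an aligned FASTA pair as a pairwise alignment
#'
#' Consumes a pre-computed two-sequence alignment (e.g. from an external
#' aligner) as a [pairwise_alignment()].
#'
#' @param path Aligned FASTA with exactly two equal-length gapped sequences.
#' @return A [pairwise_alignment()].
#' @export
read_aligned_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2L) stopf("aligned FASTA must contain exactly two sequences")
  pairwise_alignment(as.character(ss[[1]]), as.character(ss[[2]]),
                     id_a = sub("\\s.*$", "", names(ss)[1]),
                     id_b = sub("\\s.*$", "", names(ss)[2]))
}

#' @rdname read_aligned_fasta
#' @param aln A [pairwise_alignment()].
#' @export
write_aligned_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  ss <- Biostrings::BStringSet(setNames(c(aln$aligned_a, aln$aligned_b),
                                        c(aln$id_a, aln$id_b)))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
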