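# Independent oracles used to cross-check package implementations.
# These deliberately share no code with the package internals.

# --- reference MCL: dense textbook implementation -------------------------
oracle_mcl <- function(adj, inflation, expansion = 2, iter = 300) {
  n <- nrow(adj)
  A <- (adj + t(adj)) / 2
  d <- apply(A, 1, max)
  d[d == 0] <- 1
  diag(A) <- d
  M <- t(t(A) / colSums(A))
  for (s in seq_len(iter)) {
    M2 <- M
    for (e in seq_len(expansion - 1)) M2 <- M2 %*% M
    M2 <- M2 ^ inflation
    M2 <- t(t(M2) / colSums(M2))
    if (max(abs(M2 - M)) < 1e-10) { M <- M2; break }
    M <- M2
  }
  # interpret: attractor rows are those with non-negligible diagonal
  attr_rows <- which(diag(M) > 1e-6)
  member <- rep(NA_integer_, n)
  cl <- 0
  for (i in attr_rows) {
    sup <- which(M[i, ] > 1e-6)
    known <- unique(member[sup])
    known <- known[!is.na(known)]
    if (length(known)) {
      keep <- min(known)
      member[member %in% known] <- keep
      member[sup] <- keep
    } else {
      cl <- cl + 1
      member[sup] <- cl
    }
  }
  for (i in which(is.na(member))) member[i] <- member[which.max(M[, i])]
  member
}

# --- exhaustive affine-gap global alignment score (Gotoh in plain R) ------
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + gap_ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + gap_ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext,
                             Y[i, j + 1] - gap_open - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext,
                             X[i + 1, j] - gap_open - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- coarse grid search for the damage-model MLE --------------------------
oracle_grid_fit <- function(n_c, n_ct) {
  ll <- function(d) sum(n_ct * log(pmax(d, 1e-12)) +
                          (n_c - n_ct) * log(pmax(1 - d, 1e-12)))
  i <- seq_along(n_c)
  best <- list(val = -Inf)
  for (d1 in seq(0.05, 0.6, by = 0.01))
    for (lam in seq(0.1, 1.5, by = 0.02))
      for (b in c(0.001, 0.005, 0.01, 0.02, 0.05)) {
        if (d1 < b) next
        v <- ll(b + (d1 - b) * exp(-lam * (i - 1)))
        if (v > best$val) best <- list(val = v, d1 = d1, lam = lam, b = b)
      }
  best
}

# --- adjusted Rand index (mclust) -----------------------------------------
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

membership_of <- function(cs) {
  df <- as.data.frame(cs)
  setNames(df$cluster_id, df$genome_id)
}

# hand-built SAM-style record frame
sam_records <- function(seqs, pos, flag = 0L, rname = "ref",
                        cigar = paste0(nchar(seqs), "M")) {
  n <- length(seqs)
  data.frame(qname = sprintf("r%03d", seq_len(n)),
             flag = rep_len(flag, n), rname = rep_len(rname, n),
             pos = rep_len(as.integer(pos), n), mapq = rep_len(60L, n),
             cigar = rep_len(cigar, n), seq = seqs,
             qual = strrep("F", nchar(seqs)), stringsAsFactors = FALSE)
}

# random amino-acid sequence (no stops)
random_protein <- function(len, seed) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, paste(sample(aa, len, replace = TRUE), collapse = ""))
}
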