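#' Damage profile container
#'
#' Per-position C-to-T mismatch counts over the first `P` read positions
#' (5' end, read coordinates) of reads mapped to one contig. `n_c_sites[i]`
#' counts read positions `i` whose aligned reference base is a cytosine (on
#' the read's strand); `n_ct[i]` counts those where the read shows a
#' thymine. `freq[i]` is their ratio, `NA` where no C sites were seen.
#'
#' @param contig_id Contig identifier.
#' @param n_c_sites,n_ct Integer vectors of equal length `P`.
#' @param n_reads Number of mapped reads profiled.
#' @param n_skipped Number of unmapped records skipped.
#' @return An object of class `damage_profile`.
#' @export
damage_profile <- function(contig_id, n_c_sites, n_ct, n_reads,
                           n_skipped = 0L) {
  stopifnot(length(n_c_sites) == length(n_ct),
            all(n_ct <= n_c_sites), all(n_ct >= 0))
  freq <- ifelse(n_c_sites > 0, n_ct / n_c_sites, NA_real_)
  structure(list(contig_id = contig_id, P = length(n_c_sites),
                 n_c_sites = as.integer(n_c_sites), n_ct = as.integer(n_ct),
                 freq = freq, n_reads = as.integer(n_reads),
                 n_skipped = as.integer(n_skipped)),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("<damage_profile> %s: %d reads, freq[1] = %s\n",
              x$contig_id, x$n_reads,
              if (is.na(x$freq[1])) "NA" else sprintf("%.4f", x$freq[1])))
  invisible(x)
}

#' @export
as.data.frame.damage_profile <- function(x, ...) {
  data.frame(contig_id = x$contig_id, position = seq_len(x$P),
             n_c_sites = x$n_c_sites, n_ct = x$n_ct, freq = x$freq,
             stringsAsFactors = FALSE)
}

# read_pos -> ref_pos map for one CIGAR (M/I/D/S); NA where no reference base
cigar_ref_map <- function(cigar, pos, read_len) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  n <- as.integer(sub("[MIDS]", "", ops))
  op <- substring(ops, nchar(ops), nchar(ops))
  map <- rep(NA_integer_, read_len)
  rp <- 0L; gp <- pos
  for (k in seq_along(op)) {
    if (op[k] == "M") {
      map[rp + seq_len(n[k])] <- gp + seq_len(n[k]) - 1L
      rp <- rp + n[k]; gp <- gp + n[k]
    } else if (op[k] == "I" || op[k] == "S") {
      rp <- rp + n[k]
    } else { # D
      gp <- gp + n[k]
    }
  }
  map
}

#' Compute a terminal C-to-T damage profile from alignments
#'
#' Counts C-to-T transitions at the first `P` positions of mapped reads,
#' measured in read coordinates from each read's 5' end: for forward reads
#' position `i` counts from the left read end; for reverse-complement-flagged
#' reads it counts from the right end on the reference with both bases
#' complemented, so a C-to-T in read space is observed as G-to-A in
#' reference space. The reference FASTA is authoritative (MD tags are not
#' used). Unmapped records (FLAG 4) are skipped with a message; unsupported
#' CIGAR operations raise an error naming the record.
#'
#' @param records SAM-style data.frame (from [read_sam()]`$records` or
#'   [simulate_reads()]`$reads`) for one contig.
#' @param reference The contig as a [genome_record()].
#' @param positions Number of terminal positions `P` to profile (default 20).
#' @return A [damage_profile()].
#' @export
compute_damage_profile <- function(records, reference, positions = 20L) {
  stopifnot(inherits(reference, "genome_record"))
  P <- as.integer(positions)
  if (nrow(records)) {
    foreign <- records$rname != reference$id
    if (any(foreign))
      stopf("record '%s' references contig '%s', not '%s'",
            records$qname[foreign][1], records$rname[foreign][1], reference$id)
  }
  unmapped <- bitwAnd(records$flag, 4L) > 0L
  n_skipped <- sum(unmapped)
  if (n_skipped) message(sprintf("skipped %d unmapped record(s)", n_skipped))
  rec <- records[!unmapped, , drop = FALSE]
  n_c <- integer(P); n_ct <- integer(P)
  if (!nrow(rec))
    return(damage_profile(reference$id, n_c, n_ct, 0L, n_skipped))

  bad <- grepl("[^0-9MIDS]", rec$cigar)
  if (any(bad))
    stopf("unsupported CIGAR operation in record '%s' (cigar '%s')",
          rec$qname[bad][1], rec$cigar[bad][1])

  refch <- chars(reference$seq)
  L <- reference$length
  simple <- grepl("^[0-9]+M$", rec$cigar)

  count_block <- function(seqs, lens, pos, reverse) {
    # vectorised over reads for each terminal offset
    for (i in seq_len(P)) {
      ok <- lens >= i
      if (!any(ok)) next
      if (!reverse) {
        rp <- i                     # index into SAM SEQ
        gp <- pos[ok] + i - 1L      # reference position
        want_ref <- "C"; want_read <- "T"
      } else {
        rp <- lens[ok] - i + 1L
        gp <- pos[ok] + lens[ok] - i
        want_ref <- "G"; want_read <- "A"
      }
      inb <- gp >= 1L & gp <= L
      if (!any(inb)) next
      rb <- refch[gp[inb]]
      sb <- substring(seqs[ok][inb], if (reverse) rp[inb] else rp,
                      if (reverse) rp[inb] else rp)
      is_c <- rb == want_ref
      n_c[i] <<- n_c[i] + sum(is_c)
      n_ct[i] <<- n_ct[i] + sum(is_c & sb == want_read)
    }
  }

  if (any(simple)) {
    s <- rec[simple, , drop = FALSE]
    lens <- nchar(s$seq)
    fwd <- s$flag == 0L
    if (any(fwd)) count_block(s$seq[fwd], lens[fwd], s$pos[fwd], FALSE)
    if (any(!fwd)) count_block(s$seq[!fwd], lens[!fwd], s$pos[!fwd], TRUE)
  }
  if (any(!simple)) {
    g <- rec[!simple, , drop = FALSE]
    for (k in seq_len(nrow(g))) {
      len <- nchar(g$seq[k])
      map <- cigar_ref_map(g$cigar[k], g$pos[k], len)
      reverse <- g$flag[k] == 16L
      for (i in seq_len(min(P, len))) {
        rp <- if (reverse) len - i + 1L else i
        gp <- map[rp]
        if (is.na(gp) || gp < 1L || gp > L) next
        rb <- refch[gp]
        sb <- substr(g$seq[k], rp, rp)
        want_ref <- if (reverse) "G" else "C"
        want_read <- if (reverse) "A" else "T"
        if (rb == want_ref) {
          n_c[i] <- n_c[i] + 1L
          if (sb == want_read) n_ct[i] <- n_ct[i] + 1L
        }
      }
    }
  }
  damage_profile(reference$id, n_c, n_ct, nrow(rec), n_skipped)
}

# binomial log-likelihood kernel for a damage curve d(i) (constants dropped)
damage_loglik <- function(d, n_c, n_ct) {
  d <- pmin(pmax(d, 1e-12), 1 - 1e-12)
  sum(n_ct * log(d) + (n_c - n_ct) * log1p(-d))
}

#' Fit the exponential-decay damage model by maximum likelihood
#'
#' Maximises the product of per-position binomial likelihoods
#' `Binom(n_ct[i] | n_c_sites[i], d(i))` with
#' `d(i) = b + (d1 - b) exp(-lam (i - 1))` over `(d1, lam, b)` (alternative)
#' and over a constant frequency (null). The likelihood-ratio statistic is
#' referred to a chi-square with 2 degrees of freedom; because the null lies
#' on the boundary (`d1 = b`) the resulting p-values are conservative, which
#' only makes the authentication filter stricter. The score reported is
#' `1 - p_value`. Optimisation uses 5 deterministic bounded starts
#' (L-BFGS-B, `d1, b` in `[1e-6, 0.99]`, `lam` in `[1e-3, 10]`); ties are
#' broken by the first start.
#'
#' @param profile A [damage_profile()].
#' @return An object of class `damage_fit` with `d1_hat`, `lam_hat`,
#'   `b_hat`, `loglik_alt`, `loglik_null`, `lr_stat`, `p_value`, `score`,
#'   and `sufficient` (`FALSE` when fewer than 3 positions have C sites).
#' @export
fit_damage_model <- function(profile) {
  stopifnot(inherits(profile, "damage_profile"))
  keep <- profile$n_c_sites > 0L
  out <- structure(list(contig_id = profile$contig_id,
                        d1_hat = NA_real_, lam_hat = NA_real_, b_hat = NA_real_,
                        loglik_alt = NA_real_, loglik_null = NA_real_,
                        lr_stat = NA_real_, p_value = NA_real_,
                        score = NA_real_, sufficient = FALSE),
                   class = "damage_fit")
  if (sum(keep) < 3L) return(out)
  i <- which(keep)
  n_c <- profile$n_c_sites[i]
  n_ct <- profile$n_ct[i]

  p0 <- sum(n_ct) / sum(n_c)
  ll0 <- damage_loglik(rep(p0, length(i)), n_c, n_ct)

  # parameterised as (delta, lam, b) with d1 = b + delta, guaranteeing d1 >= b
  negll <- function(par) {
    d <- par[3] + par[1] * exp(-par[2] * (i - 1))
    -damage_loglik(d, n_c, n_ct)
  }
  neggr <- function(par) {
    e <- exp(-par[2] * (i - 1))
    d <- pmin(pmax(par[3] + par[1] * e, 1e-12), 1 - 1e-12)
    dl_dd <- n_ct / d - (n_c - n_ct) / (1 - d)
    -c(sum(dl_dd * e),
       sum(dl_dd * (-par[1] * (i - 1) * e)),
       sum(dl_dd))
  }
  f1 <- profile$freq[1]
  starts <- list(c(0.30, 0.50, 0.010),
                 c(0.05, 0.30, max(p0, 1e-4)),
                 c(0.01, 1.00, 0.001),
                 c(max(min(f1 - p0, 0.9), 0.001), 0.30, max(p0, 1e-4)),
                 c(0.20, 0.10, 0.005))
  lower <- c(0, 1e-3, 1e-6)
  upper <- c(0.98, 10, 0.5)
  ctrl <- list(factr = 1e2, maxit = 500)  # tight: counts can reach 1e7
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(s, lower), upper), negll, gr = neggr,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best)) return(out)
  polish <- tryCatch(
    optim(best$par, negll, gr = neggr, method = "L-BFGS-B",
          lower = lower, upper = upper, control = ctrl),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < best$value) best <- polish

  ll1 <- max(-best$value, ll0)  # null is nested; guard numerical slack
  lr <- max(2 * (ll1 - ll0), 0)
  p <- pchisq(lr, df = 2L, lower.tail = FALSE)
  out$d1_hat <- best$par[3] + best$par[1]
  out$lam_hat <- best$par[2]
  out$b_hat <- best$par[3]
  out$loglik_alt <- ll1
  out$loglik_null <- ll0
  out$lr_stat <- lr
  out$p_value <- p
  out$score <- 1 - p
  out$sufficient <- TRUE
  out
}

#' @export
print.damage_fit <- function(x, ...) {
  cat(sprintf("<damage_fit> %s: d1=%.4f lam=%.3f b=%.4f LR=%.2f p=%.3g\n",
              x$contig_id, x$d1_hat, x$lam_hat, x$b_hat, x$lr_stat, x$p_value))
  invisible(x)
}

#' Locate the knee of a score curve (Kneedle)
#'
#' Normalises the sorted-descending score curve to the unit square, measures
#' the pointwise deviation from the straight chord joining its endpoints and
#' returns the score at the maximum deviation. When the curve stays within
#' `tol` of the chord everywhere (e.g. a straight line) there is no knee and
#' `NULL` is returned.
#'
#' @param scores Numeric scores, sorted in descending order (re-sorted if
#'   not).
#' @param tol Deviation below which the curve is considered chord-like.
#' @return The score at the knee (with attributes `knee_index` and `knee_x`,
#'   the normalised curve position), or `NULL` when no knee exists.
#' @export
kneedle_threshold <- function(scores, tol = 1e-6) {
  n <- length(scores)
  if (n < 3L) stopf("kneedle_threshold() needs at least 3 points")
  s <- sort(scores, decreasing = TRUE)
  if (max(s) == min(s)) return(NULL)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  chord <- 1 - x          # normalised endpoints are (0, 1) and (1, 0)
  dev <- abs(y - chord)
  if (max(dev) < tol) return(NULL)
  k <- which.max(dev)
  structure(s[k], knee_index = k, knee_x = x[k])
}

#' Apply the ancient-contig authentication filter
#'
#' A contig passes when its damage-model score is at least
#' `score_threshold`, its empirical first-position C-to-T frequency is at
#' least `min_first_pos` (the 0.01 cut-off guards against noise from the
#' sequencing error rate), and its profile carried enough data to fit the
#' model. Reasons for failure are recorded explicitly.
#'
#' @param fits List of [fit_damage_model()] results.
#' @param profiles List of matching [damage_profile()]s (same contigs, any
#'   order).
#' @param score_threshold Score cut-off, typically chosen by
#'   [kneedle_threshold()] on the score distribution.
#' @param min_first_pos Minimum empirical `freq[1]` (default 0.01).
#' @return A data.frame with `contig_id`, `passed`, `reasons`
#'   (semicolon-joined, empty when passed), `score` and `freq1`.
#' @export
authenticate_contigs <- function(fits, profiles, score_threshold,
                                 min_first_pos = 0.01) {
  if (inherits(fits, "damage_fit")) fits <- list(fits)
  if (inherits(profiles, "damage_profile")) profiles <- list(profiles)
  prof_ids <- vapply(profiles, `[[`, "", "contig_id")
  rows <- lapply(fits, function(f) {
    j <- match(f$contig_id, prof_ids)
    if (is.na(j)) stopf("missing profile for contig '%s'", f$contig_id)
    p <- profiles[[j]]
    reasons <- character()
    if (!isTRUE(f$sufficient) || p$n_reads == 0L || is.na(p$freq[1])) {
      reasons <- "insufficient_data"
    } else {
      if (f$score < score_threshold) reasons <- c(reasons, "below_score_threshold")
      if (p$freq[1] < min_first_pos) reasons <- c(reasons, "first_position_below_minimum")
    }
    data.frame(contig_id = f$contig_id, passed = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ";"),
               score = f$score, freq1 = p$freq[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
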