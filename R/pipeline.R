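#' Contig metadata table
#'
#' One row per contig with the plumbing fields used by the workflow
#' filters. `viral_votes` is a list-column of named logical vectors (one
#' entry per classification tool; may be empty).
#'
#' @param contig_id Character vector.
#' @param length Contig lengths (bp, >= 1).
#' @param assembly_coverage Assembly fold-coverage.
#' @param viral_votes List of named logical vectors (default: no votes).
#' @param quality_tier One of `"complete"`, `"high"`, `"medium"`, `"low"`,
#'   `"unknown"` (externally supplied; tiers are consumed, never computed).
#' @return A data.frame with a `viral_votes` list-column.
#' @export
contig_meta <- function(contig_id, length, assembly_coverage = NA_real_,
                        viral_votes = NULL, quality_tier = "unknown") {
  n <- base::length(contig_id)
  stopifnot(all(length >= 1))
  tiers <- c("complete", "high", "medium", "low", "unknown")
  quality_tier <- rep_len(quality_tier, n)
  if (!all(quality_tier %in% tiers)) stopf("unknown quality tier")
  out <- data.frame(contig_id = contig_id, length = as.integer(length),
                    assembly_coverage = rep_len(assembly_coverage, n),
                    quality_tier = quality_tier, stringsAsFactors = FALSE)
  out$viral_votes <- viral_votes %||% rep(list(logical()), n)
  out
}

#' Assembly-level contig filter
#'
#' Keeps contigs strictly longer than `min_len` (the "longer than" rule)
#' with assembly coverage at least `min_cov`.
#'
#' @param metas A [contig_meta()] table.
#' @param min_len Length cut-off in bp (strict, default 4000).
#' @param min_cov Coverage cut-off (inclusive, default 20).
#' @return The qualifying subset of `metas`.
#' @export
filter_contigs <- function(metas, min_len = 4000L, min_cov = 20) {
  keep <- metas$length > min_len & !is.na(metas$assembly_coverage) &
    metas$assembly_coverage >= min_cov
  metas[keep, , drop = FALSE]
}

#' Consensus viral call across classification tools
#'
#' Keeps contigs classified as viral by at least `min_votes` tools.
#'
#' @param metas A [contig_meta()] table.
#' @param min_votes Minimum number of positive votes (default 2).
#' @return The qualifying subset of `metas`.
#' @export
consensus_viral_call <- function(metas, min_votes = 2L) {
  votes <- vapply(metas$viral_votes, function(v) sum(as.logical(v)), 1)
  metas[votes >= min_votes, , drop = FALSE]
}

#' Select the analysis set by length or quality tier
#'
#' Keeps contigs at least `min_len_alt` bp long, or assessed as medium or
#' better quality.
#'
#' @param metas A [contig_meta()] table.
#' @param min_len_alt Length arm of the rule (inclusive, default 20000).
#' @return The qualifying subset of `metas`.
#' @export
select_analysis_set <- function(metas, min_len_alt = 20000L) {
  keep <- metas$length >= min_len_alt |
    metas$quality_tier %in% c("medium", "high", "complete")
  metas[keep, , drop = FALSE]
}

#' Run configuration for the end-to-end pipeline
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param stages Character subset of `c("simulate", "damage", "cluster")`,
#'   executed in that order.
#' @param community Arguments passed to [make_community()] (minus `seed`
#'   and `outdir`).
#' @param damage_opts List with `positions` and `min_first_pos`.
#' @param votu A [votu_config()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L,
                       stages = c("simulate", "damage", "cluster"),
                       community = list(n_ancient = 5L, n_modern = 5L),
                       damage_opts = list(positions = 20L, min_first_pos = 0.01),
                       votu = votu_config()) {
  stopifnot(is.character(outdir), base::length(outdir) == 1L)
  bad <- setdiff(stages, c("simulate", "damage", "cluster"))
  if (base::length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (base::length(stages) && !"simulate" %in% stages)
    stopf("the damage and cluster stages consume the simulate stage output")
  stopifnot(is.numeric(seed), is.list(community), is.list(damage_opts),
            inherits(votu, "votu_config"))
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 community = community, damage_opts = damage_opts,
                 votu = votu),
            class = "run_config")
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  message(sprintf("[paleovir] stage %-8s done in %.1fs", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the end-to-end synthetic workflow
#'
#' Executes the enabled stages in order — simulate a community, profile and
#' authenticate damage, cluster genomes into vOTUs — writing TSV reports
#' and a JSON manifest of all inputs, seeds and parameters. Re-running the
#' same configuration reproduces every output byte for byte.
#'
#' @param config A [run_config()].
#' @return A list with `manifest`, `decisions`, `clusters`, `profiles` and
#'   `paths` (stages that did not run are `NULL`).
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(manifest = file.path(config$outdir, "manifest.json"))
  decisions <- clusters <- profiles <- NULL
  community <- NULL

  if ("simulate" %in% config$stages) {
    community <- run_stage("simulate", do.call(make_community, c(
      config$community, list(seed = config$seed, outdir = config$outdir))))
    paths <- c(paths, as.list(community$files))
  }

  if ("damage" %in% config$stages) {
    res <- run_stage("damage", {
      ids <- vapply(community$genomes, `[[`, "", "id")
      profs <- lapply(seq_along(ids), function(i) {
        rec <- community$reads[community$reads$rname == ids[i], , drop = FALSE]
        compute_damage_profile(rec, community$genomes[[i]],
                               config$damage_opts$positions %||% 20L)
      })
      fits <- lapply(profs, fit_damage_model)
      scores <- vapply(fits, `[[`, 1, "score")
      thr <- if (sum(!is.na(scores)) >= 3L)
        kneedle_threshold(scores[!is.na(scores)]) else NULL
      thr <- as.numeric(thr %||% 0.5)
      dec <- authenticate_contigs(fits, profs, thr,
                                  config$damage_opts$min_first_pos %||% 0.01)
      dec$score_threshold <- thr
      list(profiles = profs, decisions = dec)
    })
    profiles <- res$profiles
    decisions <- res$decisions
    paths$profiles <- file.path(config$outdir, "damage_profiles.tsv")
    paths$decisions <- file.path(config$outdir, "authentication.tsv")
    write_tsv(do.call(rbind, lapply(profiles, as.data.frame)), paths$profiles)
    write_tsv(decisions, paths$decisions)
  }

  if ("cluster" %in% config$stages) {
    clusters <- run_stage("cluster",
      votu_cluster(community$genomes, cfg = config$votu))
    paths$clusters <- file.path(config$outdir, "votu_clusters.tsv")
    write_tsv(as.data.frame(clusters), paths$clusters)
  }

  strip_classes <- function(x)
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  manifest <- list(
    package = "paleovir",
    seed = config$seed,
    stages = config$stages,
    parameters = strip_classes(list(
      community = config$community,
      damage_opts = config$damage_opts,
      votu = config$votu)),
    outputs = lapply(paths[names(paths) != "manifest"], basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  list(manifest = manifest, decisions = decisions, clusters = clusters,
       profiles = profiles, paths = paths)
}
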