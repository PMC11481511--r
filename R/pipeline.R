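#' Assemble a pipeline configuration
#'
#' Collects every stage's parameters (or accepts a YAML file with the same
#' field names). Either a synthetic community is generated (`simulate =
#' TRUE`, governed by `sim`) or input paths must be supplied (`fasta`,
#' `predictions`, `metadata`, optionally a precomputed ANI matrix pair via
#' `ani_prefix`).
#'
#' @param simulate Generate inputs with [generate_community()]?
#' @param sim A [sim_config()] (used when `simulate = TRUE`).
#' @param fasta,predictions,metadata Input paths (when `simulate = FALSE`).
#' @param ani_prefix Optional prefix of a precomputed identity/coverage
#'   matrix pair (skips ANI computation).
#' @param min_completeness,min_contig QC filter thresholds.
#' @param ani An [ani_params()] object.
#' @param cluster A [cluster_params()] object.
#' @param lenient A second [cluster_params()] used for the clustering
#'   comparison (default 70/70), or `NULL` to skip.
#' @param prefix Species name prefix.
#' @param seed Master seed; all stochastic stages derive their sub-seeds
#'   from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(seed = seed),
                            fasta = NULL, predictions = NULL,
                            metadata = NULL, ani_prefix = NULL,
                            min_completeness = 50, min_contig = 30000,
                            ani = ani_params(),
                            cluster = cluster_params(),
                            lenient = cluster_params(min_identity = 70,
                                                     min_coverage = 70),
                            prefix = "Ab_PS", seed = 1L) {
  if (!simulate) {
    fields <- c("fasta", "predictions", "metadata")
    vals <- list(fasta = fasta, predictions = predictions,
                 metadata = metadata)
    absent <- fields[vapply(vals, is.null, logical(1))]
    if (length(absent)) {
      stop("config field(s) required when simulate = FALSE: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    for (field in fields) {
      if (!file.exists(vals[[field]])) {
        stop(sprintf("config field `%s`: path does not exist: %s",
                     field, vals[[field]]), call. = FALSE)
      }
    }
  }
  structure(list(simulate = isTRUE(simulate), sim = sim, fasta = fasta,
                 predictions = predictions, metadata = metadata,
                 ani_prefix = ani_prefix,
                 min_completeness = min_completeness,
                 min_contig = min_contig, ani = ani, cluster = cluster,
                 lenient = lenient, prefix = prefix,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim`,
#' `ani`, `cluster` and `lenient` blocks mirror [sim_config()],
#' [ani_params()] and [cluster_params()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  build <- function(fun, block, extra = list()) {
    do.call(fun, utils::modifyList(extra, as.list(block)))
  }
  args <- list(
    simulate = if (is.null(y$simulate)) TRUE else isTRUE(y$simulate),
    seed = seed,
    sim = build(sim_config, y$sim, list(seed = seed)),
    ani = build(ani_params, y$ani),
    cluster = build(cluster_params, y$cluster))
  if (!is.null(y$lenient)) args$lenient <- build(cluster_params, y$lenient)
  for (field in c("fasta", "predictions", "metadata", "ani_prefix",
                  "min_completeness", "min_contig", "prefix")) {
    if (!is.null(y[[field]])) args[[field]] <- y[[field]]
  }
  do.call(pipeline_config, args)
}

log_stage <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}

#' Run the full prophage species pipeline
#'
#' Orchestrates simulate (optional) -> QC -> ANI -> species clustering ->
#' host range / geography / polylysogeny / diversity, writing every
#' artifact and a machine-readable JSON summary into `outdir`. Given the
#' same configuration (including seed) a rerun is byte-identical.
#'
#' @param config A [pipeline_config()] object.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the summary list (also written to
#'   `<outdir>/summary.json`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file(file.path(outdir, "pipeline.log"), open = "wt")
  on.exit(close(logfile))

  ## inputs
  if (config$simulate) {
    community <- generate_community(config$sim)
    write_community(community, file.path(outdir, "input"))
    seqs <- community$sequences
    predictions <- community$predictions
    meta <- community$metadata
    profiles <- community$st_profiles
    truth <- community$truth
    log_stage(logfile, "simulate: %d prophages, %d genomes (seed %d)",
              length(seqs), nrow(meta), config$sim$seed)
  } else {
    seqs <- as_seq_vector(Biostrings::readDNAStringSet(config$fasta))
    predictions <- parse_predictions(config$predictions)
    meta <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
    allele_cols <- paste0("allele_", 1:7)
    profiles <- if (all(allele_cols %in% names(meta))) {
      unique(meta[!is.na(meta$st) & meta$st != "", c("st", allele_cols)])
    } else NULL
    truth <- NULL
    log_stage(logfile, "load: %d sequences, %d predictions, %d genomes",
              length(seqs), nrow(predictions), nrow(meta))
  }

  ## qc
  predictions <- parse_predictions(predictions)
  resolved <- resolve_multicontig(predictions)
  filt <- filter_predictions(resolved$records, config$min_completeness,
                             config$min_contig)
  kept <- filt$kept
  log_stage(logfile, "qc: %d in, %d merged contigs, %d kept, %d dropped",
            nrow(predictions), nrow(resolved$report), nrow(kept),
            nrow(filt$dropped))
  utils::write.table(kept, file.path(outdir, "kept_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(filt$dropped, file.path(outdir, "dropped_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  missing_seq <- setdiff(kept$prophage_id, names(seqs))
  if (length(missing_seq)) {
    stop("stage ani: no sequence for kept prophage(s): ",
         paste(missing_seq, collapse = ", "), call. = FALSE)
  }
  seqs <- seqs[kept$prophage_id]

  ## ani
  if (!is.null(config$ani_prefix)) {
    mat <- read_ani_matrix(config$ani_prefix)
    log_stage(logfile, "ani: loaded precomputed matrix over %d ids",
              length(mat$ids))
  } else {
    mat <- compute_ani_matrix(seqs, config$ani)
    log_stage(logfile, "ani: %d x %d matrix (%s backend)",
              length(mat$ids), length(mat$ids), config$ani$method)
  }
  write_ani_matrix(mat, file.path(outdir, "ani"))

  ## clustering
  graph <- build_graph(mat, config$cluster)
  partition <- name_species(
    paraclique_partition(graph, config$cluster$glom),
    prefix = config$prefix, params = config$cluster)
  log_stage(logfile, "cluster: %d species (%d singletons) from %d sequences",
            length(partition$species), sum(partition$singleton),
            sum(partition$sizes))
  utils::write.table(summary(partition),
                     file.path(outdir, "species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(partition, graph, file.path(outdir, "network"),
                 records = kept, meta = meta)
  violations <- check_superinfection_exclusion(partition, kept)

  ## epidemiology
  summary_df <- species_summary(partition, kept, meta, profiles = profiles)
  utils::write.table(summary_df, file.path(outdir, "species_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  geo <- geo_dispersion(partition, kept, meta)
  fences_all <- tukey_fences(geo$n_countries)
  proper <- geo$n_countries[!partition$singleton[geo$species]]
  fences_proper <- if (length(proper)) tukey_fences(proper) else NULL
  utils::write.table(species_st_incidence(partition, kept, meta),
                     file.path(outdir, "species_by_st.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  hybrids <- hybrid_host_species(partition, kept, meta)

  ## polylysogeny
  counts <- counts_per_genome(kept, meta)
  utils::write.table(counts, file.path(outdir, "counts_per_genome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  kw_host <- if ("host" %in% names(counts) &&
                 length(unique(stats::na.omit(counts$host))) >= 2) {
    kruskal_wallis(counts$n_prophages[!is.na(counts$host)],
                   counts$host[!is.na(counts$host)])
  } else NULL
  intra <- intra_genome_ani(kept, mat)
  utils::write.table(intra$pairs, file.path(outdir, "intra_genome_ani.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(logfile, "polylysogeny: %d intra-genome pairs, mean ANI %.4f",
            intra$n_pairs, if (intra$n_pairs) intra$mean else NA)

  ## diversity
  inc <- build_incidence(partition, kept)
  curve <- accumulation_exact(inc)
  utils::write.table(as.data.frame(curve),
                     file.path(outdir, "accumulation_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sstats <- singleton_stats(partition)
  comparison <- if (!is.null(config$lenient)) {
    lenient_partition <- name_species(
      paraclique_partition(build_graph(mat, config$lenient),
                           config$lenient$glom),
      prefix = config$prefix, params = config$lenient)
    compare_clusterings(partition, lenient_partition)
  } else NULL

  ## summary
  recovered <- if (!is.null(truth)) {
    truth_split <- split(truth$prophages$prophage_id,
                         truth$prophages$true_species_id)
    keep_ids <- kept$prophage_id
    truth_split <- lapply(truth_split, function(v) sort_ids(intersect(v, keep_ids)))
    truth_split <- truth_split[lengths(truth_split) > 0]
    found <- lapply(partition$species, sort_ids)
    identical(sort(unname(vapply(truth_split, paste, "", collapse = ","))),
              sort(unname(vapply(found, paste, "", collapse = ","))))
  } else NA
  summary <- list(
    n_predictions = nrow(predictions),
    n_kept = nrow(kept),
    n_dropped = nrow(filt$dropped),
    n_species = length(partition$species),
    n_singletons = sstats$n_singletons,
    singleton_fraction = sstats$singleton_fraction,
    largest_species = unname(partition$sizes[1]),
    superinfection_violations = nrow(violations),
    truth_recovered = recovered,
    intra_genome_ani_mean = intra$mean,
    intra_genome_ani_sd = intra$sd,
    n_intra_genome_pairs = intra$n_pairs,
    country_upper_fence = fences_all$upper,
    country_upper_fence_proper = if (is.null(fences_proper)) NA else fences_proper$upper,
    country_median = stats::median(geo$n_countries),
    n_hybrid_host_species = nrow(hybrids),
    kruskal_wallis_host = if (is.null(kw_host)) NULL else
      kw_host[c("H", "df", "p")],
    accumulation_endpoint = curve$expected[nrow(curve)],
    clustering_comparison = if (is.null(comparison)) NULL else list(
      ks_D = comparison$ks$D, ks_p = comparison$ks$p,
      refinement = comparison$refinement,
      lenient_n_species = comparison$lenient_stats$n_species),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_stage(logfile, "done: %d species, summary written", summary$n_species)
  invisible(summary)
}
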