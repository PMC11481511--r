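#' Configuration for the synthetic prophage-community generator
#'
#' Defines the ground-truth structure of a simulated prophage community:
#' how many species, their size distribution (many singletons, a few very
#' large "cosmopolitan" species), the within-species sequence divergence, and
#' the bacterial host population (genomes, MLST sequence types, countries,
#' host categories) the prophages are placed into.
#'
#' Defaults describe a desk-scale community with the empirical shape of a
#' large prophage survey: 40 species of which 72% are singletons, two
#' cosmopolitan species (sizes 30 and 15) spanning 6 and 4 sequence types
#' respectively, all other species confined to a single ST, ancestors of
#' 30-60 kb, and 1% within-species substitution divergence.
#'
#' @param n_species Total number of true species.
#' @param frac_singletons Fraction of species with exactly one member.
#' @param cosmopolitan_sizes Integer vector of member counts for the
#'   designated broad-host-range species.
#' @param cosmopolitan_st_spread Integer vector (same length) giving the
#'   number of distinct STs each cosmopolitan species must span.
#' @param other_size_range Range (min, max) of member counts for the
#'   remaining multi-member, single-ST species.
#' @param within_divergence Per-site substitution probability applied to each
#'   member relative to its species ancestor (default 0.01).
#' @param indel_rate Per-site indel probability (default 5e-4); indel lengths
#'   are geometric with mean 2, capped at 10.
#' @param ancestor_length_range Ancestor length interval in bp.
#' @param n_genomes,n_sts,n_countries Host population dimensions.
#' @param host_mix Named proportions over `c(human, animal, plant)`.
#' @param flank Flanking bp added on each side of a prophage when composing
#'   the synthetic contig (contig_length = prophage length + 2 * flank).
#' @param n_subthreshold Number of extra below-threshold prediction rows
#'   (low completeness / short contig) injected for filter testing.
#' @param superinfection_exclusion If `TRUE` (default) no genome receives two
#'   members of the same species.
#' @param seed Integer seed; a fixed config is byte-reproducible.
#' @return An object of class `sim_config`.
#' @seealso [generate_community()]
#' @export
sim_config <- function(n_species = 40L,
                       frac_singletons = 0.72,
                       cosmopolitan_sizes = c(30L, 15L),
                       cosmopolitan_st_spread = c(6L, 4L),
                       other_size_range = c(2L, 6L),
                       within_divergence = 0.01,
                       indel_rate = 5e-4,
                       ancestor_length_range = c(30000L, 60000L),
                       n_genomes = 100L,
                       n_sts = 12L,
                       n_countries = 8L,
                       host_mix = c(human = 0.70, animal = 0.25, plant = 0.05),
                       flank = 5000L,
                       n_subthreshold = 0L,
                       superinfection_exclusion = TRUE,
                       seed = 1L) {
  check_scalar_number(n_species, "n_species", min = 1)
  check_scalar_number(frac_singletons, "frac_singletons", min = 0, max = 1)
  check_scalar_number(within_divergence, "within_divergence", min = 0, max = 1)
  check_scalar_number(indel_rate, "indel_rate", min = 0, max = 1)
  check_scalar_number(seed, "seed")
  if (length(cosmopolitan_sizes) != length(cosmopolitan_st_spread)) {
    stop("cosmopolitan_sizes and cosmopolitan_st_spread must have equal length",
         call. = FALSE)
  }
  if (any(cosmopolitan_st_spread > cosmopolitan_sizes)) {
    stop("a species cannot span more STs than it has members", call. = FALSE)
  }
  if (any(cosmopolitan_st_spread > n_sts)) {
    stop("cosmopolitan_st_spread exceeds n_sts", call. = FALSE)
  }
  if (abs(sum(host_mix) - 1) > 1e-8 || any(host_mix < 0)) {
    stop("host_mix must be non-negative proportions summing to 1", call. = FALSE)
  }
  if (!setequal(names(host_mix), c("human", "animal", "plant"))) {
    stop("host_mix must be named human, animal, plant", call. = FALSE)
  }
  n_singletons <- round(frac_singletons * n_species)
  n_cosmo <- length(cosmopolitan_sizes)
  if (n_singletons + n_cosmo > n_species) {
    stop("singleton fraction plus cosmopolitan species exceed n_species",
         call. = FALSE)
  }
  structure(list(
    n_species = as.integer(n_species),
    frac_singletons = frac_singletons,
    n_singletons = as.integer(n_singletons),
    cosmopolitan_sizes = as.integer(cosmopolitan_sizes),
    cosmopolitan_st_spread = as.integer(cosmopolitan_st_spread),
    other_size_range = as.integer(other_size_range),
    within_divergence = within_divergence,
    indel_rate = indel_rate,
    ancestor_length_range = as.integer(ancestor_length_range),
    n_genomes = as.integer(n_genomes),
    n_sts = as.integer(n_sts),
    n_countries = as.integer(n_countries),
    host_mix = host_mix,
    flank = as.integer(flank),
    n_subthreshold = as.integer(n_subthreshold),
    superinfection_exclusion = isTRUE(superinfection_exclusion),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate unrelated ancestor sequences
#'
#' Ancestors are i.i.d. uniform-random A/C/G/T sequences, so any two of them
#' share no detectable homology: between-species ANI is 0 at every threshold
#' studied, which makes the true partition recoverable by construction.
#'
#' @param n Number of ancestors (>= 1).
#' @param length_range Length interval in bp, `c(min, max)`.
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
generate_ancestors <- function(n, length_range = c(30000L, 60000L), seed = 1L) {
  check_scalar_number(n, "n", min = 1)
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[2] < length_range[1]) {
    stop("length_range must be a valid bp interval with positive bounds",
         call. = FALSE)
  }
  with_seed(seed, {
    lens <- sample(seq.int(length_range[1], length_range[2]), n, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

#' Mutate a nucleotide sequence
#'
#' Applies independent per-site substitutions (always to a different base)
#' and indels. Indel lengths are geometric with mean 2, capped at
#' `max_indel`; insertions and deletions are equally likely.
#'
#' @param seq A single nucleotide string.
#' @param sub_rate Per-site substitution probability, in `[0, 1)`.
#' @param indel_rate Per-site indel probability, in `[0, 1)`.
#' @param seed Integer seed.
#' @param max_indel Maximum indel length (default 10).
#' @return The mutated sequence (single string).
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate, seed = 1L,
                            max_indel = 10L) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("seq must be a single non-empty nucleotide string", call. = FALSE)
  }
  check_scalar_number(sub_rate, "sub_rate", min = 0, max = 1 - 1e-12)
  check_scalar_number(indel_rate, "indel_rate", min = 0, max = 1 - 1e-12)
  if (sub_rate == 0 && indel_rate == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(chars)
    sub_pos <- which(stats::runif(n) < sub_rate)
    if (length(sub_pos)) {
      chars[sub_pos] <- vapply(chars[sub_pos], function(b) {
        sample(bases[bases != b], 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    indel_pos <- which(stats::runif(n) < indel_rate)
    # apply right-to-left so earlier positions stay valid
    for (p in rev(indel_pos)) {
      len <- min(1L + stats::rgeom(1L, 0.5), max_indel)
      if (stats::runif(1) < 0.5) {
        del_end <- min(p + len - 1L, length(chars))
        if (p <= length(chars)) chars <- chars[-(p:del_end)]
      } else {
        chars <- append(chars, sample(bases, len, replace = TRUE), after = p)
      }
    }
    paste(chars, collapse = "")
  })
}

#' Generate a synthetic prophage community with known species structure
#'
#' Draws species sizes from the configured distribution, derives each member
#' from its species ancestor at the within-species divergence, and places
#' every prophage in a bacterial genome such that non-cosmopolitan species
#' stay within one sequence type while each cosmopolitan species spans
#' exactly its configured number of STs. Genome-level metadata (ST with a
#' 7-locus allelic profile, country, host category, year) is generated
#' alongside, together with a ground-truth table.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_community`: a list with elements
#'   `sequences` (named character vector), `predictions` (data.frame:
#'   prophage_id, genome_id, contig_id, contig_length, start, end,
#'   completeness), `metadata` (data.frame: genome_id, st, allele_1..7,
#'   host, host_detail, country, year), `st_profiles`, `truth` (list of
#'   `prophages` and `genomes` data.frames) and `config`.
#' @export
generate_community <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be a sim_config object", call. = FALSE)
  }
  n_cosmo <- length(config$cosmopolitan_sizes)
  n_other <- config$n_species - config$n_singletons - n_cosmo

  with_seed(config$seed, {
    ## species sizes and ST spreads
    other_sizes <- if (n_other > 0) {
      sample(seq.int(config$other_size_range[1], config$other_size_range[2]),
             n_other, replace = TRUE)
    } else integer(0)
    sizes <- c(config$cosmopolitan_sizes, other_sizes,
               rep(1L, config$n_singletons))
    spreads <- c(config$cosmopolitan_st_spread, rep(1L, n_other),
                 rep(1L, config$n_singletons))
    species_ids <- sprintf("sp%02d", seq_along(sizes))

    ## host population: genomes near-balanced over STs, then metadata
    sts <- sprintf("ST%d", seq_len(config$n_sts))
    genome_ids <- sprintf("g%03d", seq_len(config$n_genomes))
    genome_st <- sample(rep_len(sts, config$n_genomes))
    countries <- c("MX", "US", "FR", "DE", "CN", "JP", "BR", "ZA", "IN", "AU",
                   "GB", "IT", "ES", "KR", "CA", "AR")[seq_len(config$n_countries)]
    genome_country <- sample(countries, config$n_genomes, replace = TRUE)
    genome_host <- sample(names(config$host_mix), config$n_genomes,
                          replace = TRUE, prob = config$host_mix)
    detail_pool <- list(human = "Homo sapiens",
                        animal = c("Canis lupus familiaris", "Sus scrofa",
                                   "Gallus gallus"),
                        plant = c("grass", "Zea mays"))
    genome_detail <- vapply(genome_host, function(h) {
      pool <- detail_pool[[h]]
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, character(1), USE.NAMES = FALSE)
    genome_year <- sample(1980:2020, config$n_genomes, replace = TRUE)

    ## distinct 7-locus allelic profiles per ST
    repeat {
      profiles <- matrix(sample(1:25, config$n_sts * 7L, replace = TRUE),
                         nrow = config$n_sts, ncol = 7L)
      if (!anyDuplicated(apply(profiles, 1L, paste, collapse = "-"))) break
    }
    st_profiles <- data.frame(st = sts, profiles)
    names(st_profiles) <- c("st", paste0("allele_", 1:7))

    ## assign species to STs and members to genomes
    genomes_by_st <- split(genome_ids, genome_st)
    assign_rows <- vector("list", length(sizes))
    for (si in seq_along(sizes)) {
      size <- sizes[si]
      spread <- spreads[si]
      chosen_sts <- sample(sts, spread)
      # partition members near-evenly over the chosen STs
      per_st <- rep(size %/% spread, spread) +
        (seq_len(spread) <= size %% spread)
      member_genomes <- character(0)
      for (ki in seq_len(spread)) {
        pool <- genomes_by_st[[chosen_sts[ki]]]
        if (is.null(pool)) pool <- character(0)
        if (config$superinfection_exclusion && per_st[ki] > length(pool)) {
          stop(sprintf(
            "cannot place species %s: %d members requested in %s but only %d genomes available",
            species_ids[si], per_st[ki], chosen_sts[ki], length(pool)),
            call. = FALSE)
        }
        member_genomes <- c(member_genomes,
                            sample(pool, per_st[ki],
                                   replace = !config$superinfection_exclusion))
      }
      assign_rows[[si]] <- data.frame(
        true_species_id = species_ids[si],
        member = seq_len(size),
        genome_id = member_genomes,
        stringsAsFactors = FALSE)
    }
    truth_prophages <- do.call(rbind, assign_rows)
    truth_prophages$prophage_id <- sprintf(
      "sim|%s|m%02d", truth_prophages$true_species_id, truth_prophages$member)
    truth_prophages <- truth_prophages[
      , c("prophage_id", "true_species_id", "genome_id")]

    ## sequences: ancestors then per-member mutants
    ancestors <- generate_ancestors(length(sizes),
                                    config$ancestor_length_range,
                                    seed = sub_seed(config$seed, 1L))
    seqs <- character(nrow(truth_prophages))
    names(seqs) <- truth_prophages$prophage_id
    row <- 0L
    for (si in seq_along(sizes)) {
      for (mi in seq_len(sizes[si])) {
        row <- row + 1L
        seqs[row] <- mutate_sequence(
          ancestors[si], config$within_divergence, config$indel_rate,
          seed = sub_seed(config$seed, 1000L + row))
      }
    }

    ## prediction table: one contig per prophage, prophage centred in flanks
    lens <- nchar(seqs)
    predictions <- data.frame(
      prophage_id = truth_prophages$prophage_id,
      genome_id = truth_prophages$genome_id,
      contig_id = paste0(truth_prophages$genome_id, "_ctg",
                         stats::ave(seq_along(lens), truth_prophages$genome_id,
                                    FUN = seq_along)),
      contig_length = lens + 2L * config$flank,
      start = config$flank + 1L,
      end = config$flank + lens,
      completeness = 100,
      stringsAsFactors = FALSE)

    ## optional below-threshold rows for filter testing
    if (config$n_subthreshold > 0L) {
      extra_seq <- generate_ancestors(config$n_subthreshold, c(5000L, 20000L),
                                      seed = sub_seed(config$seed, 2L))
      extra_id <- sprintf("sim|sub|m%02d", seq_len(config$n_subthreshold))
      names(extra_seq) <- extra_id
      extra_len <- nchar(extra_seq)
      low_completeness <- seq_len(config$n_subthreshold) %% 2L == 1L
      extra <- data.frame(
        prophage_id = extra_id,
        genome_id = sample(genome_ids, config$n_subthreshold, replace = TRUE),
        contig_id = paste0("sub_ctg", seq_len(config$n_subthreshold)),
        contig_length = ifelse(low_completeness, extra_len + 30000L,
                               extra_len + 1000L),
        start = 1L,
        end = extra_len,
        completeness = ifelse(low_completeness, 40, 100),
        stringsAsFactors = FALSE)
      predictions <- rbind(predictions, extra)
      seqs <- c(seqs, extra_seq)
    }

    metadata <- data.frame(genome_id = genome_ids, st = genome_st,
                           stringsAsFactors = FALSE)
    metadata <- merge(metadata, st_profiles, by = "st", sort = FALSE)
    metadata <- metadata[match(genome_ids, metadata$genome_id),
                         c("genome_id", "st", paste0("allele_", 1:7))]
    metadata$host <- genome_host
    metadata$host_detail <- genome_detail
    metadata$country <- genome_country
    metadata$year <- genome_year
    rownames(metadata) <- NULL

    truth_genomes <- data.frame(genome_id = genome_ids, st = genome_st,
                                country = genome_country, host = genome_host,
                                stringsAsFactors = FALSE)

    structure(list(sequences = seqs,
                   predictions = predictions,
                   metadata = metadata,
                   st_profiles = st_profiles,
                   truth = list(prophages = truth_prophages,
                                genomes = truth_genomes),
                   config = config),
              class = "sim_community")
  })
}

#' @export
print.sim_community <- function(x, ...) {
  cat("Synthetic prophage community\n")
  cat(sprintf("  %d prophages in %d true species; %d genomes, %d STs, %d countries\n",
              length(x$sequences), length(unique(x$truth$prophages$true_species_id)),
              x$config$n_genomes, x$config$n_sts, x$config$n_countries))
  cat(sprintf("  within-species divergence %.3g, indel rate %.3g, seed %d\n",
              x$config$within_divergence, x$config$indel_rate, x$config$seed))
  invisible(x)
}

#' Write a synthetic community to disk
#'
#' Writes the prophage FASTA, the prediction table, the genome metadata and
#' the truth table as plain-text files under `outdir`.
#'
#' @param community A `sim_community`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_community <- function(community, outdir) {
  if (!inherits(community, "sim_community")) {
    stop("community must be a sim_community", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(outdir, "prophages.fasta"),
    predictions = file.path(outdir, "predictions.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    truth = file.path(outdir, "truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(community$sequences), paths[["fasta"]])
  utils::write.table(community$predictions, paths[["predictions"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(community$metadata, paths[["metadata"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(community$truth$prophages, paths[["truth"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
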