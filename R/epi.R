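# Host-population integration: per-species host range over MLST sequence
# types, allelic distances, geographic dispersion, Tukey fences, and
# cross-host ("hybrid") species.

join_genomes <- function(partition, records, meta) {
  membership <- partition_membership(partition)
  ids <- names(membership)
  genome <- records$genome_id[match(ids, records$prophage_id)]
  if (anyNA(genome)) {
    stop("prophage(s) without genome mapping: ",
         paste(ids[is.na(genome)], collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(genome), meta$genome_id)
  if (length(unknown)) {
    stop("genome id(s) absent from metadata: ",
         paste(sort_ids(unknown), collapse = ", "), call. = FALSE)
  }
  mrow <- match(genome, meta$genome_id)
  data.frame(prophage_id = ids,
             species = unname(membership),
             genome_id = genome,
             st = if ("st" %in% names(meta)) as.character(meta$st[mrow]) else NA_character_,
             country = if ("country" %in% names(meta)) as.character(meta$country[mrow]) else NA_character_,
             host = if ("host" %in% names(meta)) as.character(meta$host[mrow]) else NA_character_,
             stringsAsFactors = FALSE)
}

na_or_empty <- function(x) is.na(x) | x == ""

#' Host range of each species over sequence types
#'
#' For every species, the set of MLST sequence types of the genomes its
#' members reside in. Members without an ST assignment are excluded from the
#' range but counted; species with no ST-assigned member are flagged
#' unassigned.
#'
#' @param partition A `species_partition`.
#' @param records Prediction data.frame (prophage_id, genome_id).
#' @param meta Genome metadata data.frame with columns `genome_id`, `st`.
#' @return A data.frame: species, n_members, n_members_with_st, n_sts, sts
#'   (comma-separated), unassigned.
#' @export
host_range <- function(partition, records, meta) {
  j <- join_genomes(partition, records, meta)
  out <- do.call(rbind, lapply(names(partition$species), function(sp) {
    sub <- j[j$species == sp, , drop = FALSE]
    with_st <- sub$st[!na_or_empty(sub$st)]
    sts <- sort_ids(unique(with_st))
    data.frame(species = sp, n_members = nrow(sub),
               n_members_with_st = length(with_st),
               n_sts = length(sts),
               sts = paste(sts, collapse = ","),
               unassigned = length(sts) == 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Allelic distance between two MLST profiles
#'
#' Number of the 7 housekeeping loci at which two sequence-type profiles
#' carry different alleles. Loci with a missing allele in either profile are
#' excluded and reported via the `loci_compared` attribute.
#'
#' @param a,b Integer vectors of 7 alleles (NA = missing).
#' @return Integer distance in 0..7 with attribute `loci_compared`.
#' @export
st_allelic_distance <- function(a, b) {
  if (length(a) != 7L || length(b) != 7L) {
    stop("allelic profiles must have exactly 7 loci", call. = FALSE)
  }
  ok <- !is.na(a) & !is.na(b)
  d <- sum(a[ok] != b[ok])
  structure(as.integer(d), loci_compared = sum(ok))
}

#' Mean pairwise allelic distance among a species' sequence types
#'
#' Average [st_allelic_distance()] over all unordered pairs of distinct STs
#' in which a species occurs; `NA` if fewer than two STs.
#'
#' @param sts Character vector of distinct ST ids.
#' @param profiles Data.frame with columns `st`, `allele_1`..`allele_7`.
#' @return Numeric mean distance (NA when < 2 STs).
#' @export
mean_allelic_distance <- function(sts, profiles) {
  sts <- unique(sts[!na_or_empty(sts)])
  if (length(sts) < 2L) return(NA_real_)
  missing <- setdiff(sts, profiles$st)
  if (length(missing)) {
    stop("no allelic profile for ST(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  allele_cols <- paste0("allele_", 1:7)
  prof <- as.matrix(profiles[match(sts, profiles$st), allele_cols])
  pairs <- utils::combn(length(sts), 2L)
  mean(apply(pairs, 2L, function(p)
    st_allelic_distance(prof[p[1], ], prof[p[2], ])))
}

#' Geographic dispersion of each species
#'
#' Countries in which each species occurs; members without a country are
#' excluded from the set but counted in `n_members_no_country`.
#'
#' @inheritParams host_range
#' @return A data.frame: species, n_members, n_members_no_country,
#'   n_countries, countries (comma-separated).
#' @export
geo_dispersion <- function(partition, records, meta) {
  j <- join_genomes(partition, records, meta)
  out <- do.call(rbind, lapply(names(partition$species), function(sp) {
    sub <- j[j$species == sp, , drop = FALSE]
    with_country <- sub$country[!na_or_empty(sub$country)]
    countries <- sort_ids(unique(with_country))
    data.frame(species = sp, n_members = nrow(sub),
               n_members_no_country = sum(na_or_empty(sub$country)),
               n_countries = length(countries),
               countries = paste(countries, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tukey fences for outlier detection
#'
#' Quartiles by Tukey hinges (the median-of-halves convention of
#' `stats::fivenum()`); fences at `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`; values
#' outside the fences are outliers.
#'
#' @param values Numeric vector (>= 1 value, NAs dropped).
#' @return A list: q1, q3, iqr, lower, upper, outliers.
#' @export
tukey_fences <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    stop("values must contain at least one non-missing number", call. = FALSE)
  }
  fn <- stats::fivenum(values)
  q1 <- fn[2]; q3 <- fn[4]
  iqr <- q3 - q1
  lower <- q1 - 1.5 * iqr
  upper <- q3 + 1.5 * iqr
  list(q1 = q1, q3 = q3, iqr = iqr, lower = lower, upper = upper,
       outliers = values[values < lower | values > upper])
}

#' Species with members from two or more host categories
#'
#' Detects "hybrid" species whose prophages come from bacterial isolates of
#' different host categories (human / animal / plant), with a per-category
#' member breakdown.
#'
#' @inheritParams host_range
#' @return A data.frame: species, n_categories, and one count column per
#'   host category; zero rows when no species crosses categories.
#' @export
hybrid_host_species <- function(partition, records, meta) {
  j <- join_genomes(partition, records, meta)
  cats <- c("human", "animal", "plant")
  rows <- lapply(names(partition$species), function(sp) {
    sub <- j[j$species == sp & !na_or_empty(j$host), , drop = FALSE]
    counts <- vapply(cats, function(h) sum(sub$host == h), integer(1))
    if (sum(counts > 0) < 2L) return(NULL)
    cbind(data.frame(species = sp, n_categories = sum(counts > 0),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- data.frame(species = character(0), n_categories = integer(0))
    for (h in cats) out[[h]] <- integer(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binary species-by-ST incidence matrix
#'
#' @inheritParams host_range
#' @return A 0/1 matrix, species in rows, sequence types in columns.
#' @export
species_st_incidence <- function(partition, records, meta) {
  hr <- join_genomes(partition, records, meta)
  hr <- hr[!na_or_empty(hr$st), , drop = FALSE]
  sts <- sort_ids(unique(hr$st))
  species <- names(partition$species)
  m <- matrix(0L, length(species), length(sts),
              dimnames = list(species, sts))
  if (nrow(hr)) m[cbind(hr$species, hr$st)] <- 1L
  m
}

#' Per-species epidemiological summary
#'
#' Joins host range, mean allelic distance between the species' STs,
#' geographic dispersion and host-category breakdown into one table.
#'
#' @inheritParams host_range
#' @param profiles Optional ST profile data.frame (`st`, `allele_1..7`);
#'   when given, a `mean_allelic_distance` column is added.
#' @return A data.frame, one row per species.
#' @export
species_summary <- function(partition, records, meta, profiles = NULL) {
  hr <- host_range(partition, records, meta)
  gd <- geo_dispersion(partition, records, meta)
  out <- merge(hr, gd[, c("species", "n_countries", "countries")],
               by = "species", sort = FALSE)
  out$singleton <- unname(partition$singleton[out$species])
  if (!is.null(profiles)) {
    out$mean_allelic_distance <- vapply(out$sts, function(s) {
      if (s == "") return(NA_real_)
      mean_allelic_distance(strsplit(s, ",", fixed = TRUE)[[1]], profiles)
    }, numeric(1), USE.NAMES = FALSE)
  }
  j <- join_genomes(partition, records, meta)
  for (h in c("human", "animal", "plant")) {
    out[[paste0("n_", h)]] <- vapply(out$species, function(sp)
      sum(j$species == sp & !na_or_empty(j$host) & j$host == h), integer(1),
      USE.NAMES = FALSE)
  }
  out[match(names(partition$species), out$species), , drop = FALSE]
}
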