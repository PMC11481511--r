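# Species-level diversity: incidence matrix, exact site-based accumulation
# curve, singleton statistics, two-sample KS, and clustering comparison.

#' Genome-by-species incidence matrix
#'
#' Binary sites-by-species matrix: genomes are the sampling units (sites).
#'
#' @param partition A `species_partition`.
#' @param records Prediction data.frame (prophage_id, genome_id).
#' @return A 0/1 integer matrix, genomes in rows, species in columns.
#' @export
build_incidence <- function(partition, records) {
  membership <- partition_membership(partition)
  ids <- names(membership)
  genome <- records$genome_id[match(ids, records$prophage_id)]
  if (anyNA(genome)) {
    stop("prophage(s) without genome mapping: ",
         paste(ids[is.na(genome)], collapse = ", "), call. = FALSE)
  }
  genomes <- sort_ids(unique(genome))
  species <- names(partition$species)
  m <- matrix(0L, length(genomes), length(species),
              dimnames = list(genomes, species))
  m[cbind(genome, unname(membership))] <- 1L
  m
}

#' Exact site-based species accumulation curve
#'
#' Expected species richness after sampling n of the T sites without
#' replacement, by the exact hypergeometric formula
#' \deqn{E[S_n] = S - \sum_i \binom{T - T_i}{n} / \binom{T}{n},}
#' where \eqn{T_i} is the incidence (number of occupied sites) of species i.
#' Binomial coefficients are evaluated on the log scale, so large T is safe.
#' The standard deviation comes from the full analytic variance, including
#' the pairwise covariance of species absences (co-occurrence counts enter
#' through the probability that a site pair misses both species). The
#' confidence band is `expected +/- z * sd` with `z = qnorm(1 - (1 -
#' level)/2)`.
#'
#' @param inc Binary incidence matrix, sites in rows (see
#'   [build_incidence()]).
#' @param level Confidence level for the band (default 0.95).
#' @return An object of class `accum_curve`: a data.frame with columns `n`,
#'   `expected`, `sd`, `lower`, `upper`, plus attributes `S`, `T` and
#'   `method`.
#' @export
accumulation_exact <- function(inc, level = 0.95) {
  inc <- as.matrix(inc)
  if (any(!inc %in% c(0L, 1L))) {
    stop("incidence matrix must be binary", call. = FALSE)
  }
  Tn <- nrow(inc)
  if (Tn < 1L) stop("need at least one site", call. = FALSE)
  Ti <- colSums(inc)
  keep <- Ti >= 1L
  Ti <- Ti[keep]
  S <- length(Ti)
  both <- crossprod(inc[, keep, drop = FALSE])  # co-occurrence counts
  # neither[i, j] = T - T_i - T_j + B_ij = sites containing neither species
  neither <- Tn - outer(Ti, Ti, "+") + as.matrix(both)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ns <- seq_len(Tn)
  expected <- sd_vec <- numeric(Tn)
  lchoose_T <- lchoose(Tn, ns)
  for (n in ns) {
    qi <- exp(lchoose(Tn - Ti, n) - lchoose_T[n])       # P(species i absent)
    expected[n] <- S - sum(qi)
    qij <- exp(lchoose(neither, n) - lchoose_T[n])      # P(i and j absent)
    diag(qij) <- qi
    # Var(S_n) = sum_i qi(1-qi) + sum_{i != j} (qij - qi qj)
    v <- sum(qi * (1 - qi)) + sum(qij - outer(qi, qi)) -
      sum(diag(qij) - qi^2)
    sd_vec[n] <- sqrt(max(v, 0))
  }
  out <- data.frame(n = ns, expected = expected, sd = sd_vec,
                    lower = expected - z * sd_vec,
                    upper = expected + z * sd_vec)
  structure(out, S = S, T = Tn, method = "exact", level = level,
            class = c("accum_curve", "data.frame"))
}

#' Species accumulation curve
#'
#' `method = "exact"` (default) uses the exact site-based expectation of
#' [accumulation_exact()]. `method = "rarefaction"` is the individual-based
#' variant mapped back to sites, delegated to
#' `vegan::specaccum(method = "rarefaction")` (expected richness at `m = n x
#' mean individuals per site`).
#'
#' @param inc Incidence (or count) matrix, sites in rows.
#' @param method `"exact"` or `"rarefaction"`.
#' @param level Confidence level for the band.
#' @return An `accum_curve` object.
#' @export
accumulation_curve <- function(inc, method = c("exact", "rarefaction"),
                               level = 0.95) {
  method <- match.arg(method)
  if (method == "exact") return(accumulation_exact(inc, level = level))
  sac <- vegan::specaccum(as.data.frame(as.matrix(inc)),
                          method = "rarefaction")
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(n = sac$sites, expected = sac$richness, sd = sac$sd,
                    lower = sac$richness - z * sac$sd,
                    upper = sac$richness + z * sac$sd)
  structure(out, S = sum(colSums(as.matrix(inc)) > 0), T = nrow(inc),
            method = "rarefaction", level = level,
            class = c("accum_curve", "data.frame"))
}

#' @export
print.accum_curve <- function(x, ...) {
  cat(sprintf("Species accumulation curve (%s): %d sites, %d species\n",
              attr(x, "method"), attr(x, "T"), attr(x, "S")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' @export
plot.accum_curve <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::plot(df$n, df$expected, type = "n",
                 ylim = range(df$lower, df$upper),
                 xlab = "genomes sampled", ylab = "expected species", ...)
  graphics::polygon(c(df$n, rev(df$n)), c(df$lower, rev(df$upper)),
                    col = "grey85", border = NA)
  graphics::lines(df$n, df$expected, lwd = 2)
  invisible(x)
}

#' Singleton statistics of a partition
#'
#' @param partition A `species_partition`.
#' @return A list: n_species, n_singletons, singleton_fraction, and
#'   `size_histogram` (a table of cluster sizes).
#' @export
singleton_stats <- function(partition) {
  stopifnot(inherits(partition, "species_partition"))
  sizes <- unname(partition$sizes)
  if (length(sizes) == 0L) stop("empty partition", call. = FALSE)
  list(n_species = length(sizes),
       n_singletons = sum(sizes == 1L),
       singleton_fraction = mean(sizes == 1L),
       size_histogram = table(sizes))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of |F_x - F_y| over the pooled support; the p-value is
#' the asymptotic Kolmogorov distribution at effective sample size
#' `n_x n_y / (n_x + n_y)`.
#'
#' @param x,y Non-empty numeric samples.
#' @return A list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Compare a strict and a lenient clustering of the same sequences
#'
#' Computes the KS comparison of the two cluster-size distributions,
#' singleton statistics for each, and the refinement mapping: since the
#' lenient thresholds admit a superset of edges, every strict cluster should
#' sit inside exactly one lenient cluster.
#'
#' @param strict,lenient Two `species_partition` objects over the same ids.
#' @return A list: `ks` (D, p), `strict_stats`, `lenient_stats`, `mapping`
#'   (data.frame strict_species, lenient_species, contained), and
#'   `refinement` (TRUE iff every strict cluster is contained in one lenient
#'   cluster).
#' @export
compare_clusterings <- function(strict, lenient) {
  stopifnot(inherits(strict, "species_partition"),
            inherits(lenient, "species_partition"))
  ids_s <- sort_ids(unlist(strict$species, use.names = FALSE))
  ids_l <- sort_ids(unlist(lenient$species, use.names = FALSE))
  if (!identical(ids_s, ids_l)) {
    stop("the two partitions cover different id sets", call. = FALSE)
  }
  mem_l <- partition_membership(lenient)
  mapping <- do.call(rbind, lapply(names(strict$species), function(sp) {
    targets <- unique(unname(mem_l[strict$species[[sp]]]))
    data.frame(strict_species = sp,
               lenient_species = paste(sort_ids(targets), collapse = ","),
               contained = length(targets) == 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(mapping) <- NULL
  list(ks = ks_two_sample(unname(strict$sizes), unname(lenient$sizes)),
       strict_stats = singleton_stats(strict),
       lenient_stats = singleton_stats(lenient),
       mapping = mapping,
       refinement = all(mapping$contained))
}
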