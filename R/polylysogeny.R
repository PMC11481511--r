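# Polylysogeny: per-genome prophage counts, group tests, and intra-genome
# prophage divergence. ANI in this module is reported as a fraction (0-1),
# the scale on which intra-genome divergence is summarized; identity
# elsewhere is percent, and the conversion happens here, explicitly.

#' Prophage counts per bacterial genome
#'
#' Counts kept prophages per genome; genomes present in the metadata but
#' carrying no prophage are included with count 0.
#'
#' @param records Prediction data.frame (prophage_id, genome_id).
#' @param meta Optional genome metadata; when given, `host` and `st` are
#'   attached and zero-count genomes added.
#' @return A data.frame: genome_id, n_prophages, and (with metadata) host
#'   and st.
#' @export
counts_per_genome <- function(records, meta = NULL) {
  tab <- table(records$genome_id)
  out <- data.frame(genome_id = names(tab),
                    n_prophages = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    absent <- setdiff(meta$genome_id, out$genome_id)
    if (length(absent)) {
      out <- rbind(out, data.frame(genome_id = absent, n_prophages = 0L))
    }
    mrow <- match(out$genome_id, meta$genome_id)
    if ("host" %in% names(meta)) out$host <- as.character(meta$host[mrow])
    if ("st" %in% names(meta)) out$st <- as.character(meta$st[mrow])
  }
  out <- out[order(out$genome_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (`stats::kruskal.test()` under the hood). When every value is
#' identical across all groups, H = 0 and p = 1.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each non-empty), or
#'   a numeric vector when `g` is given.
#' @param g Optional grouping factor parallel to `groups`.
#' @return A list: `H`, `df`, `p`, and per-group `medians`.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  if (!is.list(groups) || length(groups) < 2L ||
      any(lengths(groups) == 0L)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    res <- list(H = 0, df = length(groups) - 1L, p = 1)
  } else {
    kt <- stats::kruskal.test(values, fac)
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value)
  }
  res$medians <- vapply(groups, stats::median, numeric(1))
  res
}

#' Pairwise ANI between prophages of the same genome
#'
#' For every genome carrying two or more prophages, all unordered pairs are
#' scored with the symmetrized identity (mean of the two directed values) as
#' a fraction in `[0, 1]`; unalignable pairs contribute 0. The global mean
#' and standard deviation are pooled over all pairs (not per-genome means).
#'
#' @param records Prediction data.frame (prophage_id, genome_id).
#' @param mat An `ani_matrix` containing every within-genome prophage.
#' @return An object of class `intra_genome_ani`: list with `pairs`
#'   (genome_id, prophage_a, prophage_b, ani), `per_genome` (genome_id,
#'   n_prophages, n_pairs, max_ani), `mean`, `sd`, `n_pairs`.
#' @export
intra_genome_ani <- function(records, mat) {
  stopifnot(inherits(mat, "ani_matrix"))
  missing <- setdiff(records$prophage_id, mat$ids)
  if (length(missing)) {
    stop("prophage(s) absent from the ANI matrix: ",
         paste(sort_ids(missing), collapse = ", "), call. = FALSE)
  }
  sym <- (mat$identity + t(mat$identity)) / 2 / 100
  by_genome <- split(records$prophage_id, records$genome_id)
  pair_rows <- list()
  pg_rows <- list()
  for (gid in names(by_genome)) {
    ids <- sort_ids(by_genome[[gid]])
    n <- length(ids)
    if (n < 2L) next
    cmb <- utils::combn(ids, 2L)
    ani <- sym[cbind(cmb[1, ], cmb[2, ])]
    pair_rows[[gid]] <- data.frame(genome_id = gid,
                                   prophage_a = cmb[1, ],
                                   prophage_b = cmb[2, ],
                                   ani = as.numeric(ani),
                                   stringsAsFactors = FALSE)
    pg_rows[[gid]] <- data.frame(genome_id = gid, n_prophages = n,
                                 n_pairs = ncol(cmb),
                                 max_ani = max(ani),
                                 stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else {
    data.frame(genome_id = character(0), prophage_a = character(0),
               prophage_b = character(0), ani = numeric(0))
  }
  per_genome <- if (length(pg_rows)) do.call(rbind, pg_rows) else {
    data.frame(genome_id = character(0), n_prophages = integer(0),
               n_pairs = integer(0), max_ani = numeric(0))
  }
  rownames(pairs) <- rownames(per_genome) <- NULL
  structure(list(pairs = pairs, per_genome = per_genome,
                 mean = if (nrow(pairs)) mean(pairs$ani) else NA_real_,
                 sd = if (nrow(pairs) > 1) stats::sd(pairs$ani) else NA_real_,
                 n_pairs = nrow(pairs)),
            class = "intra_genome_ani")
}

#' @export
print.intra_genome_ani <- function(x, ...) {
  cat(sprintf("Intra-genome prophage ANI: %d pairs in %d polylysogenic genomes\n",
              x$n_pairs, nrow(x$per_genome)))
  if (x$n_pairs > 0) {
    cat(sprintf("  pooled mean %.4f (sd %.4f); max per-genome ANI %.4f\n",
                x$mean, x$sd, max(x$per_genome$max_ani)))
  }
  invisible(x)
}
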