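# Independent oracles and small fixtures shared across tests.

rand_seq <- function(n, seed) {
  prophagr:::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                          replace = TRUE), collapse = ""))
}

# canonical form of a partition (list of member vectors) for set comparison
canon_partition <- function(p) {
  unname(sort(vapply(p, function(v) paste(sort(v), collapse = ","),
                     character(1))))
}

# brute-force maximum clique over all vertex subsets (<= ~15 vertices),
# tie broken by lexicographically smallest sorted name vector
brute_max_clique <- function(adj) {
  ids <- rownames(adj)
  n <- length(ids)
  best <- character(0)
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    k <- length(members)
    if (k < length(best)) next
    is_clique <- TRUE
    if (k > 1) {
      sub <- adj[members, members, drop = FALSE]
      is_clique <- all(sub[upper.tri(sub)])
    }
    if (!is_clique) next
    cand <- sort(ids[members])
    if (k > length(best)) {
      best <- cand
    } else if (k == length(best) && k > 0) {
      # lexicographic comparison of sorted id vectors
      for (j in seq_len(k)) {
        if (cand[j] < best[j]) { best <- cand; break }
        if (cand[j] > best[j]) break
      }
    }
  }
  best
}

# brute-force two-sample KS statistic: sup |F_x - F_y| over pooled support
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Kruskal-Wallis H recomputed from first principles with tie correction
brute_kw_H <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  r <- rank(values)
  ri <- split(r, rep(seq_along(groups), lengths(groups)))
  H <- 12 / (n * (n + 1)) *
    sum(vapply(ri, function(v) sum(v)^2 / length(v), numeric(1))) -
    3 * (n + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# random binary sites x species incidence matrix with no empty species
random_incidence <- function(nsites, nspecies, seed, p = 0.25) {
  prophagr:::with_seed(seed, {
    m <- matrix(rbinom(nsites * nspecies, 1, p), nsites, nspecies)
    keep <- colSums(m) > 0
    if (!all(keep)) m <- m[, keep, drop = FALSE]
    dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                        paste0("s", seq_len(ncol(m))))
    m
  })
}

# a small, fast community for module-level tests (ancestors 3-6 kb)
small_sim_config <- function(seed = 11L, ...) {
  sim_config(n_species = 8L, frac_singletons = 0.5,
             cosmopolitan_sizes = c(6L, 4L), cosmopolitan_st_spread = c(3L, 2L),
             other_size_range = c(2L, 3L),
             ancestor_length_range = c(3000L, 6000L),
             n_genomes = 30L, n_sts = 5L, n_countries = 4L,
             flank = 15000L, seed = seed, ...)
}

small_community <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$comm)) {
      cache$comm <- generate_community(small_sim_config())
      cache$mat <- compute_ani_matrix(cache$comm$sequences)
    }
    list(comm = cache$comm, mat = cache$mat)
  }
})
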