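#' Species-level clustering parameters
#'
#' Thresholds and settings for turning an ANI matrix into a species graph
#' and clustering it with the paraclique strategy. The operational species
#' definition is identity >= 95% and coverage >= 90% (a strict `>` variant
#' is available); a lenient 70/70 setting is used for robustness checks.
#'
#' Because the ANI matrices are asymmetric, the two directed values of a
#' pair are symmetrized before thresholding: `"mean-min"` (default) takes
#' the mean identity and the minimum coverage — conservative on coverage, so
#' a short sequence embedded in a longer one cannot chain species together —
#' `"mean-both"` takes both means, and `"either"` accepts the pair if either
#' direction passes both thresholds.
#'
#' @param min_identity Identity threshold in percent (default 95).
#' @param min_coverage Coverage threshold in percent (default 90).
#' @param glom Paraclique glom factor g in (0, 1]: a vertex joins a growing
#'   cluster C when adjacent to at least `ceiling(g * |C|)` members.
#' @param symmetrization One of `"mean-min"`, `"mean-both"`, `"either"`.
#' @param strict If `TRUE`, thresholds are strict (`>`); default non-strict
#'   (`>=`).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(min_identity = 95, min_coverage = 90, glom = 0.9,
                           symmetrization = c("mean-min", "mean-both",
                                              "either"),
                           strict = FALSE) {
  symmetrization <- match.arg(symmetrization)
  check_scalar_number(min_identity, "min_identity", 0, 100)
  check_scalar_number(min_coverage, "min_coverage", 0, 100)
  check_scalar_number(glom, "glom", 1e-9, 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 glom = glom, symmetrization = symmetrization,
                 strict = isTRUE(strict)),
            class = "cluster_params")
}

#' Build the species graph from an ANI matrix
#'
#' Vertices are sequence ids; an undirected edge joins two sequences iff
#' their symmetrized identity and coverage pass the thresholds in `params`.
#' No self-loops.
#'
#' @param mat An `ani_matrix`.
#' @param params A [cluster_params()] object.
#' @return An `igraph` undirected graph whose vertex names are the ids.
#' @export
build_graph <- function(mat, params = cluster_params()) {
  stopifnot(inherits(mat, "ani_matrix"))
  idm <- mat$identity
  cvm <- mat$coverage
  pass <- function(m, thr) if (params$strict) m > thr else m >= thr
  adj <- switch(params$symmetrization,
    "mean-min" = pass((idm + t(idm)) / 2, params$min_identity) &
                 pass(pmin(cvm, t(cvm)), params$min_coverage),
    "mean-both" = pass((idm + t(idm)) / 2, params$min_identity) &
                  pass((cvm + t(cvm)) / 2, params$min_coverage),
    "either" = {
      dir_ok <- pass(idm, params$min_identity) & pass(cvm, params$min_coverage)
      dir_ok | t(dir_ok)
    })
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  g
}

# lexicographically smallest sorted id vector among candidate cliques
smallest_clique <- function(cliques) {
  sorted <- lapply(cliques, sort_ids)
  best <- 1L
  for (i in seq_along(sorted)[-1]) {
    a <- sorted[[best]]; b <- sorted[[i]]
    k <- min(length(a), length(b))
    cmp <- 0L
    for (j in seq_len(k)) {
      if (a[j] != b[j]) { cmp <- if (b[j] < a[j]) 1L else -1L; break }
    }
    if (cmp == 1L || (cmp == 0L && length(b) < length(a))) best <- i
  }
  sorted[[best]]
}

#' Paraclique clustering of the species graph
#'
#' Iterates: (i) find a maximum clique (exact; ties broken by the
#' lexicographically smallest sorted id list); (ii) grow it by repeatedly
#' absorbing the unassigned vertex adjacent to at least `ceiling(g * |C|)`
#' current members (ties: smallest id) until none qualifies; (iii) emit the
#' cluster and remove its vertices — until no edges remain. Remaining
#' vertices become singleton clusters. Fully deterministic.
#'
#' @param graph An undirected `igraph` graph with named vertices.
#' @param glom Glom factor g in (0, 1].
#' @return An unnamed partition: list of character vectors of member ids,
#'   multi-member clusters in emission order, then singletons in id order.
#' @export
paraclique_partition <- function(graph, glom = 0.9) {
  check_scalar_number(glom, "glom", 1e-9, 1)
  ids <- igraph::V(graph)$name
  if (is.null(ids)) stop("graph vertices must be named", call. = FALSE)
  clusters <- list()
  g <- graph
  while (igraph::ecount(g) > 0) {
    maxcl <- igraph::largest_cliques(g)
    seed <- smallest_clique(lapply(maxcl, function(v)
      igraph::V(g)$name[as.integer(v)]))
    members <- seed
    unassigned <- setdiff(igraph::V(g)$name, members)
    adj <- igraph::as_adj_list(g)
    names(adj) <- igraph::V(g)$name
    nbr_names <- lapply(adj, function(v) igraph::V(g)$name[as.integer(v)])
    repeat {
      need <- ceiling(glom * length(members))
      deg_in <- vapply(unassigned, function(v)
        sum(nbr_names[[v]] %in% members), integer(1))
      ok <- unassigned[deg_in >= need]
      if (length(ok) == 0L) break
      pick <- sort_ids(ok)[1]
      members <- c(members, pick)
      unassigned <- setdiff(unassigned, pick)
    }
    clusters[[length(clusters) + 1L]] <- sort_ids(members)
    g <- igraph::delete_vertices(g, members)
  }
  leftover <- sort_ids(igraph::V(g)$name)
  clusters <- c(clusters, as.list(leftover))
  clusters
}

#' Name species clusters
#'
#' Orders clusters by size (descending), then by smallest member id, and
#' names them `<prefix>1..<prefix>n`. Renaming an already named partition is
#' idempotent.
#'
#' @param partition Unnamed partition (list of id vectors) or a
#'   `species_partition`.
#' @param prefix Name prefix (default `"Ab_PS"`).
#' @param params Optional [cluster_params()] recorded in the result.
#' @return An object of class `species_partition`: list with `species`
#'   (named list of member id vectors), `sizes`, `singleton` (logical),
#'   `prefix` and `params`.
#' @export
name_species <- function(partition, prefix = "Ab_PS", params = NULL) {
  if (inherits(partition, "species_partition")) {
    if (is.null(params)) params <- partition$params
    partition <- unname(partition$species)
  }
  sizes <- lengths(partition)
  first_id <- vapply(partition, function(m) sort_ids(m)[1], character(1))
  ord <- order(-sizes, first_id, method = "radix")
  species <- lapply(partition[ord], sort_ids)
  names(species) <- paste0(prefix, seq_along(species))
  structure(list(species = species,
                 sizes = lengths(species),
                 singleton = lengths(species) == 1L,
                 prefix = prefix,
                 params = params),
            class = "species_partition")
}

#' Delimit phage species from an ANI matrix
#'
#' Convenience wrapper: [build_graph()] + [paraclique_partition()] +
#' [name_species()].
#'
#' @param mat An `ani_matrix`.
#' @param params A [cluster_params()] object.
#' @param prefix Species name prefix.
#' @return A named `species_partition`.
#' @export
delimit_species <- function(mat, params = cluster_params(),
                            prefix = "Ab_PS") {
  graph <- build_graph(mat, params)
  name_species(paraclique_partition(graph, params$glom), prefix = prefix,
               params = params)
}

#' @export
print.species_partition <- function(x, ...) {
  n <- length(x$species)
  cat(sprintf("Species partition: %d species over %d sequences\n",
              n, sum(x$sizes)))
  cat(sprintf("  %d singletons (%.1f%%); largest species %s with %d members\n",
              sum(x$singleton), 100 * mean(x$singleton),
              names(x$species)[1], x$sizes[1]))
  invisible(x)
}

#' @export
summary.species_partition <- function(object, ...) {
  data.frame(species = names(object$species),
             size = unname(object$sizes),
             singleton = unname(object$singleton),
             members = vapply(object$species, paste, character(1),
                              collapse = ","),
             row.names = NULL)
}

#' Membership lookup for a partition
#'
#' @param partition A `species_partition`.
#' @return Named character vector mapping member id to species name.
#' @export
partition_membership <- function(partition) {
  stopifnot(inherits(partition, "species_partition"))
  members <- unlist(partition$species, use.names = FALSE)
  stats::setNames(rep(names(partition$species), partition$sizes), members)
}

#' Export the species network
#'
#' Writes the thresholded ANI graph with species (and, when metadata is
#' supplied, host / ST / country) node attributes as GraphML plus
#' tab-delimited edge and node tables, loadable by standard graph viewers.
#'
#' @param partition A `species_partition`.
#' @param graph The `igraph` graph the partition was computed on.
#' @param prefix Output path prefix (writes `<prefix>.graphml`,
#'   `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`).
#' @param records Optional prediction data.frame mapping prophage to genome.
#' @param meta Optional genome metadata data.frame (genome_id, st, host,
#'   country, ...).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(partition, graph, prefix, records = NULL,
                           meta = NULL) {
  stopifnot(inherits(partition, "species_partition"))
  membership <- partition_membership(partition)
  ids <- igraph::V(graph)$name
  igraph::V(graph)$species <- unname(membership[ids])
  if (!is.null(records) && !is.null(meta)) {
    genome <- records$genome_id[match(ids, records$prophage_id)]
    igraph::V(graph)$genome <- ifelse(is.na(genome), "", genome)
    mrow <- match(genome, meta$genome_id)
    for (col in intersect(c("st", "host", "country"), names(meta))) {
      val <- as.character(meta[[col]][mrow])
      igraph::vertex_attr(graph, col) <- ifelse(is.na(val), "", val)
    }
  }
  paths <- c(graphml = paste0(prefix, ".graphml"),
             edges = paste0(prefix, "_edges.tsv"),
             nodes = paste0(prefix, "_nodes.tsv"))
  igraph::write_graph(graph, paths[["graphml"]], format = "graphml")
  el <- igraph::as_edgelist(graph)
  utils::write.table(
    data.frame(source = el[, 1], target = el[, 2]),
    paths[["edges"]], sep = "\t", quote = FALSE, row.names = FALSE)
  node_df <- data.frame(id = ids, species = unname(membership[ids]))
  for (col in setdiff(igraph::vertex_attr_names(graph),
                      c("name", "species"))) {
    node_df[[col]] <- igraph::vertex_attr(graph, col)
  }
  utils::write.table(node_df, paths[["nodes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Check superinfection exclusion
#'
#' Superinfection exclusion predicts that no bacterial genome carries two
#' prophages of the same species. Lists every (genome, species) pair with
#' two or more members; an empty result is a pass.
#'
#' @param partition A `species_partition`.
#' @param records Prediction data.frame mapping `prophage_id` to
#'   `genome_id`.
#' @return A data.frame with columns genome_id, species, n_members,
#'   prophage_ids; zero rows when the check passes.
#' @export
check_superinfection_exclusion <- function(partition, records) {
  stopifnot(inherits(partition, "species_partition"))
  membership <- partition_membership(partition)
  ids <- names(membership)
  genome <- records$genome_id[match(ids, records$prophage_id)]
  if (anyNA(genome)) {
    stop("prophage(s) without genome mapping: ",
         paste(ids[is.na(genome)], collapse = ", "), call. = FALSE)
  }
  key <- paste(genome, membership, sep = "\r")
  dup_keys <- names(which(table(key) >= 2))
  if (length(dup_keys) == 0L) {
    return(data.frame(genome_id = character(0), species = character(0),
                      n_members = integer(0), prophage_ids = character(0)))
  }
  out <- do.call(rbind, lapply(dup_keys, function(kk) {
    sel <- key == kk
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    data.frame(genome_id = parts[1], species = parts[2],
               n_members = sum(sel),
               prophage_ids = paste(sort_ids(ids[sel]), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
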