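make_ani <- function(ids, id_pairs = list(), cov_pairs = list(),
                     default_id = 0, default_cov = 0) {
  n <- length(ids)
  idm <- matrix(default_id, n, n, dimnames = list(ids, ids))
  cvm <- matrix(default_cov, n, n, dimnames = list(ids, ids))
  diag(idm) <- diag(cvm) <- 100
  for (p in id_pairs) idm[p[[1]], p[[2]]] <- p[[3]]
  for (p in cov_pairs) cvm[p[[1]], p[[2]]] <- p[[3]]
  ani_matrix(idm, cvm)
}

graph_from_edges <- function(ids, edges) {
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (length(edges)) g <- igraph::add_edges(g, unlist(edges))
  g
}

test_that("graph construction applies thresholds and symmetrization", {
  ids <- c("a", "b", "c")
  # all off-diagonal identity 0 -> edgeless
  g0 <- build_graph(make_ani(ids), cluster_params())
  expect_equal(igraph::ecount(g0), 0)

  # all pairwise 99 identity / 95 coverage -> triangle
  m <- make_ani(ids, default_id = 99, default_cov = 95)
  g1 <- build_graph(m, cluster_params())
  expect_equal(igraph::ecount(g1), 3)

  # asymmetric pair: identity 96/94 (mean 95 passes), coverage 91/85
  m2 <- make_ani(c("a", "b"),
                 id_pairs = list(list("a", "b", 96), list("b", "a", 94)),
                 cov_pairs = list(list("a", "b", 91), list("b", "a", 85)))
  expect_equal(igraph::ecount(build_graph(m2, cluster_params())), 0)  # min cov 85 < 90
  expect_equal(igraph::ecount(
    build_graph(m2, cluster_params(symmetrization = "either"))), 1)   # a->b passes

  # strict flag: exactly-at-threshold pair only passes the non-strict rule
  m3 <- make_ani(c("a", "b"),
                 id_pairs = list(list("a", "b", 95), list("b", "a", 95)),
                 cov_pairs = list(list("a", "b", 90), list("b", "a", 90)))
  expect_equal(igraph::ecount(build_graph(m3, cluster_params())), 1)
  expect_equal(igraph::ecount(build_graph(m3, cluster_params(strict = TRUE))), 0)
})

test_that("paraclique handles edgeless and complete graphs", {
  g <- graph_from_edges(letters[1:5], list())
  p <- paraclique_partition(g, 0.9)
  expect_length(p, 5L)
  expect_true(all(lengths(p) == 1L))

  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- letters[1:6]
  p6 <- paraclique_partition(k6, 0.5)
  expect_length(p6, 1L)
  expect_setequal(p6[[1]], letters[1:6])
})

test_that("glom factor controls absorption into the seed clique", {
  # K5 on a..e plus v adjacent to 4 of the 5
  ids <- c(letters[1:5], "v")
  edges <- c(combn(letters[1:5], 2, simplify = FALSE),
             lapply(letters[1:4], function(x) c(x, "v")))
  g <- graph_from_edges(ids, edges)
  # g = 0.9: ceiling(0.9 * 5) = 5 > 4 -> v not absorbed
  p9 <- paraclique_partition(g, 0.9)
  expect_equal(canon_partition(p9), canon_partition(list(letters[1:5], "v")))
  # g = 0.8: ceiling(0.8 * 5) = 4 -> v absorbed
  p8 <- paraclique_partition(g, 0.8)
  expect_equal(canon_partition(p8), canon_partition(list(ids)))
})

test_that("maximum-clique seed matches brute force on random graphs", {
  prophagr:::with_seed(202, {
    for (rep in 1:40) {
      n <- sample(4:10, 1)
      ids <- sprintf("v%02d", seq_len(n))
      adj <- matrix(runif(n * n) < 0.45, n, n, dimnames = list(ids, ids))
      adj <- adj | t(adj); diag(adj) <- FALSE
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      if (igraph::ecount(g) == 0) next
      first <- paraclique_partition(g, 1.0)[[1]]
      expect_identical(first, brute_max_clique(adj))
    }
  })
})

test_that("partitions are disjoint covers and deterministic", {
  fit <- small_community()
  g <- build_graph(fit$mat, cluster_params())
  p1 <- paraclique_partition(g, 0.9)
  p2 <- paraclique_partition(g, 0.9)
  expect_identical(p1, p2)
  all_ids <- unlist(p1)
  expect_false(anyDuplicated(all_ids) > 0)
  expect_setequal(all_ids, fit$mat$ids)
})

test_that("species naming orders by size then smallest id and is idempotent", {
  p <- list(c("x9", "x2"), c("a1", "a2", "a3"), "z5", c("b1", "b0"))
  named <- name_species(p)
  expect_equal(names(named$species), paste0("Ab_PS", 1:4))
  expect_equal(unname(named$sizes), c(3L, 2L, 2L, 1L))
  expect_equal(named$species[["Ab_PS1"]], c("a1", "a2", "a3"))
  # size-2 tie: cluster containing "b0" precedes the one containing "x2"
  expect_equal(named$species[["Ab_PS2"]], c("b0", "b1"))
  expect_true(named$singleton[["Ab_PS4"]])
  renamed <- name_species(named)
  expect_identical(renamed$species, named$species)
  custom <- name_species(p, prefix = "PS")
  expect_equal(names(custom$species)[1], "PS1")
})

test_that("network export round-trips nodes and degrees", {
  fit <- small_community()
  g <- build_graph(fit$mat, cluster_params())
  part <- name_species(paraclique_partition(g, 0.9))
  prefix <- file.path(tempdir(), "net")
  paths <- export_network(part, g, prefix, records = fit$comm$predictions,
                          meta = fit$comm$metadata)
  expect_true(all(file.exists(paths)))
  back <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(back), length(fit$mat$ids))
  expect_equal(sort(unname(igraph::degree(back))),
               sort(unname(igraph::degree(g))))
  nodes <- read.delim(paths[["nodes"]])
  expect_setequal(nodes$id, fit$mat$ids)
  expect_true(all(c("species", "st", "host", "country") %in% names(nodes)))
})

test_that("superinfection exclusion check flags co-resident same-species pairs", {
  part <- name_species(list(c("p1", "p2"), "p3"))
  rec_ok <- data.frame(prophage_id = c("p1", "p2", "p3"),
                       genome_id = c("g1", "g2", "g1"))
  expect_equal(nrow(check_superinfection_exclusion(part, rec_ok)), 0L)
  rec_bad <- data.frame(prophage_id = c("p1", "p2", "p3"),
                        genome_id = c("g1", "g1", "g1"))
  v <- check_superinfection_exclusion(part, rec_bad)
  expect_equal(nrow(v), 1L)
  expect_equal(v$genome_id, "g1")
  expect_equal(v$n_members, 2L)
  expect_error(
    check_superinfection_exclusion(part, rec_ok[1:2, ]), "p3")
})
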