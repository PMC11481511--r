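test_that("incidence matrix is binary and consistent with the partition", {
  fit <- small_community()
  part <- delimit_species(fit$mat)
  inc <- build_incidence(part, fit$comm$predictions)
  expect_true(all(inc %in% 0:1))
  expect_equal(colnames(inc), names(part$species))
  # every species occupies at least one genome
  expect_true(all(colSums(inc) >= 1))
  # genomes with prophages from k species have row sum k
  expect_equal(sum(inc), nrow(unique(data.frame(
    g = fit$comm$predictions$genome_id,
    s = partition_membership(part)[fit$comm$predictions$prophage_id]))))
})

test_that("accumulation curve endpoints obey the analytic identities", {
  inc <- random_incidence(20, 25, seed = 301)
  curve <- accumulation_exact(inc)
  S <- ncol(inc)
  expect_equal(curve$expected[nrow(curve)], S, tolerance = 1e-9)
  expect_equal(curve$expected[1], mean(rowSums(inc)), tolerance = 1e-9)
  expect_equal(curve$sd[nrow(curve)], 0, tolerance = 1e-9)
})

test_that("accumulation curve is monotone and concave", {
  inc <- random_incidence(25, 40, seed = 302, p = 0.15)
  curve <- accumulation_exact(inc)
  gains <- diff(curve$expected)
  expect_true(all(gains > -1e-12))
  expect_true(all(diff(gains) < 1e-9))
})

test_that("one ubiquitous species gives a constant curve of 1", {
  inc <- matrix(1L, 10, 1, dimnames = list(paste0("g", 1:10), "s1"))
  curve <- accumulation_exact(inc)
  expect_equal(curve$expected, rep(1, 10), tolerance = 1e-12)
  expect_equal(curve$sd, rep(0, 10), tolerance = 1e-12)
})

test_that("exact expectation agrees with vegan's site-based formula", {
  inc <- random_incidence(15, 30, seed = 303)
  curve <- accumulation_exact(inc)
  ref <- vegan::specaccum(as.data.frame(inc), method = "exact")
  expect_equal(curve$expected, unname(ref$richness), tolerance = 1e-8)
})

test_that("rarefaction mode reproduces the individual-based curve", {
  inc <- random_incidence(12, 20, seed = 304)
  curve <- accumulation_curve(inc, method = "rarefaction")
  ref <- vegan::specaccum(as.data.frame(inc), method = "rarefaction")
  expect_equal(curve$expected, unname(ref$richness), tolerance = 1e-8)
  expect_equal(curve$expected[nrow(curve)], ncol(inc), tolerance = 1e-9)
})

test_that("rejects out-of-range and non-binary input", {
  expect_error(accumulation_exact(matrix(2L, 3, 2)), "binary")
  expect_error(accumulation_exact(matrix(integer(0), 0, 0)), "site")
})

test_that("singleton statistics summarize the size distribution", {
  all_single <- name_species(as.list(paste0("p", 1:4)))
  expect_equal(singleton_stats(all_single)$singleton_fraction, 1)
  one_big <- name_species(list(paste0("p", 1:5)))
  expect_equal(singleton_stats(one_big)$singleton_fraction, 0)
  mix <- name_species(list("a", "b", "c", c("d", "e"),
                           c("f", "g", "h", "i", "j")))
  st <- singleton_stats(mix)
  expect_equal(st$singleton_fraction, 0.6)
  expect_equal(st$n_species, 5L)
  expect_equal(as.integer(st$size_histogram[c("1", "2", "5")]), c(3L, 1L, 1L))
})

test_that("KS statistic equals the brute-force sup over the pooled support", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:3, 11:13)$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 4))$D, 1 / 3,
               tolerance = 1e-12)
  prophagr:::with_seed(305, {
    for (i in 1:20) {
      x <- sample(1:6, sample(2:4, 1), replace = TRUE)
      y <- sample(1:6, sample(2:4, 1), replace = TRUE)
      expect_equal(ks_two_sample(x, y)$D, brute_ks_D(x, y),
                   tolerance = 1e-12)
    }
  })
  # D is invariant under a monotone transform of both samples
  x <- c(1, 3, 4, 7); y <- c(2, 3, 5)
  expect_equal(ks_two_sample(x, y)$D, ks_two_sample(exp(x), exp(y))$D)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("clustering comparison reports KS, singletons and refinement", {
  strict <- name_species(list(c("a", "b"), "c", "d"))
  lenient <- name_species(list(c("a", "b", "c"), "d"))
  cmp <- compare_clusterings(strict, lenient)
  expect_true(cmp$refinement)
  expect_equal(cmp$strict_stats$n_species, 3L)
  expect_equal(cmp$lenient_stats$n_species, 2L)

  identical_cmp <- compare_clusterings(strict, strict)
  expect_equal(identical_cmp$ks$D, 0)
  expect_true(identical_cmp$refinement)

  # all singletons vs one cluster: refinement holds
  s2 <- name_species(as.list(letters[1:4]))
  l2 <- name_species(list(letters[1:4]))
  expect_true(compare_clusterings(s2, l2)$refinement)

  # a strict cluster split across lenient clusters is not a refinement
  not_ref <- compare_clusterings(name_species(list(c("a", "c"), c("b", "d"))),
                                 name_species(list(c("a", "b"), c("c", "d"))))
  expect_false(not_ref$refinement)

  other_ids <- name_species(as.list(c("a", "b", "c", "e")))
  expect_error(compare_clusterings(strict, other_ids), "different id sets")
})
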