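test_that("fragmentation follows the 1,020 bp window and 100 bp tail rule", {
  expect_equal(nrow(fragment_sequence(rand_seq(2040, 1))), 2L)
  fr <- fragment_sequence(rand_seq(2100, 1))   # 60 bp tail dropped
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$length, c(1020L, 1020L))
  fr2 <- fragment_sequence(rand_seq(2140, 1))  # 100 bp tail kept
  expect_equal(nrow(fr2), 3L)
  expect_equal(fr2$length[3], 100L)
  expect_equal(nrow(fragment_sequence(rand_seq(50, 1))), 0L)
  expect_error(fragment_sequence(""), "non-empty")
})

test_that("a 50 bp sequence yields no fragments and a no-alignment ANI", {
  res <- compute_pairwise_ani(rand_seq(50, 2), rand_seq(5000, 3))
  expect_equal(res$n_fragments, 0L)
  expect_equal(res$identity, 0)
  expect_equal(res$coverage, 0)
})

test_that("local aligner matches Biostrings optimal scores", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  prophagr:::with_seed(101, {
    for (i in 1:15) {
      q <- paste(sample(c("A", "C", "G", "T"), sample(60:300, 1), TRUE),
                 collapse = "")
      s <- paste(sample(c("A", "C", "G", "T"), sample(80:500, 1), TRUE),
                 collapse = "")
      if (i %% 2 == 0) {
        # plant a diverged copy of the query inside the subject
        s <- paste0(substr(s, 1, 40),
                    mutate_sequence(q, 0.08, 0.005, seed = i),
                    substr(s, 41, nchar(s)))
      }
      ref <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 1)
      expect_equal(sw_align(q, s)$score, Biostrings::score(ref))
    }
  })
})

test_that("self-comparison gives identity exactly 100", {
  s <- rand_seq(2040, 7)   # multiple of the fragment size
  res <- compute_pairwise_ani(s, s)
  expect_identical(res$identity, 100)
  expect_identical(res$coverage, 100)
  # non-multiple length: tail rule may shave < 1% coverage
  s2 <- rand_seq(30050, 8)
  res2 <- compute_pairwise_ani(s2, s2)
  expect_identical(res2$identity, 100)
  expect_gte(res2$coverage, 99)
})

test_that("substitutions confined to one fragment give the expected weighted identity", {
  q <- rand_seq(2040, 13)
  chars <- strsplit(q, "")[[1]]
  pos <- prophagr:::with_seed(14, sample(30:990, 51))  # keep fragment ends intact
  bases <- c("A", "C", "G", "T")
  subject <- chars
  for (p in pos) subject[p] <- bases[bases != chars[p]][1]
  res <- compute_pairwise_ani(paste(subject, collapse = ""), q)
  expect_equal(sort(res$fragments$identity),
               sort(c(100 * (1020 - 51) / 1020, 100)), tolerance = 1e-12)
  expect_equal(res$identity, 100 * (2040 - 51) / 2040, tolerance = 1e-12)
  expect_equal(res$coverage, 100)
})

test_that("seeded backend equals the exhaustive DP reference on small pairs", {
  p_seed <- ani_params(method = "seeded")
  p_exact <- ani_params(method = "exact")
  for (k in 1:3) {
    anc <- generate_ancestors(1, c(3000, 5000), seed = 40 + k)
    mut <- mutate_sequence(anc, c(0.01, 0.03, 0.05)[k], 5e-4, seed = 50 + k)
    a <- compute_pairwise_ani(anc, mut, p_seed)
    b <- compute_pairwise_ani(anc, mut, p_exact)
    expect_equal(a$fragments$identity, b$fragments$identity)
    expect_equal(a$identity, b$identity)
    expect_equal(a$coverage, b$coverage)
  }
})

test_that("ANI is nearly symmetric within species and decreases with divergence", {
  anc <- generate_ancestors(1, c(5000, 5000), seed = 61)
  mut <- mutate_sequence(anc, 0.01, 5e-4, seed = 62)
  ab <- compute_pairwise_ani(anc, mut)
  ba <- compute_pairwise_ani(mut, anc)
  expect_lt(abs(ab$identity - ba$identity), 2)

  ids <- vapply(c(0.005, 0.02, 0.06), function(r) {
    compute_pairwise_ani(anc, mutate_sequence(anc, r, 0, seed = 63))$identity
  }, numeric(1))
  expect_true(all(diff(ids) < 0))
})

test_that("ANI matrix shape, diagonal, and round-trip io", {
  seqs <- c(a = rand_seq(2040, 71),
            b = rand_seq(2500, 72),
            c = rand_seq(3000, 73))
  seqs["b"] <- paste0(substr(seqs["a"], 1, 1500), rand_seq(1000, 74))
  mat <- compute_ani_matrix(seqs)
  expect_equal(dim(mat$identity), c(3L, 3L))
  expect_equal(unname(diag(mat$identity)), rep(100, 3))
  expect_true(all(mat$identity >= 0 & mat$identity <= 100))
  expect_true(all(mat$coverage >= 0 & mat$coverage <= 100))

  prefix <- tempfile()
  write_ani_matrix(mat, prefix)
  back <- read_ani_matrix(prefix)
  expect_equal(back$identity, mat$identity, tolerance = 1e-9)
  expect_equal(back$coverage, mat$coverage, tolerance = 1e-9)

  one <- compute_ani_matrix(seqs[1])
  expect_equal(dim(one$identity), c(1L, 1L))
  expect_equal(one$identity[1, 1], 100)

  expect_error(compute_ani_matrix(setNames(seqs, c("a", "a", "c"))),
               "duplicate")
})

test_that("fraction-dialect matrices are rescaled to percent on import", {
  m <- matrix(c(1, 0.97, 0.96, 1), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  cv <- matrix(c(1, 0.95, 0.92, 1), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  idf <- tempfile(); cvf <- tempfile()
  write.table(data.frame(id = rownames(m), m, check.names = FALSE), idf,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = rownames(cv), cv, check.names = FALSE), cvf,
              sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_ani_matrix(identity_file = idf, coverage_file = cvf)
  expect_equal(back$identity["x", "y"], 96)
  expect_equal(back$coverage["y", "x"], 95)
})
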