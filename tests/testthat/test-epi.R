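toy_epi <- function() {
  part <- name_species(list(c("p1", "p2", "p3"), c("p4", "p5"), "p6"))
  rec <- data.frame(prophage_id = paste0("p", 1:6),
                    genome_id = paste0("g", 1:6))
  meta <- data.frame(
    genome_id = paste0("g", 1:6),
    st = c("ST2", "ST2", "ST2", "ST1", "ST10", NA),
    country = c("MX", "MX", "US", "FR", NA, "MX"),
    host = c("human", "human", "animal", "human", "plant", "human"),
    stringsAsFactors = FALSE)
  list(part = part, rec = rec, meta = meta)
}

test_that("host range counts STs and flags unassigned species", {
  t <- toy_epi()
  hr <- host_range(t$part, t$rec, t$meta)
  expect_equal(hr$n_sts[hr$species == "Ab_PS1"], 1L)       # all ST2
  expect_equal(hr$n_sts[hr$species == "Ab_PS2"], 2L)       # ST1, ST10
  expect_true(hr$unassigned[hr$species == "Ab_PS3"])       # no ST
  expect_equal(hr$n_members_with_st[hr$species == "Ab_PS3"], 0L)
  expect_true(all(hr$n_sts <= hr$n_members_with_st | hr$unassigned))
  bad_meta <- t$meta[1:3, ]
  expect_error(host_range(t$part, t$rec, bad_meta), "g4")
})

test_that("allelic distance counts differing loci and is a metric", {
  expect_equal(as.integer(st_allelic_distance(rep(1L, 7), rep(1L, 7))), 0L)
  expect_equal(as.integer(st_allelic_distance(1:7, 8:14)), 7L)
  expect_equal(as.integer(st_allelic_distance(c(1, 1, 1, 1, 1, 1, 1),
                                              c(1, 2, 1, 3, 1, 1, 4))), 3L)
  d <- st_allelic_distance(c(1, NA, 3, 4, 5, 6, 7), c(1, 2, 3, 9, 5, 6, 7))
  expect_equal(as.integer(d), 1L)
  expect_equal(attr(d, "loci_compared"), 6L)
  expect_error(st_allelic_distance(1:6, 1:7), "7 loci")

  prophagr:::with_seed(77, {
    for (i in 1:20) {
      a <- sample(1:4, 7, TRUE); b <- sample(1:4, 7, TRUE)
      cc <- sample(1:4, 7, TRUE)
      dab <- as.integer(st_allelic_distance(a, b))
      expect_equal(dab, as.integer(st_allelic_distance(b, a)))
      expect_lte(dab, as.integer(st_allelic_distance(a, cc)) +
                   as.integer(st_allelic_distance(cc, b)))
    }
  })
})

test_that("mean allelic distance averages over distinct ST pairs", {
  profiles <- data.frame(st = c("ST1", "ST2", "ST3"),
                         rbind(rep(1, 7),
                               c(1, 2, 1, 3, 1, 1, 4),
                               c(2, 2, 1, 3, 1, 1, 4)))
  names(profiles) <- c("st", paste0("allele_", 1:7))
  # pairwise: d(1,2)=3, d(1,3)=4, d(2,3)=1 -> mean 8/3
  expect_equal(mean_allelic_distance(c("ST1", "ST2", "ST3"), profiles), 8 / 3)
  expect_true(is.na(mean_allelic_distance("ST1", profiles)))
  expect_error(mean_allelic_distance(c("ST1", "ST9"), profiles), "ST9")
})

test_that("geographic dispersion counts countries and notes missing ones", {
  t <- toy_epi()
  gd <- geo_dispersion(t$part, t$rec, t$meta)
  expect_equal(gd$n_countries[gd$species == "Ab_PS1"], 2L)  # MX, US
  expect_equal(gd$countries[gd$species == "Ab_PS1"], "MX,US")
  expect_equal(gd$n_countries[gd$species == "Ab_PS2"], 1L)  # FR (one NA)
  expect_equal(gd$n_members_no_country[gd$species == "Ab_PS2"], 1L)
})

test_that("Tukey fences use hinge quartiles", {
  f <- tukey_fences(c(1, 1, 1, 1))
  expect_equal(f$iqr, 0)
  expect_equal(f$upper, 1)
  expect_length(f$outliers, 0L)

  f2 <- tukey_fences(c(1, 1, 1, 2, 2, 3, 20))
  expect_equal(f2$q1, 1)
  expect_equal(f2$q3, 2.5)
  expect_equal(f2$upper, 4.75)
  expect_equal(f2$outliers, 20)

  f3 <- tukey_fences(5)
  expect_equal(f3$q1, 5)
  expect_equal(f3$q3, 5)
  expect_length(f3$outliers, 0L)
  expect_error(tukey_fences(NA_real_), "at least one")
})

test_that("hybrid host species require two or more categories", {
  t <- toy_epi()
  hy <- hybrid_host_species(t$part, t$rec, t$meta)
  # Ab_PS1: 2 human + 1 animal; Ab_PS2: 1 human + 1 plant
  expect_equal(hy$species, c("Ab_PS1", "Ab_PS2"))
  expect_equal(hy$human, c(2L, 1L))
  expect_equal(hy$animal, c(1L, 0L))
  expect_equal(hy$plant, c(0L, 1L))
  expect_equal(hy$n_categories, c(2L, 2L))

  # a 118-human + 1-plant species is reported with its breakdown
  big_part <- name_species(list(paste0("q", 1:119)))
  big_rec <- data.frame(prophage_id = paste0("q", 1:119),
                        genome_id = paste0("h", 1:119))
  big_meta <- data.frame(genome_id = paste0("h", 1:119),
                         host = c(rep("human", 118), "plant"))
  hy2 <- hybrid_host_species(big_part, big_rec, big_meta)
  expect_equal(hy2$human, 118L)
  expect_equal(hy2$plant, 1L)

  all_human <- hybrid_host_species(
    big_part, big_rec,
    within(big_meta, host <- "human"))
  expect_equal(nrow(all_human), 0L)
})

test_that("synthetic narrow species sit in one ST, cosmopolitans span their quota", {
  fit <- small_community()
  comm <- fit$comm
  truth_part <- name_species(split(comm$truth$prophages$prophage_id,
                                   comm$truth$prophages$true_species_id))
  hr <- host_range(truth_part, comm$predictions, comm$metadata)
  sizes <- unname(truth_part$sizes[hr$species])
  cfg <- comm$config
  expect_setequal(sort(hr$n_sts[sizes %in% cfg$cosmopolitan_sizes]),
                  sort(cfg$cosmopolitan_st_spread))
  expect_true(all(hr$n_sts[!sizes %in% cfg$cosmopolitan_sizes] == 1L))
})

test_that("species summary joins range, geography, hosts and allelic distances", {
  fit <- small_community()
  comm <- fit$comm
  part <- delimit_species(fit$mat)
  ss <- species_summary(part, comm$predictions, comm$metadata,
                        profiles = comm$st_profiles)
  expect_equal(ss$species, names(part$species))
  expect_equal(sum(ss$n_members), length(comm$sequences))
  expect_true(all(ss$n_sts <= ss$n_members_with_st))
  multi <- ss[ss$n_sts >= 2, ]
  expect_true(all(!is.na(multi$mean_allelic_distance)))
  inc <- species_st_incidence(part, comm$predictions, comm$metadata)
  expect_equal(rownames(inc), names(part$species))
  expect_equal(unname(rowSums(inc)), ss$n_sts)
})
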