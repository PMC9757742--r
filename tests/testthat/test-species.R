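test_that("body-size matching uses the relative difference rule", {
  expect_true(body_sizes_match(50, 50, 0.01))
  expect_true(body_sizes_match(100, 99.5, 0.01))   # 0.005 < 0.01
  expect_false(body_sizes_match(100, 90, 0.01))    # 0.1
  expect_false(body_sizes_match(100, 99, 0.01))    # exactly at threshold
  expect_error(body_sizes_match(-1, 5, 0.01), "positive")
})

test_that("trophic assignment escalates the threshold until a match emerges", {
  sp <- virtual_species(1, "mammal", 100, 1, 0, "abc")
  tab <- data.frame(taxon = "mammal", mass = 100,
                    trophic_level = 2.5, trophic_breadth = 1)
  got <- assign_trophic(sp, tab)
  expect_equal(got$match_threshold, 0.01)
  expect_equal(got$trophic_level, 2.5)
  expect_equal(got$trophic_breadth_floor, 1.5)
  expect_false(got$basal)

  # single record at twice the mass: relative difference is exactly 0.5, so
  # the first admitting threshold is 0.51
  tab2 <- data.frame(taxon = "mammal", mass = 200,
                     trophic_level = 3, trophic_breadth = 0.5)
  expect_equal(assign_trophic(sp, tab2)$match_threshold, 0.51)

  expect_error(assign_trophic(sp, data.frame(taxon = "bird", mass = 1,
                                             trophic_level = 2,
                                             trophic_breadth = 1)),
               "no trophic records")
})

test_that("trophic assignment never crosses taxa", {
  set.seed(21)
  tab <- data.frame(taxon = rep(c("mammal", "bird"), each = 30),
                    mass = rlnorm(60, 4, 1),
                    trophic_level = runif(60, 1.5, 4),
                    trophic_breadth = runif(60, 0.3, 1.5))
  tab$trophic_level[tab$taxon == "bird"] <- 99  # poison pill
  for (i in 1:25) {
    sp <- virtual_species(i, "mammal", rlnorm(1, 4, 1), 1, 0, "a")
    expect_lt(assign_trophic(sp, tab)$trophic_level, 99)
  }
})

test_that("phenotype compatibility enumerates ordered letter pairs", {
  set.seed(31)
  M <- matrix(runif(676, -1, 1), 26, 26, dimnames = list(letters, letters))
  tm <- structure(list(M = M, norm_min = -30, norm_max = 30, n_pairs = 0),
                  class = "trait_matrix")
  norm <- function(raw) min(1, max(0, (raw + 30) / 60))
  expect_equal(phenotype_compatibility("a", "b", tm), norm(M["a", "b"]))
  expect_equal(phenotype_compatibility("ab", "c", tm),
               norm(M["a", "c"] + M["b", "c"]))
  for (i in 1:20) {
    ph1 <- random_phenotypes(1); ph2 <- random_phenotypes(1)
    expect_equal(phenotype_compatibility(ph1, ph2, tm),
                 norm(brute_compat_raw(ph1, ph2, M)))
  }
  expect_error(phenotype_compatibility("aZ", "b", tm), "lowercase")
})

test_that("an all-ones trait matrix scores the product of phenotype lengths", {
  tm <- plain_tm()  # norm over [0, 100]
  for (L1 in c(1, 4, 10)) for (L2 in c(1, 7, 10)) {
    ph1 <- paste(rep("q", L1), collapse = "")
    ph2 <- paste(rep("z", L2), collapse = "")
    expect_equal(phenotype_compatibility(ph1, ph2, tm), L1 * L2 / 100)
  }
  # brute force over all length combinations: the maximum raw score is 100
  expect_equal(max(outer(1:10, 1:10)), 100)
})

test_that("trait-matrix normalization is seeded, bounded and uses both tails", {
  set.seed(41)
  tm1 <- make_trait_matrix(1e4)
  set.seed(41)
  tm2 <- make_trait_matrix(1e4)
  expect_identical(tm1, tm2)
  expect_lt(tm1$norm_min, tm1$norm_max)

  # with the full-size normalization sample, fresh random pairs stay inside
  # [0, 1] and occupy both tails of the score range; the exact extremes of
  # a subsample are dominated by the rare longest-phenotype pairs, so the
  # tail check is on reaching both outer fifths, not the extreme percentiles
  set.seed(42)
  tm_full <- make_trait_matrix(1e6)
  scores <- coexsim:::normalize_compat(
    coexsim:::raw_scores_random_pairs(tm_full$M, 1e5), tm_full)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_lt(min(scores), 0.2)
  expect_gt(max(scores), 0.8)
  expect_equal(median(scores), 0.5, tolerance = 0.1)
})

test_that("ratio limits are central-90% quantiles with pooled fallback", {
  set.seed(51)
  n <- 1000
  rec <- data.frame(resource_taxon = "mammal", consumer_taxon = "bird",
                    consumer_mass = 1000,
                    resource_mass = 1000 * runif(n, 0.01, 1))
  lim <- derive_ratio_limits(rec, min_records = 20)
  # uniform on [0.01, 1]: 5th and 95th percentiles at 0.0595 and 0.9505
  expect_lt(abs(lim$l_l["mammal", "bird"] - 0.0595), 0.025)
  expect_lt(abs(lim$l_u["mammal", "bird"] - 0.9505), 0.025)
  expect_false(lim$fallback["mammal", "bird"])
  # every other pair uses the pooled distribution
  expect_true(lim$fallback["bird", "mammal"])
  expect_equal(lim$l_l["bird", "mammal"], lim$pooled[1])

  # a sparse pair (3 records) stays on the pooled fallback
  rec2 <- rbind(rec, data.frame(resource_taxon = "reptile",
                                consumer_taxon = "reptile",
                                consumer_mass = 10, resource_mass = 5)[c(1, 1, 1), ])
  lim2 <- derive_ratio_limits(rec2, min_records = 20)
  expect_true(lim2$fallback["reptile", "reptile"])

  # degenerate distribution: widened and flagged
  rec3 <- data.frame(resource_taxon = "bird", consumer_taxon = "bird",
                     consumer_mass = 10, resource_mass = 1)[rep(1, 25), ]
  lim3 <- derive_ratio_limits(rec3, min_records = 20)
  expect_true(lim3$degenerate["bird", "bird"])
  expect_lt(lim3$l_l["bird", "bird"], lim3$l_u["bird", "bird"])

  expect_error(derive_ratio_limits(rec[0, ]), "no interaction records")
})

test_that("species pools honour counts, invariants and the fixture mass distribution", {
  set.seed(61)
  climate <- make_climate(nrow = 3, ncol = 3, years = 8)
  tables <- make_trait_tables(climate, n_niche_per_taxon = 120,
                              n_trophic_per_taxon = 60,
                              n_interactions_per_pair = 25)
  counts <- c(mammal = 80, bird = 40, reptile = 20, amphibian = 10)
  pool <- make_species_pool(tables$niche_records, tables$niche_samples,
                            tables$trophic_table, counts)
  expect_equal(unname(table(pool$taxon)[names(counts)]),
               unname(counts), ignore_attr = TRUE)
  expect_true(all(nchar(pool$phenotype) >= 1 & nchar(pool$phenotype) <= 10))
  expect_true(all(pool$trophic_breadth_floor <= pool$trophic_level))
  expect_true(all(pool$body_mass > 0))
  expect_true(all(pool$adaptive_capacity >= 0 & pool$adaptive_capacity <= 1))
  expect_identical(pool$basal, pool$trophic_breadth_floor <= 1)

  # sampling preserves the marginal mass distribution
  mam <- pool$body_mass[pool$taxon == "mammal"]
  src <- tables$niche_records$mass[tables$niche_records$taxon == "mammal"]
  expect_gt(suppressWarnings(ks.test(mam, src))$p.value, 0.01)

  # seeded determinism
  set.seed(99)
  p1 <- make_species_pool(tables$niche_records, tables$niche_samples,
                          tables$trophic_table, c(mammal = 15))
  set.seed(99)
  p2 <- make_species_pool(tables$niche_records, tables$niche_samples,
                          tables$trophic_table, c(mammal = 15))
  expect_identical(p1, p2)

  # oversampling falls back to replacement with a warning
  expect_warning(
    make_species_pool(tables$niche_records, tables$niche_samples,
                      tables$trophic_table, c(mammal = 200)),
    "replacement")
})
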