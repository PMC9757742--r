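test_that("seeding follows the land-fraction rule and the persistence filter", {
  set.seed(12)
  cl <- make_climate(nrow = 2, ncol = 2, years = 8)
  tabs <- mini_tables(cl, n = 40)
  cfg <- desk_config(years = 2, replicates = 1,
                     counts_per_taxon = c(mammal = 40, bird = 40,
                                          reptile = 40, amphibian = 40),
                     trait_pairs = 1e4)
  pool <- make_species_pool(tabs$niche_records, tabs$niche_samples,
                            tabs$trophic_table, cfg$counts_per_taxon)
  tm <- make_trait_matrix(1e4)
  lim <- derive_ratio_limits(tabs$interaction_records)

  # u = 0 leaves a cell empty
  lu0 <- make_landuse(nrow = 2, ncol = 2, years = 3, u0 = c(0, 1, 1, 1))
  w <- populate(make_world(pool, lim, tm, cl, lu0, cfg))
  expect_length(w$cells[[1]]$members, 0)
  expect_equal(w$phase, "seeded")

  # communities only hold species passing the filter in every calib month
  for (cell in 2:4) {
    mem <- w$cells[[cell]]$members
    if (length(mem) > 0)
      expect_true(all(coexsim:::calib_ext_max(w, mem, cell) < 0.05))
    expect_equal(w$cells[[cell]]$basal_cap,
                 sum(w$pool$basal[mem]))
  }

  # a hostile climate filters everyone out
  cl_hot <- cl
  cl_hot$T <- cl$T + 60
  w_hot <- populate(make_world(pool, lim, tm, cl_hot,
                               make_landuse(nrow = 2, ncol = 2, years = 3),
                               cfg))
  expect_true(all(lengths(lapply(w_hot$cells, `[[`, "members")) == 0))
})

test_that("burn-in freezes thresholds and an unforced step leaves them valid", {
  w <- mini_world(seed = 13, burn_in_steps = 10)
  expect_equal(w$phase, "burned_in")
  for (cell in seq_len(w$n_cells)) {
    web <- w$cells[[cell]]$web
    expect_true(web$frozen)
    if (length(web$ids) > 0) {
      Ap <- web$A_prime
      expect_true(all(colSums(Ap)[!web$basal] >= web$theta_consumer))
      expect_true(all(rowSums(Ap) <= web$theta_resource))
    }
  }
})

test_that("a stationary world with dispersal and adaptation off is a fixed point", {
  w <- mini_world(seed = 14, years = 5, stationary = TRUE,
                  dispersal = FALSE, adaptation = FALSE)
  for (arm in c("coext", "control")) {
    res <- run_arm(w, arm, years = 5)
    m <- res$metrics
    expect_true(all(m[cause_cols] == 0))
    expect_true(all(m$gains == 0))
    r0 <- m$richness[m$year == 0]
    for (y in 1:5) expect_equal(m$richness[m$year == y], r0)
  }
})

test_that("cause tallies balance the richness ledger each cell-year", {
  w <- mini_world(seed = 15, years = 6, stationary = FALSE)
  for (arm in c("coext", "control")) {
    m <- run_arm(w, arm, years = 6)$metrics
    m <- m[order(m$cell, m$year), ]
    for (cell in unique(m$cell)) {
      mc <- m[m$cell == cell, ]
      losses <- unname(rowSums(mc[cause_cols]))
      expect_equal(mc$richness[-1],
                   mc$richness[-nrow(mc)] - losses[-1] + mc$gains[-1])
    }
  }
})

test_that("disabling the adaptation lottery leaves every niche untouched", {
  w <- mini_world(seed = 16, years = 3, adaptation = FALSE,
                  stationary = FALSE)
  w$arm <- "coext"
  for (cell in seq_len(w$n_cells))
    w$cells[[cell]]$rich_cap <- length(w$cells[[cell]]$members)
  before <- w$niche
  res <- step_year(w, 1)
  expect_identical(res$world$niche, before)
})

test_that("the coextinction effect is a guarded percentage", {
  expect_equal(coextinction_effect(0.1, 0.1), 0)
  expect_equal(coextinction_effect(0.3, 0.1), 200)
  expect_true(is.na(coextinction_effect(0.2, 0)))
  expect_error(coextinction_effect(-0.1, 0.5), "non-negative")
})

test_that("experiments are reproducible from the master seed", {
  set.seed(17)
  cl <- make_climate(nrow = 3, ncol = 3, years = 9)
  lu <- make_landuse(nrow = 3, ncol = 3, years = 5)
  tabs <- mini_tables(cl, n = 40)
  cfg <- desk_config(years = 4, replicates = 2, burn_in_steps = 10,
                     counts_per_taxon = c(mammal = 40, bird = 40,
                                          reptile = 40, amphibian = 40),
                     trait_pairs = 1e4)
  e1 <- run_experiment(cl, lu, tabs, cfg, master_seed = 11)
  e2 <- run_experiment(cl, lu, tabs, cfg, master_seed = 11)
  expect_identical(e1$metrics, e2$metrics)
  expect_identical(e1$summary, e2$summary)
  e3 <- run_experiment(cl, lu, tabs, cfg, master_seed = 12)
  expect_false(identical(e1$metrics, e3$metrics))
})

test_that("the parameter-randomization harness draws inside the stated ranges", {
  set.seed(18)
  cl <- make_climate(nrow = 2, ncol = 2, years = 7)
  lu <- make_landuse(nrow = 2, ncol = 2, years = 3)
  tabs <- mini_tables(cl, n = 25)
  cfg <- desk_config(years = 2, replicates = 4, burn_in_steps = 5,
                     counts_per_taxon = c(mammal = 25, bird = 25,
                                          reptile = 25, amphibian = 25),
                     trait_pairs = 1e4)
  ranges <- list(burn_in_steps = c(0, 20), c_thresh = c(0.45, 0.65),
                 p_adp = c(0, 0.005), C_adp = c(0, 0.05),
                 S_LUC = c(-1, 1), V_LUC = c(0, 1))
  ex <- run_experiment(cl, lu, tabs, cfg, master_seed = 5,
                       param_ranges = ranges, arms = "coext")
  dp <- ex$drawn_params
  expect_equal(nrow(dp), 4)
  for (nm in names(ranges)) {
    expect_true(all(dp[[nm]] >= ranges[[nm]][1] - 1e-9))
    expect_true(all(dp[[nm]] <= ranges[[nm]][2] + 1e-9))
  }
  expect_gt(length(unique(dp$c_thresh)), 1)
})

test_that("world and config validation reject inconsistent inputs", {
  cl <- make_climate(nrow = 2, ncol = 2, years = 7)
  lu <- make_landuse(nrow = 3, ncol = 3, years = 10)
  cfg <- desk_config(years = 2, trait_pairs = 1e4)
  expect_error(make_world(NULL, NULL, NULL, cl, lu, cfg))
  expect_error(sim_config(p_thresh = 1.2), "p_thresh")
  expect_error(sim_config(S_LUC = 3), "S_LUC")
  expect_error(desk_config(years = -1), "horizon")
  lu2 <- make_landuse(nrow = 2, ncol = 2, years = 10)
  cfg_long <- desk_config(years = 50)
  expect_error(make_world(NULL, NULL, NULL, cl, lu2, cfg_long), "shorter")
})
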