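# Small worlds for simulator tests. The desk-scale study conditions
# (5x5 grid, 150 species per taxon, 60 seeded species per fully natural
# cell, 40-year horizon, 0.8 deg C/decade warming) live in desk_config()
# and the fixture generators' defaults; the helpers below shrink only the
# axes that a given test does not exercise.

mini_tables <- function(climate, n = 60) {
  make_trait_tables(climate, n_niche_per_taxon = n, n_trophic_per_taxon = n,
                    n_interactions_per_pair = 30)
}

# a seeded + burned-in world on a small stationary grid
mini_world <- function(seed = 1, nrow = 3, ncol = 3, years = 10,
                       stationary = TRUE, dispersal = TRUE,
                       adaptation = TRUE, burn_in_steps = 20, ...) {
  set.seed(seed)
  climate <- make_climate(nrow = nrow, ncol = ncol,
                          years = years + 5, calib_years = 5,
                          stationary = stationary)
  landuse <- make_landuse(nrow = nrow, ncol = ncol, years = years + 1)
  tables <- mini_tables(climate)
  cfg <- desk_config(years = years, replicates = 1,
                     counts_per_taxon = c(mammal = 60, bird = 60,
                                          reptile = 60, amphibian = 60),
                     trait_pairs = 2e4, burn_in_steps = burn_in_steps,
                     dispersal = dispersal, adaptation = adaptation, ...)
  pool <- make_species_pool(tables$niche_records, tables$niche_samples,
                            tables$trophic_table, cfg$counts_per_taxon)
  tm <- make_trait_matrix(cfg$trait_pairs)
  limits <- derive_ratio_limits(tables$interaction_records)
  world <- make_world(pool, limits, tm, climate, landuse, cfg)
  world$streams <- coexsim:::default_streams(world, seed)
  world <- coexsim:::stream_eval(world$streams, "populate",
                                 function() populate(world))
  burn_in(world)
}

cause_cols <- paste0("n_", c("climate", "landuse", "outcompeted",
                             "bottom_up", "top_down", "disconnected"))
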