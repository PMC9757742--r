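#' Synthetic fixture generators
#'
#' Every input the simulator needs can be generated synthetically: gridded
#' monthly climate with latitudinal structure, seasonality and a secular
#' warming trend; yearly land-use (fraction of primary + secondary land)
#' trajectories; and the three trait tables (niche-source climate samples,
#' trophic level/breadth by body mass and taxon, and resource-consumer
#' interaction records carrying prey-predator body-mass-ratio structure).
#' The generators emulate the statistical structure the algorithms are
#' sensitive to: log-normal body masses, a positive trophic-level/body-mass
#' association within each taxon, and taxon-pair-specific mass-ratio
#' distributions.
#'
#' @name fixtures
NULL

#' Gridded monthly climate series
#'
#' Temperature is a latitudinal gradient plus a seasonal sinusoid, a linear
#' secular trend and Gaussian noise; precipitation is built the same way and
#' clamped non-negative. The first `calib_years` are the niche-calibration
#' window. With `stationary = TRUE` the calibration block (with its noise,
#' but no trend) is tiled periodically over the whole series, so conditions
#' literally never change relative to the calibration window -- the variant
#' used for equilibrium runs.
#'
#' @param nrow,ncol grid dimensions; cell ids are row-major from the
#'   northwest corner.
#' @param years total years including the calibration window.
#' @param calib_years length of the calibration window.
#' @param trend_T warming trend in degrees C per decade.
#' @param trend_P precipitation trend in mm per decade.
#' @param base_T,base_P series-wide baselines (deg C, mm/month).
#' @param lat_gradient_T,lat_gradient_P per-row decrease moving north.
#' @param seasonal_amplitude_T,seasonal_amplitude_P seasonal sinusoid
#'   amplitudes.
#' @param noise_sd_T,noise_sd_P month-to-month Gaussian noise.
#' @param stationary tile the calibration block instead of extending the
#'   series (implies no trend).
#' @return a `climate_grid`: list with `T` and `P` (cells x months
#'   matrices), grid dimensions and window bookkeeping.
#' @export
make_climate <- function(nrow = 5, ncol = 5, years = 45, calib_years = 5,
                         trend_T = 0.8, trend_P = 0,
                         base_T = 18, base_P = 100,
                         lat_gradient_T = 1.5, lat_gradient_P = 5,
                         seasonal_amplitude_T = 8, seasonal_amplitude_P = 40,
                         noise_sd_T = 1, noise_sd_P = 15,
                         stationary = FALSE) {
  stopifnot(nrow > 0, ncol > 0, years > calib_years, calib_years > 0)
  n_cells <- nrow * ncol
  row_of <- rep(seq_len(nrow), each = ncol)

  gen_block <- function(n_months, trend_per_decade, base, lat_grad, amp,
                        noise_sd, clamp0) {
    t_idx <- seq_len(n_months)
    season <- amp * sin(2 * pi * (t_idx %% 12) / 12)
    trend <- trend_per_decade * (t_idx - 1) / 120
    out <- matrix(0, n_cells, n_months)
    for (cell in seq_len(n_cells)) {
      out[cell, ] <- base - lat_grad * (row_of[cell] - 1) + season + trend +
        stats::rnorm(n_months, 0, noise_sd)
    }
    if (clamp0) out[out < 0] <- 0
    out
  }

  n_months <- years * 12
  if (stationary) {
    block_months <- calib_years * 12
    reps <- ceiling(n_months / block_months)
    Tb <- gen_block(block_months, 0, base_T, lat_gradient_T,
                    seasonal_amplitude_T, noise_sd_T, clamp0 = FALSE)
    Pb <- gen_block(block_months, 0, base_P, lat_gradient_P,
                    seasonal_amplitude_P, noise_sd_P, clamp0 = TRUE)
    Tm <- do.call(cbind, rep(list(Tb), reps))[, seq_len(n_months), drop = FALSE]
    Pm <- do.call(cbind, rep(list(Pb), reps))[, seq_len(n_months), drop = FALSE]
  } else {
    Tm <- gen_block(n_months, trend_T, base_T, lat_gradient_T,
                    seasonal_amplitude_T, noise_sd_T, clamp0 = FALSE)
    Pm <- gen_block(n_months, trend_P, base_P, lat_gradient_P,
                    seasonal_amplitude_P, noise_sd_P, clamp0 = TRUE)
  }
  structure(list(T = Tm, P = Pm, nrow = nrow, ncol = ncol, years = years,
                 calib_years = calib_years, stationary = stationary),
            class = "climate_grid")
}

#' Yearly land-use (primary + secondary land fraction) series
#'
#' `u(cell, y + 1) = u(cell, y) * (1 - rate)`, i.e. geometric decay of the
#' natural-land fraction at a per-cell annual loss rate. `rate = 0` gives
#' the stationary variant.
#'
#' @param nrow,ncol grid dimensions.
#' @param years number of yearly values (the first is the seeding year).
#' @param u0 initial fraction, scalar or one value per cell.
#' @param annual_loss_rate in `[0, 1]`, scalar or one value per cell.
#' @return a `landuse_grid`: list with `u` (cells x years matrix) and grid
#'   dimensions.
#' @export
make_landuse <- function(nrow = 5, ncol = 5, years = 41, u0 = 1,
                         annual_loss_rate = 0) {
  stopifnot(all(annual_loss_rate >= 0), all(annual_loss_rate <= 1),
            all(u0 >= 0), all(u0 <= 1))
  n_cells <- nrow * ncol
  u0 <- rep_len(u0, n_cells)
  rate <- rep_len(annual_loss_rate, n_cells)
  u <- sapply(seq_len(years), function(y) u0 * (1 - rate)^(y - 1))
  u <- matrix(u, n_cells, years)
  structure(list(u = u, nrow = nrow, ncol = ncol, years = years),
            class = "landuse_grid")
}

#' Synthetic trait tables
#'
#' Generates the three tables the species factory consumes. Body masses are
#' log-normal per taxon. Trophic level increases stochastically with
#' within-taxon body-mass rank (so the pool reproduces the positive trophic
#' level/body mass association of real interaction data) and trophic breadth
#' is drawn so that small, low-trophic-level species are usually basal.
#' Interaction records carry log-normal prey-predator mass ratios whose
#' log-mean differs by taxon pair. Niche-source climate samples are the
#' calibration-window series of a random cell of the supplied climate, so
#' every record's niche is realizable somewhere on the grid.
#'
#' @param climate a `climate_grid` supplying niche-source samples.
#' @param n_niche_per_taxon records in the niche/body-mass table, per taxon.
#' @param n_trophic_per_taxon records in the trophic table, per taxon.
#' @param n_interactions_per_pair interaction records per ordered taxon pair.
#' @param region_radius Chebyshev radius of the home region a record's
#'   niche is calibrated on (0 = a single cell; the default 1 gives a 3 x 3
#'   window, emulating species ranging over several localities, so the
#'   climate of any one cell inside the range stays strictly within the
#'   range-wide extremes).
#' @param mass_meanlog named per-taxon log-mean body mass (grams).
#' @param mass_sdlog log-sd of body mass.
#' @param ratio_base_meanlog baseline log mass ratio of interaction records.
#' @param ratio_pair_spread deterministic per-pair offset scale applied to
#'   the log-ratio mean (resource taxon index minus consumer taxon index).
#' @param ratio_sdlog log-sd of the interaction mass ratios.
#' @return list with `niche_records`, `niche_samples`, `trophic_table`,
#'   `interaction_records`, and `params` (the injected generator constants,
#'   useful as an oracle in tests).
#' @export
make_trait_tables <- function(climate,
                              n_niche_per_taxon = 250,
                              n_trophic_per_taxon = 120,
                              n_interactions_per_pair = 60,
                              mass_meanlog = c(mammal = log(500),
                                               bird = log(80),
                                               reptile = log(150),
                                               amphibian = log(20)),
                              mass_sdlog = 1.2,
                              ratio_base_meanlog = -2.2,
                              ratio_pair_spread = 0.15,
                              ratio_sdlog = 0.8,
                              region_radius = 1) {
  stopifnot(inherits(climate, "climate_grid"))
  calib <- seq_len(climate$calib_years * 12)
  n_cells <- climate$nrow * climate$ncol
  cell_row <- rep(seq_len(climate$nrow), each = climate$ncol)
  cell_col <- rep(seq_len(climate$ncol), times = climate$nrow)
  region_of <- function(home) {
    which(abs(cell_row - cell_row[home]) <= region_radius &
            abs(cell_col - cell_col[home]) <= region_radius)
  }

  niche_records <- list()
  niche_samples <- list()
  rec_id <- 0L
  for (taxon in TAXA) {
    n <- n_niche_per_taxon
    if (length(n_niche_per_taxon) > 1) n <- n_niche_per_taxon[[taxon]]
    if (n == 0) next
    for (j in seq_len(n)) {
      rec_id <- rec_id + 1L
      home <- sample.int(n_cells, 1L)
      niche_records[[rec_id]] <- data.frame(
        record_id = rec_id, taxon = taxon,
        mass = stats::rlnorm(1, mass_meanlog[[taxon]], mass_sdlog),
        home_cell = home)
      region <- region_of(home)
      sT <- as.vector(t(climate$T[region, calib, drop = FALSE]))
      sP <- as.vector(t(climate$P[region, calib, drop = FALSE]))
      niche_samples[[rec_id]] <- data.frame(
        record_id = rec_id,
        variable = rep(c("T", "P"), times = c(length(sT), length(sP))),
        value = c(sT, sP))
    }
  }

  trophic <- list()
  for (taxon in TAXA) {
    n <- n_trophic_per_taxon
    if (length(n_trophic_per_taxon) > 1) n <- n_trophic_per_taxon[[taxon]]
    if (n == 0) next
    mass <- stats::rlnorm(n, mass_meanlog[[taxon]], mass_sdlog)
    u <- stats::pnorm((log(mass) - mass_meanlog[[taxon]]) / mass_sdlog)
    tl <- pmin(pmax(1.2 + 2.3 * u + stats::rnorm(n, 0, 0.25), 1.05), 4.5)
    breadth <- stats::runif(n, 0.2, pmax(tl - 0.2, 0.21))
    trophic[[taxon]] <- data.frame(taxon = taxon, mass = mass,
                                   trophic_level = tl,
                                   trophic_breadth = breadth)
  }

  inter <- list()
  k <- 0L
  for (rt in TAXA) for (ct in TAXA) {
    n <- n_interactions_per_pair
    if (n == 0) next
    k <- k + 1L
    mu <- ratio_base_meanlog +
      ratio_pair_spread * (match(rt, TAXA) - match(ct, TAXA))
    cmass <- stats::rlnorm(n, mass_meanlog[[ct]], mass_sdlog)
    ratio <- exp(stats::rnorm(n, mu, ratio_sdlog))
    inter[[k]] <- data.frame(resource_taxon = rt,
                             resource_mass = cmass * ratio,
                             consumer_taxon = ct, consumer_mass = cmass)
  }

  list(niche_records = do.call(rbind, niche_records),
       niche_samples = do.call(rbind, niche_samples),
       trophic_table = do.call(rbind, trophic),
       interaction_records = do.call(rbind, inter),
       params = list(mass_meanlog = mass_meanlog, mass_sdlog = mass_sdlog,
                     ratio_base_meanlog = ratio_base_meanlog,
                     ratio_pair_spread = ratio_pair_spread,
                     ratio_sdlog = ratio_sdlog))
}
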