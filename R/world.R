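#' World simulation
#'
#' The world is a lattice of localities, each holding a community of pool
#' species and (in the coextinction arm) a local food web. A run proceeds
#' as: seeding (`4500 * u` random species per cell, climate-filtered,
#' arranged into webs), a dispersal-only burn-in with webs rebuilt
#' periodically and thresholds frozen at its end, then yearly forcing steps
#' with monthly climate mortality, yearly land-use loss, an adaptation
#' lottery, coextinction cascades (coextinction arm only), and a dispersal
#' round. A control arm runs from the same post-burn-in snapshot with all
#' network effects disabled: primary extinctions are plain removals and the
#' only colonization constraints are climate and a per-cell diversity cap
#' at the snapshot richness.
#'
#' @name world_sim
NULL

CAUSES <- c("climate", "landuse", "outcompeted",
            "bottom_up", "top_down", "disconnected")

# ---- reproducible named RNG streams ---------------------------------------

seed_from <- function(master, k) {
  as.integer((as.double(master) %% 2147483629 * 16807 +
                as.double(k) * 999331) %% 2147483629 + 1)
}

make_streams <- function(seed, names) {
  env <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed(seed_from(seed, i))
    env[[names[i]]] <- get(".Random.seed", envir = globalenv())
  }
  env
}

clone_streams <- function(streams) {
  list2env(as.list(streams), new.env(parent = emptyenv()))
}

default_streams <- function(world, seed) {
  make_streams(seed, c("populate", "burnin",
                       as.vector(outer(c("mort_", "luc_", "adapt_", "disp_"),
                                       seq_len(world$n_cells), paste0))))
}

stream_eval <- function(streams, name, fn) {
  prev <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", streams[[name]], envir = globalenv())
  res <- fn()
  streams[[name]] <- get(".Random.seed", envir = globalenv())
  if (!is.null(prev)) assign(".Random.seed", prev, envir = globalenv())
  res
}

# ---- world construction ----------------------------------------------------

#' Assemble a world state
#'
#' @param pool a `species_pool`.
#' @param limits a `ratio_limits`.
#' @param tm a `trait_matrix`.
#' @param climate a `climate_grid`.
#' @param landuse a `landuse_grid` on the same grid; its first yearly value
#'   is the seeding year.
#' @param config a `coexsim_config`.
#' @return a `world_state` (phase `"created"`).
#' @export
make_world <- function(pool, limits, tm, climate, landuse, config) {
  stopifnot(inherits(climate, "climate_grid"),
            inherits(landuse, "landuse_grid"),
            climate$nrow == landuse$nrow, climate$ncol == landuse$ncol)
  if ((climate$years - climate$calib_years) < config$years)
    stop("climate series shorter than calibration window + simulated years")
  if (landuse$years < config$years + 1)
    stop("land-use series shorter than simulated years + seeding year")
  n_cells <- climate$nrow * climate$ncol
  coords <- cbind(row = rep(seq_len(climate$nrow), each = climate$ncol),
                  col = rep(seq_len(climate$ncol), times = climate$nrow))
  D <- as.matrix(stats::dist(coords))
  cells <- lapply(seq_len(n_cells), function(i)
    list(members = integer(0), web = NULL, basal_cap = 0L, rich_cap = 0L,
         arrival = numeric(0)))
  structure(
    list(pool = pool, limits = limits, tm = tm,
         counts = phenotype_counts(pool$phenotype),
         niche = pool_niche_matrix(pool),
         climate = climate, landuse = landuse, config = config,
         n_cells = n_cells, dist_round = round(D),
         snames = list(mort = paste0("mort_", seq_len(n_cells)),
                       luc = paste0("luc_", seq_len(n_cells)),
                       adapt = paste0("adapt_", seq_len(n_cells)),
                       disp = paste0("disp_", seq_len(n_cells))),
         calib_months = seq_len(climate$calib_years * 12),
         month0 = climate$calib_years * 12,
         sd_T = stats::sd(climate$T), sd_P = stats::sd(climate$P),
         cells = cells, streams = NULL, arm = NA_character_,
         phase = "created"),
    class = "world_state")
}

#' @export
print.world_state <- function(x, ...) {
  rich <- vapply(x$cells, function(c) length(c$members), integer(1))
  cat(sprintf("<world_state> %dx%d grid, phase=%s, arm=%s, richness %d-%d\n",
              x$climate$nrow, x$climate$ncol, x$phase,
              x$arm, min(rich), max(rich)))
  invisible(x)
}

# max combined extinction probability of pool rows over the calibration
# window; cached per (species, cell) since niches are immutable until the
# adaptation lottery starts (after burn-in), the only phases that use it
calib_ext_max <- function(world, idx, cell) {
  world$calib_pmax[idx, cell]
}

build_calib_cache <- function(world) {
  out <- matrix(NA_real_, nrow(world$pool), world$n_cells)
  for (cell in seq_len(world$n_cells)) {
    out[, cell] <- max_ext_prob_matrix(world$niche,
                                       world$climate$T[cell, world$calib_months],
                                       world$climate$P[cell, world$calib_months])
  }
  out
}

#' Seed the world's communities
#'
#' Each cell receives `round(seed_multiplier * u)` species drawn uniformly
#' from the pool, keeps only those whose combined extinction probability is
#' below the persistence filter for every month of the calibration window,
#' and arranges them into a food web (dropping non-participants). The
#' initial basal richness becomes the cell's colonization cap.
#'
#' @param world a `world_state` (phase `"created"`).
#' @return the world, phase `"seeded"`.
#' @export
populate <- function(world) {
  cfg <- world$config
  n_pool <- nrow(world$pool)
  if (is.null(world$calib_pmax)) world$calib_pmax <- build_calib_cache(world)
  for (cell in seq_len(world$n_cells)) {
    u <- world$landuse$u[cell, 1]
    n <- round(cfg$seed_multiplier * u)
    if (n > n_pool) {
      warning("cell ", cell, ": seeding count ", n,
              " exceeds pool size; capping")
      n <- n_pool
    }
    if (n == 0) next
    cand <- sample.int(n_pool, n)
    ok <- cand[calib_ext_max(world, cand, cell) < cfg$p_immune]
    web <- build_web(world$pool, ok, world$limits, world$tm,
                     cfg$c_thresh, world$counts)
    world$cells[[cell]]$members <- web$ids
    world$cells[[cell]]$web <- web
    world$cells[[cell]]$basal_cap <- sum(web$basal)
    world$cells[[cell]]$arrival <-
      stats::setNames(rep(0, length(web$ids)), web$ids)
  }
  world$phase <- "seeded"
  world
}

# rebuild one cell's web from its members, enforcing the basal cap by
# removing the climatically least-suitable basal species (newest first on
# ties); used during burn-in (thresholds not yet frozen)
rebuild_cell_web <- function(world, cell) {
  st <- world$cells[[cell]]
  web <- build_web(world$pool, st$members, world$limits, world$tm,
                   world$config$c_thresh, world$counts)
  excess <- sum(web$basal) - st$basal_cap
  if (excess > 0) {
    basal_ids <- web$ids[web$basal]
    p_ext <- calib_ext_max(world, basal_ids, cell)
    rank <- st$arrival[as.character(basal_ids)]
    victims <- basal_ids[order(-p_ext, -rank)][seq_len(excess)]
    web <- build_web(world$pool, setdiff(web$ids, victims), world$limits,
                    world$tm, world$config$c_thresh, world$counts)
  }
  st$members <- web$ids
  st$web <- web
  st$arrival <- st$arrival[as.character(web$ids)]
  world$cells[[cell]] <- st
  world
}

# one dispersal attempt from `cell`: sample a resident, draw a distance
# 1 + logNormal(0, 1), pick uniformly one cell whose grid distance rounds to
# the drawn distance (rounded); returns NULL on a silent failure
draw_dispersal <- function(world, cell) {
  members <- world$cells[[cell]]$members
  if (length(members) == 0) return(NULL)
  sp <- members[sample.int(length(members), 1L)]
  d <- 1 + stats::rlnorm(1, 0, 1)
  targets <- which(world$dist_round[cell, ] == round(d))
  targets <- setdiff(targets, cell)
  if (length(targets) == 0) return(NULL)
  list(sp = sp, target = targets[sample.int(length(targets), 1L)])
}

#' Burn-in phase
#'
#' Dispersal-only steps that give communities biogeographic structure before
#' forcing begins: at each step every cell sends one randomly chosen
#' resident towards a cell at a random dispersal distance, and the migrant
#' establishes if the target climate passes the calibration-window
#' persistence filter. Webs are rebuilt (with the basal cap enforced) every
#' `rebuild_every` steps; at the end the webs are rebuilt once more and the
#' coextinction thresholds recomputed and frozen.
#'
#' @param world a seeded `world_state`.
#' @return the world, phase `"burned_in"`, thresholds frozen.
#' @export
burn_in <- function(world) {
  cfg <- world$config
  if (is.null(world$calib_pmax)) world$calib_pmax <- build_calib_cache(world)
  run <- function() {
    for (step in seq_len(cfg$burn_in_steps)) {
      if (cfg$dispersal) {
        for (cell in seq_len(world$n_cells)) {
          mv <- draw_dispersal(world, cell)
          if (is.null(mv)) next
          tgt <- world$cells[[mv$target]]
          if (mv$sp %in% tgt$members) next
          if (calib_ext_max(world, mv$sp, mv$target) >= cfg$p_immune) next
          tgt$members <- c(tgt$members, mv$sp)
          tgt$arrival[as.character(mv$sp)] <- step
          world$cells[[mv$target]] <- tgt
        }
      }
      if (step %% cfg$rebuild_every == 0) {
        for (cell in seq_len(world$n_cells))
          world <- rebuild_cell_web(world, cell)
      }
    }
    world
  }
  world <- if (is.null(world$streams)) run() else
    stream_eval(world$streams, "burnin", run)
  for (cell in seq_len(world$n_cells)) {
    world <- rebuild_cell_web(world, cell)
    world$cells[[cell]]$web <- freeze_thresholds(world$cells[[cell]]$web)
  }
  world$phase <- "burned_in"
  world
}

# ---- yearly forcing --------------------------------------------------------

community_metrics <- function(pool, members) {
  if (length(members) == 0) {
    return(data.frame(richness = 0, edges = NA_real_, connectance = NA_real_,
                      diameter = NA_real_, lwcc_fraction = NA_real_,
                      mean_tl = 0, max_tl = 0, mean_mass = 0, max_mass = 0,
                      mean_log10_mass = 0))
  }
  sub <- pool[members, ]
  data.frame(richness = length(members), edges = NA_real_,
             connectance = NA_real_, diameter = NA_real_,
             lwcc_fraction = NA_real_,
             mean_tl = mean(sub$trophic_level), max_tl = max(sub$trophic_level),
             mean_mass = mean(sub$body_mass), max_mass = max(sub$body_mass),
             mean_log10_mass = mean(log10(sub$body_mass)))
}

cell_metrics_row <- function(world, cell, year, tallies, gains) {
  st <- world$cells[[cell]]
  m <- if (identical(world$arm, "coext")) web_metrics(st$web, world$pool)
       else community_metrics(world$pool, st$members)
  cbind(data.frame(arm = world$arm, cell = cell, year = year),
        m,
        as.data.frame(as.list(stats::setNames(tallies, paste0("n_", CAUSES)))),
        data.frame(gains = gains))
}

#' Baseline metrics of a burned-in world
#'
#' @param world a `world_state` with `arm` set.
#' @return metrics rows for year 0 (no losses, no gains).
#' @export
snapshot_metrics <- function(world) {
  zero <- stats::setNames(rep(0L, length(CAUSES)), CAUSES)
  do.call(rbind, lapply(seq_len(world$n_cells), function(cell)
    cell_metrics_row(world, cell, 0L, zero, 0L)))
}

#' Advance the world by one year
#'
#' Applies, in order: twelve monthly climate-mortality rounds (species with
#' extinction probability at or below the immunity level never die;
#' otherwise death is a Bernoulli draw at that probability), the yearly
#' land-use loss, the adaptation lottery (each resident may shift its niche
#' towards the previous year's local means with probability `p_adp`),
#' coextinction cascades over all of the year's primary losses (coextinction
#' arm only), a dispersal round, and metrics emission.
#'
#' @param world a burned-in `world_state` with `arm` set to `"coext"` or
#'   `"control"`.
#' @param year simulation year (1-based, after the calibration window).
#' @return list with `world` and `metrics` (one row per cell).
#' @export
step_year <- function(world, year) {
  cfg <- world$config
  coext <- identical(world$arm, "coext")
  months <- world$month0 + (year - 1) * 12 + seq_len(12)
  prev_months <- months - 12
  tallies <- matrix(0L, world$n_cells, length(CAUSES),
                    dimnames = list(NULL, CAUSES))
  gains <- integer(world$n_cells)
  Tm <- world$climate$T
  Pm <- world$climate$P
  cur_mean_T <- rowMeans(Tm[, months, drop = FALSE])
  cur_mean_P <- rowMeans(Pm[, months, drop = FALSE])

  for (cell in seq_len(world$n_cells)) {
    st <- world$cells[[cell]]
    if (length(st$members) == 0) next

    # (1) monthly climate mortality
    st$members <- stream_eval(world$streams, world$snames$mort[cell], function() {
      members <- st$members
      for (m in months) {
        if (length(members) == 0) break
        p <- ext_prob_matrix(world$niche[members, , drop = FALSE],
                             Tm[cell, m], Pm[cell, m])
        vulnerable <- p > cfg$p_immune
        if (!any(vulnerable)) next
        die <- vulnerable
        die[vulnerable] <- stats::runif(sum(vulnerable)) < p[vulnerable]
        tallies[cell, "climate"] <<- tallies[cell, "climate"] + sum(die)
        members <- members[!die]
      }
      members
    })

    # (2) yearly land-use loss
    u_prev <- world$landuse$u[cell, year]
    u_now <- world$landuse$u[cell, year + 1]
    P_LUC <- if (u_prev > 0) min(max((u_prev - u_now) / u_prev, 0), 1) else 0
    if (P_LUC > 0 && length(st$members) > 0) {
      st$members <- stream_eval(world$streams, world$snames$luc[cell], function() {
        n <- loss_count(loss_fraction(P_LUC, cfg$S_LUC), length(st$members))
        if (n > 0) {
          victims <- select_landuse_casualties(
            st$members, world$pool$body_mass[st$members], n, cfg$V_LUC)
          tallies[cell, "landuse"] <<- tallies[cell, "landuse"] + n
          setdiff(st$members, victims)
        } else st$members
      })
    }

    # (3) adaptation lottery
    if (cfg$adaptation && cfg$p_adp > 0 && length(st$members) > 0) {
      stream_eval(world$streams, world$snames$adapt[cell], function() {
        win <- st$members[stats::runif(length(st$members)) < cfg$p_adp]
        for (s in win) {
          world$niche[s, ] <<- shift_niche_row(
            world$niche[s, ],
            mean(Tm[cell, prev_months]), mean(Pm[cell, prev_months]),
            cfg$C_adp * world$pool$adaptive_capacity[s], cfg$p_thresh)
        }
        NULL
      })
    }

    # (4) cascades (coextinction arm)
    if (coext) {
      pending <- setdiff(st$web$ids, st$members)
      if (length(pending) > 0) {
        res <- cascade(st$web, pending)
        st$web <- res$web
        st$members <- res$web$ids
        for (cz in res$causes)
          tallies[cell, cz] <- tallies[cell, cz] + 1L
      }
    }
    st$arrival <- st$arrival[names(st$arrival) %in% as.character(st$members)]
    world$cells[[cell]] <- st
  }

  # (5) dispersal round
  if (cfg$dispersal) {
    for (cell in seq_len(world$n_cells)) {
      mv <- stream_eval(world$streams, world$snames$disp[cell], function() {
        mv <- draw_dispersal(world, cell)
        if (is.null(mv)) return(NULL)
        if (mv$sp %in% world$cells[[mv$target]]$members) return(NULL)
        p_e <- ext_prob_matrix(world$niche[mv$sp, , drop = FALSE],
                               cur_mean_T[mv$target], cur_mean_P[mv$target])
        if (stats::runif(1) >= 1 - p_e) return(NULL)
        mv
      })
      if (is.null(mv)) next
      tgt <- world$cells[[mv$target]]
      suit_fun <- function(idx)
        ext_prob_matrix(world$niche[idx, , drop = FALSE],
                        cur_mean_T[mv$target], cur_mean_P[mv$target])
      if (coext) {
        res <- try_colonize(tgt$web, mv$sp, world$pool, world$limits,
                            world$tm, cfg$c_thresh,
                            basal_cap = tgt$basal_cap,
                            suitability = suit_fun,
                            arrival_rank = tgt$arrival,
                            counts = world$counts)
        tgt$web <- res$web
        tgt$members <- res$web$ids
        resident_removed <- res$removed != mv$sp & res$causes != "rejected"
        for (cz in res$causes[resident_removed])
          tallies[mv$target, cz] <- tallies[mv$target, cz] + 1L
        if (mv$sp %in% res$web$ids) {
          gains[mv$target] <- gains[mv$target] + 1L
          tgt$arrival[as.character(mv$sp)] <- world$month0 + year
        }
      } else {
        members <- c(tgt$members, mv$sp)
        tgt$arrival[as.character(mv$sp)] <- world$month0 + year
        excess <- length(members) - tgt$rich_cap
        if (excess > 0) {
          p_ext <- suit_fun(members)
          rank <- tgt$arrival[as.character(members)]
          rank[is.na(rank)] <- 0
          victims <- members[order(-p_ext, -rank)][seq_len(excess)]
          resident_victims <- setdiff(victims, mv$sp)
          tallies[mv$target, "outcompeted"] <-
            tallies[mv$target, "outcompeted"] + length(resident_victims)
          members <- setdiff(members, victims)
        }
        if (mv$sp %in% members) gains[mv$target] <- gains[mv$target] + 1L
        tgt$members <- members
      }
      tgt$arrival <- tgt$arrival[names(tgt$arrival) %in%
                                   as.character(tgt$members)]
      world$cells[[mv$target]] <- tgt
    }
  }

  metrics <- do.call(rbind, lapply(seq_len(world$n_cells), function(cell)
    cell_metrics_row(world, cell, year, tallies[cell, ], gains[cell])))
  list(world = world, metrics = metrics)
}

#' Run one arm from a burned-in snapshot
#'
#' @param world a burned-in `world_state`.
#' @param arm `"coext"` or `"control"`.
#' @param years horizon (defaults to the config's).
#' @return list with the final `world` and the `metrics` data.frame
#'   (including the year-0 baseline).
#' @export
run_arm <- function(world, arm = c("coext", "control"), years = NULL) {
  arm <- match.arg(arm)
  stopifnot(world$phase == "burned_in")
  if (is.null(years)) years <- world$config$years
  world$arm <- arm
  if (is.null(world$streams)) world$streams <- default_streams(world, 1L)
  world$streams <- clone_streams(world$streams)
  for (cell in seq_len(world$n_cells))
    world$cells[[cell]]$rich_cap <- length(world$cells[[cell]]$members)
  out <- vector("list", years + 1)
  out[[1]] <- snapshot_metrics(world)
  for (y in seq_len(years)) {
    res <- step_year(world, y)
    world <- res$world
    out[[y + 1]] <- res$metrics
  }
  world$phase <- "done"
  list(world = world, metrics = do.call(rbind, out))
}

#' Coextinction effect (percentage amplification)
#'
#' `100 * (loss_coext - loss_control) / loss_control`; undefined (NA) when
#' the control loss is zero.
#'
#' @param loss_coext,loss_control diversity-loss fractions in `[0, 1]`.
#' @return percentage increase, `NA` where undefined.
#' @export
coextinction_effect <- function(loss_coext, loss_control) {
  if (any(loss_coext < 0, na.rm = TRUE) || any(loss_control < 0, na.rm = TRUE))
    stop("losses must be non-negative")
  ifelse(loss_control > 0,
         100 * (loss_coext - loss_control) / loss_control, NA_real_)
}

#' Run the full experiment
#'
#' For each replicate: generate an independent species pool and trait
#' matrix, seed and burn in a world, then run the coextinction and control
#' arms from the same post-burn-in snapshot with identical random-stream
#' states. Fully reproducible from `(inputs, config, master_seed)`.
#'
#' @param climate a `climate_grid`.
#' @param landuse a `landuse_grid`.
#' @param tables trait tables as produced by [make_trait_tables()].
#' @param config a `coexsim_config`.
#' @param master_seed integer master seed.
#' @param arms which arms to run.
#' @param param_ranges optional named list of `c(lo, hi)` ranges; when
#'   given, each replicate draws its own values of those config entries
#'   uniformly (the parameter-randomization harness; supported names:
#'   `burn_in_steps`, `c_thresh`, `p_adp`, `C_adp`, `S_LUC`, `V_LUC`).
#' @return an experiment bundle: list with `metrics` (per cell, year, arm,
#'   replicate), `summary` (per replicate and arm: mean local diversity
#'   loss, mean log10 body mass at year 0 and the final year, and the
#'   per-replicate coextinction effect), `config`, `master_seed`,
#'   `replicate_seeds`, and `drawn_params`.
#' @export
run_experiment <- function(climate, landuse, tables, config = sim_config(),
                           master_seed = 1L,
                           arms = c("coext", "control"),
                           param_ranges = NULL) {
  arms <- match.arg(arms, several.ok = TRUE)
  R <- config$replicates
  rep_seeds <- vapply(seq_len(R), function(r) seed_from(master_seed, 1000 + r),
                      integer(1))
  limits <- derive_ratio_limits(tables$interaction_records,
                                config$min_ratio_records)
  all_metrics <- list()
  summary_rows <- list()
  drawn <- list()

  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    cfg <- config
    if (!is.null(param_ranges)) {
      for (nm in names(param_ranges)) {
        rg <- param_ranges[[nm]]
        val <- stats::runif(1, rg[1], rg[2])
        if (nm == "burn_in_steps") val <- round(val)
        cfg[[nm]] <- val
      }
      cfg <- validate_config(unclass(cfg))
    }
    drawn[[r]] <- cfg[c("burn_in_steps", "c_thresh", "p_adp", "C_adp",
                        "S_LUC", "V_LUC")]
    pool <- make_species_pool(tables$niche_records, tables$niche_samples,
                              tables$trophic_table, cfg$counts_per_taxon,
                              cfg$p_thresh)
    tm <- make_trait_matrix(cfg$trait_pairs)
    world <- make_world(pool, limits, tm, climate, landuse, cfg)
    world$streams <- default_streams(world, rep_seeds[r])
    world <- stream_eval(world$streams, "populate", function() populate(world))
    world <- burn_in(world)

    for (arm in arms) {
      res <- run_arm(world, arm)
      m <- res$metrics
      m$replicate <- r
      all_metrics[[length(all_metrics) + 1]] <- m
      s <- arm_summary(m)
      summary_rows[[length(summary_rows) + 1]] <-
        cbind(data.frame(replicate = r, arm = arm), s)
    }
  }

  metrics <- do.call(rbind, all_metrics)
  summary <- do.call(rbind, summary_rows)
  if (all(c("coext", "control") %in% summary$arm)) {
    wide <- merge(summary[summary$arm == "coext",
                          c("replicate", "mean_loss")],
                  summary[summary$arm == "control",
                          c("replicate", "mean_loss")],
                  by = "replicate", suffixes = c("_coext", "_control"))
    wide$coextinction_effect <-
      coextinction_effect(wide$mean_loss_coext, wide$mean_loss_control)
    effect <- wide
  } else effect <- NULL

  structure(list(metrics = metrics, summary = summary, effect = effect,
                 config = config, master_seed = master_seed,
                 replicate_seeds = rep_seeds,
                 drawn_params = if (is.null(param_ranges)) NULL else
                   do.call(rbind, lapply(drawn, as.data.frame))),
            class = "coexsim_experiment")
}

# per-arm summary of one replicate's metrics: mean local diversity loss
# (relative to the year-0 richness, over cells occupied at year 0) and mean
# log10 body mass at year 0 and the final year
arm_summary <- function(m) {
  y0 <- m[m$year == 0, ]
  yF <- m[m$year == max(m$year), ]
  occ <- y0$cell[y0$richness > 0]
  r0 <- y0$richness[match(occ, y0$cell)]
  rF <- yF$richness[match(occ, yF$cell)]
  loss <- if (length(occ) > 0) mean((r0 - rF) / r0) else NA_real_
  data.frame(
    mean_loss = loss,
    mass0 = mean(y0$mean_log10_mass[y0$richness > 0]),
    massF = mean(yF$mean_log10_mass[yF$richness > 0]),
    final_year = max(m$year))
}

# shift one row of a niche parameter matrix towards local means by the
# fraction frac = C_adp * A of the remaining distance (the shift length
# C_adp * A * d_N along the standardized segment is that same fraction on
# every axis), then re-derive the logistic parameters
shift_niche_row <- function(row, target_T, target_P, frac, p_thresh = 0.95) {
  dT <- frac * (target_T - row[["T_xmean"]])
  dP <- frac * (target_P - row[["P_xmean"]])
  if (dT != 0) {
    ax <- fit_axis_params(row[["T_xmean"]] + dT, row[["T_vmin"]] + dT,
                          row[["T_vmax"]] + dT, p_thresh = p_thresh)
    row[c("T_xmean", "T_vmin", "T_vmax", "T_a", "T_b", "T_c", "T_d")] <-
      c(ax$x_mean, ax$v_min, ax$v_max, ax$a, ax$b, ax$c, ax$d)
  }
  if (dP != 0) {
    ax <- fit_axis_params(row[["P_xmean"]] + dP, row[["P_vmin"]] + dP,
                          row[["P_vmax"]] + dP, p_thresh = p_thresh)
    row[c("P_xmean", "P_vmin", "P_vmax", "P_a", "P_b", "P_c", "P_d")] <-
      c(ax$x_mean, ax$v_min, ax$v_max, ax$a, ax$b, ax$c, ax$d)
  }
  row
}
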