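#' Virtual species and trait machinery
#'
#' Virtual species carry a body mass, a trophic position (maximum distance
#' from a basal resource) and a trophic breadth floor (the minimum trophic
#' level of a resource they can use), a functional phenotype (a random string
#' of 1-10 lowercase letters), an adaptive capacity in `[0, 1]`, and two
#' fitted niche axes. Species whose trophic breadth reaches down to the
#' plant/invertebrate level (trophic level 1 by convention) are "basal":
#' herbivores and insectivores whose resources are treated as non-depletable.
#'
#' @name virtual_species
NULL

# trophic level of the implicit plant/invertebrate resource pool
BASAL_RESOURCE_LEVEL <- 1

TAXA <- c("mammal", "bird", "reptile", "amphibian")

#' Construct a virtual species
#'
#' @param id opaque identifier.
#' @param taxon one of `"mammal"`, `"bird"`, `"reptile"`, `"amphibian"`.
#' @param body_mass grams, positive.
#' @param trophic_level maximum distance from a basal resource (>= 1).
#' @param trophic_breadth_floor minimum trophic level of a consumable
#'   resource; at or below 1 the species is basal.
#' @param phenotype string of 1-10 lowercase letters.
#' @param adaptive_capacity in `[0, 1]`.
#' @param niche_T,niche_P fitted `niche_axis` objects (may be `NULL` for
#'   purely structural uses).
#' @param match_threshold final body-size-match threshold recorded during
#'   trophic assignment.
#' @return a `virtual_species`.
#' @export
virtual_species <- function(id, taxon, body_mass, trophic_level,
                            trophic_breadth_floor, phenotype,
                            adaptive_capacity = 0.5, niche_T = NULL,
                            niche_P = NULL, match_threshold = NA_real_) {
  new_virtual_species(id, taxon, body_mass, trophic_level,
                      trophic_breadth_floor, phenotype, adaptive_capacity,
                      niche_T, niche_P, match_threshold)
}

new_virtual_species <- function(id, taxon, body_mass, trophic_level,
                                trophic_breadth_floor, phenotype,
                                adaptive_capacity, niche_T, niche_P,
                                match_threshold = NA_real_) {
  stopifnot(body_mass > 0, nchar(phenotype) >= 1, nchar(phenotype) <= 10,
            trophic_breadth_floor <= trophic_level)
  structure(
    list(id = id, taxon = taxon, body_mass = body_mass,
         trophic_level = trophic_level,
         trophic_breadth_floor = trophic_breadth_floor,
         basal = trophic_breadth_floor <= BASAL_RESOURCE_LEVEL,
         phenotype = phenotype, adaptive_capacity = adaptive_capacity,
         niche_T = niche_T, niche_P = niche_P,
         match_threshold = match_threshold),
    class = "virtual_species")
}

#' Do two body sizes match?
#'
#' Two masses match when their relative difference,
#' `(max(m1, m2) - min(m1, m2)) / max(m1, m2)`, is strictly below `r_thresh`.
#'
#' @param m1,m2 body masses in grams, positive.
#' @param r_thresh relative-difference threshold in `(0, 1]`.
#' @return logical.
#' @export
body_sizes_match <- function(m1, m2, r_thresh) {
  if (any(m1 <= 0) || any(m2 <= 0)) stop("body masses must be positive")
  stopifnot(r_thresh > 0, r_thresh <= 1)
  hi <- pmax(m1, m2)
  (hi - pmin(m1, m2)) / hi < r_thresh
}

#' Assign trophic level and breadth by body-size matching
#'
#' Scans the trophic records of the species' own taxon in random order at
#' `r_thresh = 0.01`; if no record matches the species' body mass, the
#' threshold is raised by 0.01 and the scan repeated until a match emerges.
#' The trophic level and breadth of the matched record are copied onto the
#' species and the final threshold is recorded.
#'
#' @param species a `virtual_species` (mass and taxon populated).
#' @param trophic_table data.frame with columns `taxon`, `mass`,
#'   `trophic_level`, `trophic_breadth`.
#' @param step threshold escalation step.
#' @return the species with `trophic_level`, `trophic_breadth_floor`,
#'   `basal` and `match_threshold` filled in.
#' @export
assign_trophic <- function(species, trophic_table, step = 0.01) {
  cand <- trophic_table[trophic_table$taxon == species$taxon, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("no trophic records for taxon '", species$taxon, "'")
  hi <- pmax(cand$mass, species$body_mass)
  r <- (hi - pmin(cand$mass, species$body_mass)) / hi
  # Scanning a fresh random order at each escalation and stopping at the
  # first match is equivalent to: find the first threshold admitting any
  # candidate, then pick uniformly among the admitted candidates.
  k <- 1L
  repeat {
    ok <- which(r < k * step)
    if (length(ok) > 0) break
    k <- k + 1L
    if (k * step > 1 + max(r)) stop("trophic match escalation failed")
  }
  pick <- ok[sample.int(length(ok), 1L)]
  species$trophic_level <- cand$trophic_level[pick]
  breadth <- cand$trophic_breadth[pick]
  species$trophic_breadth_floor <- max(species$trophic_level - breadth, 0)
  species$basal <- species$trophic_breadth_floor <= BASAL_RESOURCE_LEVEL
  species$match_threshold <- k * step
  species
}

#' Random functional phenotypes
#'
#' @param n number of phenotypes.
#' @return character vector of random strings of 1-10 lowercase letters.
#' @export
random_phenotypes <- function(n) {
  lens <- sample.int(10L, n, replace = TRUE)
  vapply(lens, function(L)
    paste(letters[sample.int(26L, L, replace = TRUE)], collapse = ""),
    character(1))
}

# letter-count matrix (n x 26) of a character vector of phenotypes
phenotype_counts <- function(phenotypes) {
  n <- length(phenotypes)
  chars <- strsplit(phenotypes, "")
  lens <- lengths(chars)
  li <- match(unlist(chars), letters)
  ri <- rep.int(seq_len(n), lens)
  out <- matrix(tabulate(ri + n * (li - 1L), nbins = n * 26L), n, 26L,
                dimnames = list(NULL, letters))
  out
}

#' Create a trait-compatibility matrix
#'
#' Draws a 26 x 26 matrix of letter-by-letter compatibilities uniform on
#' `[-1, 1]`, then estimates normalization constants by scoring `n_pairs`
#' random phenotype pairs (generated exactly as in species creation) and
#' recording the minimum and maximum raw score observed. Normalized
#' compatibilities later computed with this matrix are mapped through
#' `(raw - norm_min) / (norm_max - norm_min)` and clipped to `[0, 1]`.
#'
#' @param n_pairs number of random pairs used for normalization
#'   (default `1e6`).
#' @return a `trait_matrix` object (fields `M`, `norm_min`, `norm_max`).
#' @export
make_trait_matrix <- function(n_pairs = 1e6) {
  M <- matrix(stats::runif(26 * 26, -1, 1), 26, 26,
              dimnames = list(letters, letters))
  tm <- structure(list(M = M, norm_min = 0, norm_max = 1, n_pairs = n_pairs),
                  class = "trait_matrix")
  rng <- range(raw_scores_random_pairs(M, n_pairs))
  if (rng[1] >= rng[2])
    stop("degenerate trait matrix: normalization constants coincide")
  tm$norm_min <- rng[1]
  tm$norm_max <- rng[2]
  tm
}

# raw compatibility scores of n random phenotype pairs, chunked for memory
raw_scores_random_pairs <- function(M, n, chunk = 50000L) {
  out <- numeric(0)
  done <- 0L
  while (done < n) {
    k <- min(chunk, n - done)
    U <- phenotype_counts(random_phenotypes(k))
    V <- phenotype_counts(random_phenotypes(k))
    out <- c(out, rowSums((U %*% M) * V))
    done <- done + k
  }
  out
}

#' Normalized compatibility of two phenotypes
#'
#' The raw score sums `M[l1, l2]` over all ordered letter pairs (letters of
#' the resource phenotype index rows, letters of the consumer phenotype index
#' columns); the result is normalized by the matrix' Monte-Carlo constants
#' and clipped to `[0, 1]`.
#'
#' @param ph1 resource phenotype.
#' @param ph2 consumer phenotype.
#' @param tm a `trait_matrix`.
#' @return compatibility in `[0, 1]`.
#' @export
phenotype_compatibility <- function(ph1, ph2, tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  i1 <- match(strsplit(ph1, "")[[1]], letters)
  i2 <- match(strsplit(ph2, "")[[1]], letters)
  if (anyNA(i1) || anyNA(i2))
    stop("phenotypes must use lowercase letters a-z only")
  raw <- sum(tm$M[i1, i2, drop = FALSE])
  normalize_compat(raw, tm)
}

normalize_compat <- function(raw, tm) {
  pmin(1, pmax(0, (raw - tm$norm_min) / (tm$norm_max - tm$norm_min)))
}

#' Derive admissible resource:consumer body-mass ratio limits
#'
#' For each (resource taxon, consumer taxon) pair with at least `min_records`
#' interaction records, `l_l` and `l_u` are the 5th and 95th percentiles
#' (central 90% limits) of the resource:consumer mass ratios. Pairs with too
#' few records fall back to the pooled all-taxa distribution. A degenerate
#' pair distribution (all ratios equal) is widened by machine epsilon and
#' flagged.
#'
#' @param interaction_records data.frame with columns `resource_taxon`,
#'   `resource_mass`, `consumer_taxon`, `consumer_mass`.
#' @param min_records minimum records per taxon pair before falling back.
#' @return a `ratio_limits` object: 4 x 4 matrices `l_l` and `l_u` indexed
#'   `[resource_taxon, consumer_taxon]`, plus the pooled limits.
#' @export
derive_ratio_limits <- function(interaction_records, min_records = 20) {
  if (nrow(interaction_records) == 0) stop("no interaction records")
  ratios <- interaction_records$resource_mass / interaction_records$consumer_mass
  stopifnot(all(ratios > 0))
  q <- function(x) {
    lim <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    flagged <- FALSE
    if (lim[1] >= lim[2]) {
      eps <- .Machine$double.eps * max(1, lim[1])
      lim <- c(lim[1] - eps, lim[2] + eps)
      flagged <- TRUE
    }
    list(lim = lim, flagged = flagged)
  }
  pooled <- q(ratios)
  ll <- matrix(pooled$lim[1], 4, 4, dimnames = list(TAXA, TAXA))
  lu <- matrix(pooled$lim[2], 4, 4, dimnames = list(TAXA, TAXA))
  fallback <- matrix(TRUE, 4, 4, dimnames = list(TAXA, TAXA))
  degenerate <- matrix(pooled$flagged, 4, 4, dimnames = list(TAXA, TAXA))
  for (rt in TAXA) for (ct in TAXA) {
    sel <- interaction_records$resource_taxon == rt &
      interaction_records$consumer_taxon == ct
    if (sum(sel) >= min_records) {
      res <- q(ratios[sel])
      ll[rt, ct] <- res$lim[1]
      lu[rt, ct] <- res$lim[2]
      fallback[rt, ct] <- FALSE
      degenerate[rt, ct] <- res$flagged
    }
  }
  structure(list(l_l = ll, l_u = lu, fallback = fallback,
                 degenerate = degenerate, pooled = pooled$lim),
            class = "ratio_limits")
}

#' Generate a pool of virtual species
#'
#' Samples `(niche, mass)` records per taxon to the requested counts, assigns
#' trophic level and breadth by body-size matching against the trophic table,
#' draws a random phenotype (length uniform on 1-10, letters uniform) and an
#' adaptive capacity uniform on `[0, 1]`, and fits both niche axes to the
#' record's climate samples. The latent taxon tag is retained only for
#' mass-ratio-limit lookup during web assembly.
#'
#' @param niche_records data.frame with columns `record_id`, `taxon`, `mass`.
#' @param niche_samples data.frame with columns `record_id`, `variable`
#'   (`"T"` or `"P"`), `value`: the monthly climate samples each record's
#'   niche is calibrated on.
#' @param trophic_table see [assign_trophic()].
#' @param counts_per_taxon named integer vector over
#'   `mammal`, `bird`, `reptile`, `amphibian`.
#' @param p_thresh edge survival probability for the niche fits.
#' @return a `species_pool`: data.frame with one row per species (niche
#'   parameters inline, columns as in the serialization format) and the
#'   trophic/phenotype fields.
#' @export
make_species_pool <- function(niche_records, niche_samples, trophic_table,
                              counts_per_taxon = c(mammal = 5513, bird = 10425,
                                                   reptile = 10038,
                                                   amphibian = 7302),
                              p_thresh = 0.95) {
  stopifnot(all(names(counts_per_taxon) %in% TAXA))
  sampT <- split(niche_samples$value[niche_samples$variable == "T"],
                 niche_samples$record_id[niche_samples$variable == "T"])
  sampP <- split(niche_samples$value[niche_samples$variable == "P"],
                 niche_samples$record_id[niche_samples$variable == "P"])

  rows <- list()
  sp_id <- 0L
  for (taxon in names(counts_per_taxon)) {
    n <- counts_per_taxon[[taxon]]
    if (n == 0) next
    recs <- niche_records[niche_records$taxon == taxon, , drop = FALSE]
    if (nrow(recs) == 0) stop("no niche records for taxon '", taxon, "'")
    replace <- n > nrow(recs)
    if (replace)
      warning("requested ", n, " ", taxon, "s from ", nrow(recs),
              " records; sampling with replacement")
    picks <- sample.int(nrow(recs), n, replace = replace)
    phens <- random_phenotypes(n)
    for (j in seq_len(n)) {
      sp_id <- sp_id + 1L
      rec <- recs[picks[j], ]
      key <- as.character(rec$record_id)
      axT <- fit_axis(sampT[[key]], p_thresh = p_thresh)
      axP <- fit_axis(sampP[[key]], p_thresh = p_thresh)
      sp <- new_virtual_species(
        id = sp_id, taxon = taxon, body_mass = rec$mass,
        trophic_level = 1, trophic_breadth_floor = 0,
        phenotype = phens[j],
        adaptive_capacity = stats::runif(1),
        niche_T = axT, niche_P = axP)
      sp <- assign_trophic(sp, trophic_table)
      rows[[sp_id]] <- c(
        list(id = sp$id, taxon = sp$taxon, body_mass = sp$body_mass,
             trophic_level = sp$trophic_level,
             trophic_breadth_floor = sp$trophic_breadth_floor,
             basal = sp$basal, phenotype = sp$phenotype,
             adaptive_capacity = sp$adaptive_capacity,
             match_threshold = sp$match_threshold),
        as.list(c(axis_to_row(axT, "T"), axis_to_row(axP, "P"))))
    }
  }
  pool <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(pool) <- NULL
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' Extract one species from a pool as a `virtual_species`
#'
#' @param pool a `species_pool`.
#' @param i row index.
#' @param niche optional niche parameter matrix overriding the pool's inline
#'   niche columns (the world simulator mutates niches per arm).
#' @return a `virtual_species`.
#' @export
pool_species <- function(pool, i, niche = NULL) {
  row <- pool[i, ]
  np <- if (is.null(niche)) unlist(row[.NICHE_COLS]) else niche[i, ]
  new_virtual_species(
    id = row$id, taxon = row$taxon, body_mass = row$body_mass,
    trophic_level = row$trophic_level,
    trophic_breadth_floor = row$trophic_breadth_floor,
    phenotype = row$phenotype, adaptive_capacity = row$adaptive_capacity,
    niche_T = row_to_axis(np, "T"), niche_P = row_to_axis(np, "P"),
    match_threshold = row$match_threshold)
}

# niche parameter matrix (n x 14) of a pool; the world simulator copies and
# mutates this per arm while the pool itself stays immutable
pool_niche_matrix <- function(pool) {
  as.matrix(pool[, .NICHE_COLS])
}
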