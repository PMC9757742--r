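# Independent brute-force oracles used across tests. These deliberately
# re-derive every quantity with plain loops, never through the package's own
# vectorized code paths.

# raw phenotype compatibility by explicit enumeration of ordered letter pairs
brute_compat_raw <- function(ph1, ph2, M) {
  l1 <- strsplit(ph1, "")[[1]]
  l2 <- strsplit(ph2, "")[[1]]
  s <- 0
  for (a in l1) for (b in l2) s <- s + M[a, b]
  s
}

# competition rescaling by explicit double loop
brute_rescale <- function(A) {
  n <- nrow(A)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    S <- sum(A[i, ])
    if (S > 0) for (j in seq_len(n)) out[i, j] <- A[i, j] * (A[i, j] / S)
  }
  out
}

# fixed-point cascade oracle: recompute all sums from scratch each sweep,
# using index bookkeeping entirely separate from cascade()'s. The threshold
# comparisons carry a tie tolerance: nodes sitting exactly at a frozen
# threshold (equality by construction) must not be tipped over by the
# last-ulp difference between this oracle's arithmetic and the package's.
brute_cascade <- function(A, basal, theta_c, theta_r, primary_idx,
                          eps = 1e-9) {
  n <- nrow(A)
  alive <- rep(TRUE, n)
  alive[primary_idx] <- FALSE
  repeat {
    idx <- which(alive)
    if (length(idx) == 0) break
    Ap <- brute_rescale(A[idx, idx, drop = FALSE])
    # reachability from basal along resource -> consumer links
    reach <- basal[idx]
    repeat {
      grew <- FALSE
      for (j in seq_along(idx)) {
        if (!reach[j] && any(reach & A[idx, idx[j]] > 0)) {
          reach[j] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    doomed <- logical(length(idx))
    for (j in seq_along(idx)) {
      if (!basal[idx[j]] && sum(Ap[, j]) < theta_c - eps) doomed[j] <- TRUE
      if (sum(Ap[j, ]) > theta_r + eps) doomed[j] <- TRUE
      if (!basal[idx[j]] && !reach[j]) doomed[j] <- TRUE
    }
    if (!any(doomed)) break
    alive[idx[doomed]] <- FALSE
  }
  which(alive)
}

# a random weighted web over up to n nodes with a plausible basal backbone.
# Nodes without a directed path from a basal node are stripped before the
# thresholds freeze: assembly-rule webs cannot contain them (strict
# trophic-level ordering traces every supported chain down to a basal
# participant), and a frozen web must be a cascade fixed point
random_web <- function(n, p_link = 0.35, p_basal = 0.4, frozen = TRUE) {
  basal <- runif(n) < p_basal
  if (!any(basal)) basal[sample.int(n, 1)] <- TRUE
  A <- matrix(0, n, n)
  link <- matrix(runif(n * n) < p_link, n, n)
  diag(link) <- FALSE
  A[link] <- runif(sum(link), 0.05, 1)
  keep <- basal | coexsim:::reachable_from_basal(A > 0, basal)
  A <- A[keep, keep, drop = FALSE]
  basal <- basal[keep]
  web <- food_web(A, basal = basal)
  if (frozen) web <- freeze_thresholds(web)
  web
}

# a hand-controllable assembly context: trait matrix with all entries 1
# (raw score = |ph1| * |ph2|, normalized over [0, 100]) and wide-open,
# taxon-independent mass-ratio limits
plain_tm <- function() {
  structure(list(M = matrix(1, 26, 26, dimnames = list(letters, letters)),
                 norm_min = 0, norm_max = 100, n_pairs = 0),
            class = "trait_matrix")
}

open_limits <- function(ll = 1e-9, lu = 1e9) {
  taxa <- c("mammal", "bird", "reptile", "amphibian")
  m <- function(x) matrix(x, 4, 4, dimnames = list(taxa, taxa))
  structure(list(l_l = m(ll), l_u = m(lu), fallback = m(TRUE),
                 degenerate = m(FALSE), pooled = c(ll, lu)),
            class = "ratio_limits")
}

# minimal pool data.frame for assembly tests; phenotypes of length 8 give
# normalized compatibility 0.64 under plain_tm(), above the 0.55 threshold
craft_pool <- function(trophic_level, floor, mass = NULL, phen_len = 8) {
  n <- length(trophic_level)
  if (is.null(mass)) mass <- rep(100, n)
  phen_len <- rep_len(phen_len, n)
  df <- data.frame(
    id = seq_len(n), taxon = rep("mammal", n), body_mass = mass,
    trophic_level = trophic_level, trophic_breadth_floor = floor,
    basal = floor <= 1,
    phenotype = vapply(seq_len(n), function(i)
      paste(rep(letters[i %% 26 + 1], phen_len[i]), collapse = ""),
      character(1)),
    adaptive_capacity = rep(0.5, n))
  class(df) <- c("species_pool", "data.frame")
  df
}
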