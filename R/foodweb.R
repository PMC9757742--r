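#' Local food webs
#'
#' A food web is a weighted directed graph over the local community: links
#' run resource -> consumer, with weights equal to the rescaled functional
#' compatibility of the pair. `A[i, j]` is the interaction strength between
#' resource `i` and consumer `j`; `A_prime` is the competition-rescaled
#' matrix, and the two coextinction thresholds (`theta_consumer`,
#' `theta_resource`) are derived from `A_prime` at assembly and frozen after
#' the burn-in.
#'
#' @name food_web
NULL

#' Construct a food web from a weight matrix
#'
#' Builds a `food_web` directly from a raw resource-by-consumer weight
#' matrix (bypassing the assembly rules), computing the competition-rescaled
#' matrix and, unless supplied, the coextinction thresholds. Useful for
#' worked examples and for propagating cascades on externally specified
#' webs.
#'
#' @param A square non-negative weight matrix, resources in rows.
#' @param basal logical vector flagging basal nodes (default: none).
#' @param ids node identifiers (default `1:n`).
#' @param theta_consumer,theta_resource optional fixed thresholds; computed
#'   from `A_prime` when omitted.
#' @param frozen mark thresholds as frozen.
#' @return a `food_web`.
#' @export
food_web <- function(A, basal = rep(FALSE, nrow(A)), ids = seq_len(nrow(A)),
                     theta_consumer = NULL, theta_resource = NULL,
                     frozen = FALSE) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), all(A >= 0),
            length(basal) == nrow(A), length(ids) == nrow(A))
  new_food_web(ids = ids, basal = basal, A = A,
               theta_consumer = theta_consumer,
               theta_resource = theta_resource, frozen = frozen)
}

new_food_web <- function(ids, basal, A, theta_consumer = NULL,
                         theta_resource = NULL, frozen = FALSE) {
  Ap <- rescale_matrix(A)
  web <- structure(
    list(ids = ids, basal = basal, A = A, A_prime = Ap,
         theta_consumer = theta_consumer, theta_resource = theta_resource,
         frozen = frozen),
    class = "food_web")
  if (is.null(theta_consumer) || is.null(theta_resource)) {
    th <- compute_thresholds(web)
    web$theta_consumer <- th[["theta_consumer"]]
    web$theta_resource <- th[["theta_resource"]]
  }
  web
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf(
    "<food_web> %d species (%d basal), %d links, theta_c=%.4g theta_r=%.4g%s\n",
    length(x$ids), sum(x$basal), sum(x$A > 0),
    x$theta_consumer, x$theta_resource,
    if (x$frozen) " [frozen]" else ""))
  invisible(x)
}

#' Is a trophic link admissible?
#'
#' A directed link from `resource` to `consumer` is drawn iff (i) the
#' consumer's trophic level is strictly greater than the resource's, and the
#' resource's trophic level is not below the consumer's trophic breadth
#' floor; (ii) the resource:consumer body-mass ratio lies strictly inside
#' the `(l_l, l_u)` limits of the taxon pair; and (iii) the normalized
#' phenotype compatibility exceeds `c_thresh`.
#'
#' @param resource,consumer `virtual_species`.
#' @param limits a `ratio_limits`.
#' @param tm a `trait_matrix`.
#' @param c_thresh functional compatibility threshold (default 0.55).
#' @return list with `allowed` (logical) and `compatibility` (raw normalized
#'   compatibility, reported regardless of outcome).
#' @export
link_allowed <- function(resource, consumer, limits, tm, c_thresh = 0.55) {
  cf <- phenotype_compatibility(resource$phenotype, consumer$phenotype, tm)
  troph_ok <- consumer$trophic_level > resource$trophic_level &&
    resource$trophic_level >= consumer$trophic_breadth_floor
  ratio <- resource$body_mass / consumer$body_mass
  ll <- limits$l_l[resource$taxon, consumer$taxon]
  lu <- limits$l_u[resource$taxon, consumer$taxon]
  ratio_ok <- ratio > ll && ratio < lu
  list(allowed = troph_ok && ratio_ok && cf > c_thresh, compatibility = cf)
}

#' Rescale a link weight from raw compatibility
#'
#' Links only exist above the compatibility threshold; their weight is the
#' compatibility mapped linearly so that the threshold maps to 0 and perfect
#' compatibility to 1: `w = 1 - (1 - c_f) / (1 - c_thresh)`.
#'
#' @param c_f raw normalized compatibility, `> c_thresh`.
#' @param c_thresh compatibility threshold (default 0.55).
#' @return link weight in `(0, 1]`.
#' @export
rescale_link_weight <- function(c_f, c_thresh = 0.55) {
  if (any(c_f < c_thresh)) stop("links require c_f > c_thresh")
  1 - (1 - c_f) / (1 - c_thresh)
}

#' Competition-rescale an adjacency matrix
#'
#' Each entry of resource row `i` is divided by the row's total consumer
#' pressure `S_i = sum_j A[i, j]` and multiplied by its original value:
#' `A'[i, j] = A[i, j] * (A[i, j] / S_i)`. Rows with no consumers stay
#' all-zero. Column sums of `A'` measure resource availability to each
#' consumer; row sums measure consumer pressure on each resource.
#'
#' @param A non-negative weight matrix (resources in rows, consumers in
#'   columns).
#' @return the rescaled matrix `A'`.
#' @export
rescale_matrix <- function(A) {
  if (length(A) == 0) return(A)
  S <- rowSums(A)
  scale <- ifelse(S > 0, 1 / S, 0)
  A * A * scale
}

#' Coextinction thresholds of a web
#'
#' `theta_consumer` is the minimum available resource,
#' `min_j sum_i A'[i, j]`, over non-basal nodes; `theta_resource` is the
#' maximum consumer pressure, `max_i sum_j A'[i, j]`, over nodes with at
#' least one consumer. Webs with no non-basal consumers (or no consumed
#' resources) get sentinels that never trigger (`-Inf` / `+Inf`).
#'
#' @param web a `food_web`.
#' @return named numeric vector `theta_consumer`, `theta_resource`.
#' @export
compute_thresholds <- function(web) {
  Ap <- web$A_prime
  nonbasal <- !web$basal
  tc <- if (any(nonbasal)) min(colSums(Ap)[nonbasal]) else -Inf
  press <- rowSums(Ap)
  consumed <- rowSums(web$A) > 0
  tr <- if (any(consumed)) max(press[consumed]) else Inf
  c(theta_consumer = tc, theta_resource = tr)
}

#' Refresh and freeze a web's thresholds (end of burn-in)
#'
#' @param web a `food_web`.
#' @return the web with thresholds recomputed from the current `A_prime`
#'   and `frozen = TRUE`.
#' @export
freeze_thresholds <- function(web) {
  th <- compute_thresholds(web)
  web$theta_consumer <- th[["theta_consumer"]]
  web$theta_resource <- th[["theta_resource"]]
  web$frozen <- TRUE
  web
}

# pairwise weight matrix for a set of pool rows; 0 where no link.
# Vectorized: compatibility through letter-count matrices, ratio limits
# through taxon-indexed matrices.
pairwise_weights <- function(pool, members, limits, tm, c_thresh = 0.55,
                             counts = NULL) {
  n <- length(members)
  if (n == 0) return(matrix(0, 0, 0))
  sub <- pool[members, , drop = FALSE]
  U <- if (is.null(counts)) phenotype_counts(sub$phenotype)
       else counts[members, , drop = FALSE]
  cf <- normalize_compat(U %*% tm$M %*% t(U), tm)

  tl <- sub$trophic_level
  floor_ <- sub$trophic_breadth_floor
  troph_ok <- outer(tl, tl, "<") & outer(tl, floor_, ">=")

  ratio <- outer(sub$body_mass, sub$body_mass, function(r, c) r / c)
  ti <- match(sub$taxon, TAXA)
  ll <- limits$l_l[cbind(rep(ti, n), rep(ti, each = n))]
  lu <- limits$l_u[cbind(rep(ti, n), rep(ti, each = n))]
  ratio_ok <- ratio > matrix(ll, n, n) & ratio < matrix(lu, n, n)

  allowed <- troph_ok & ratio_ok & cf > c_thresh
  W <- matrix(0, n, n)
  W[allowed] <- 1 - (1 - cf[allowed]) / (1 - c_thresh)
  W
}

#' Assemble a local food web
#'
#' Evaluates all ordered pairs of the community under the three link rules,
#' assigns rescaled weights, and drops non-basal species with no incoming
#' resource link, iterating to a fixed point (a dropped resource can strand
#' its consumers). Basal species always participate. The rescaled matrix and
#' thresholds are computed for the surviving set.
#'
#' @param pool a `species_pool`.
#' @param members integer vector of pool row indices forming the community
#'   (may be empty).
#' @param limits a `ratio_limits`.
#' @param tm a `trait_matrix`.
#' @param c_thresh functional compatibility threshold.
#' @param counts optional precomputed letter-count matrix for the whole pool.
#' @return a `food_web` whose `ids` are pool row indices.
#' @export
build_web <- function(pool, members, limits, tm, c_thresh = 0.55,
                      counts = NULL) {
  members <- as.integer(members)
  W <- pairwise_weights(pool, members, limits, tm, c_thresh, counts)
  basal <- pool$basal[members]
  keep <- rep(TRUE, length(members))
  repeat {
    has_resource <- colSums(W[keep, , drop = FALSE] > 0) > 0
    drop <- keep & !basal & !has_resource
    if (!any(drop)) break
    keep[drop] <- FALSE
    W[drop, ] <- 0
    W[, drop] <- 0
  }
  new_food_web(ids = members[keep], basal = basal[keep],
               A = W[keep, keep, drop = FALSE])
}

#' Structural metrics of a web
#'
#' Richness, number of links, connectance (`E / n^2`, with the squared
#' denominator because no interaction is excluded a priori, self-links
#' included), diameter (longest finite shortest path on the undirected
#' projection), fraction of nodes in the largest weakly connected component,
#' and community means/maxima of trophic level and body mass. All metrics
#' are 0 for an empty web by convention.
#'
#' @param web a `food_web`.
#' @param pool the `species_pool` the web's ids index into.
#' @return one-row data.frame.
#' @export
web_metrics <- function(web, pool) {
  n <- length(web$ids)
  if (n == 0) {
    return(data.frame(richness = 0, edges = 0, connectance = 0, diameter = 0,
                      lwcc_fraction = 0, mean_tl = 0, max_tl = 0,
                      mean_mass = 0, max_mass = 0, mean_log10_mass = 0))
  }
  E <- sum(web$A > 0)
  g <- igraph::graph_from_adjacency_matrix(web$A > 0, mode = "directed")
  diam <- if (E == 0) 0 else
    igraph::diameter(igraph::as_undirected(g, mode = "collapse"),
                     unconnected = TRUE)
  comps <- igraph::components(g, mode = "weak")
  sub <- pool[web$ids, ]
  data.frame(
    richness = n, edges = E, connectance = E / n^2, diameter = diam,
    lwcc_fraction = max(comps$csize) / n,
    mean_tl = mean(sub$trophic_level), max_tl = max(sub$trophic_level),
    mean_mass = mean(sub$body_mass), max_mass = max(sub$body_mass),
    mean_log10_mass = mean(log10(sub$body_mass)))
}

#' Serialize a web as a weighted edge list
#'
#' @param web a `food_web`.
#' @return data.frame with columns `resource_id`, `consumer_id`, `weight`,
#'   `weight_rescaled`.
#' @export
web_edge_list <- function(web) {
  idx <- which(web$A > 0, arr.ind = TRUE)
  data.frame(resource_id = web$ids[idx[, 1]],
             consumer_id = web$ids[idx[, 2]],
             weight = web$A[idx],
             weight_rescaled = web$A_prime[idx])
}
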