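#' Coextinction cascades
#'
#' After primary losses are removed from a web, the cascade iterates to a
#' fixed point. In each sweep the competition-rescaled matrix is recomputed
#' for the current survivors and three criteria are evaluated against the
#' same snapshot: (a) bottom-up -- a non-basal consumer whose available
#' resource `sum_i A'[i, j]` falls strictly below the frozen
#' `theta_consumer`; (b) top-down -- a resource whose consumer pressure
#' `sum_j A'[i, j]` rises strictly above the frozen `theta_resource`; and
#' (c) disconnection -- a non-basal species with no directed path from any
#' basal node. All species marked in a sweep are removed simultaneously and
#' the sweep repeats until nothing is marked. On a frozen equilibrium web
#' with no primary losses, nothing goes extinct.
#'
#' @name coextinction_cascade
NULL

# nodes reachable from the basal set along resource -> consumer links
reachable_from_basal <- function(adj, basal) {
  reach <- basal
  repeat {
    new <- reach | (colSums(adj[reach, , drop = FALSE]) > 0)
    if (all(new == reach)) return(reach)
    reach <- new
  }
}

#' Propagate an extinction cascade
#'
#' @param web a `food_web` with frozen (or assembly-time) thresholds.
#' @param primary_losses vector of node ids (pool row indices) to remove
#'   before propagation; must be a subset of `web$ids`.
#' @return list with `web` (the surviving sub-web, thresholds untouched),
#'   `coextinct` (ids lost to propagation, excluding the primary losses) and
#'   `causes` (character vector parallel to `coextinct`, one of
#'   `"bottom_up"`, `"top_down"`, `"disconnected"`; when several criteria
#'   fire in the same sweep for one species they are reported in that
#'   priority order).
#' @export
cascade <- function(web, primary_losses = integer(0)) {
  stopifnot(all(primary_losses %in% web$ids))
  keep <- !(web$ids %in% primary_losses)
  ids <- web$ids[keep]
  basal <- web$basal[keep]
  A <- web$A[keep, keep, drop = FALSE]

  coextinct <- integer(0)
  causes <- character(0)
  while (length(ids) > 0) {
    Ap <- rescale_matrix(A)
    avail <- colSums(Ap)
    press <- rowSums(Ap)
    bu <- !basal & avail < web$theta_consumer
    td <- press > web$theta_resource
    disc <- !basal & !reachable_from_basal(A > 0, basal)
    out <- bu | td | disc
    if (!any(out)) break
    cause <- ifelse(bu, "bottom_up", ifelse(td, "top_down", "disconnected"))
    coextinct <- c(coextinct, ids[out])
    causes <- c(causes, cause[out])
    ids <- ids[!out]
    basal <- basal[!out]
    A <- A[!out, !out, drop = FALSE]
  }

  surv <- new_food_web(ids = ids, basal = basal, A = A,
                       theta_consumer = web$theta_consumer,
                       theta_resource = web$theta_resource,
                       frozen = web$frozen)
  list(web = surv, coextinct = coextinct, causes = causes)
}

#' Adjudicate a colonization attempt
#'
#' The colonizer has already passed the climatic acceptance draw. For a
#' non-basal colonizer the web is rebuilt with the colonizer included under
#' the resident web's frozen thresholds: if it gains no resource link it is
#' rejected; if its added pressure (or competition) violates a threshold the
#' cascade runs, possibly removing the colonizer itself and others; else it
#' is simply accepted. A basal colonizer always enters, but if the basal
#' count then exceeds the locality's basal cap, basal species are removed in
#' decreasing order of combined climatic extinction probability (least
#' suitable first; ties broken against the most recent arrival) until the
#' cap is restored, and those removals propagate through the cascade.
#'
#' @param web resident `food_web`.
#' @param colonizer_idx pool row index of the colonizer.
#' @param pool,limits,tm,c_thresh web assembly inputs (see [build_web()]).
#' @param basal_cap locality's initial basal richness.
#' @param suitability function mapping pool row indices to combined climatic
#'   extinction probability under current local conditions (used only for
#'   the basal cap rule).
#' @param arrival_rank named numeric: later arrivals have larger rank; the
#'   colonizer is treated as the latest. Used only to break suitability ties.
#' @param counts optional precomputed phenotype letter-count matrix.
#' @return list with `outcome` (`"rejected"`, `"accepted"`, or
#'   `"accepted_with_cascade"`), `web`, `removed` (ids lost, including a
#'   rejected or cascaded-away colonizer), `causes` (parallel to `removed`).
#' @export
try_colonize <- function(web, colonizer_idx, pool, limits, tm,
                         c_thresh = 0.55, basal_cap = Inf,
                         suitability = NULL, arrival_rank = NULL,
                         counts = NULL) {
  colonizer_idx <- as.integer(colonizer_idx)
  stopifnot(!(colonizer_idx %in% web$ids))
  members <- c(web$ids, colonizer_idx)
  web2 <- build_web(pool, members, limits, tm, c_thresh, counts)
  web2$theta_consumer <- web$theta_consumer
  web2$theta_resource <- web$theta_resource
  web2$frozen <- web$frozen
  is_basal <- pool$basal[colonizer_idx]

  if (!is_basal && !(colonizer_idx %in% web2$ids)) {
    return(list(outcome = "rejected", web = web,
                removed = colonizer_idx, causes = "rejected"))
  }

  removed <- integer(0)
  causes <- character(0)

  if (is_basal) {
    basal_ids <- web2$ids[web2$basal]
    excess <- length(basal_ids) - basal_cap
    if (excess > 0) {
      p_ext <- vapply(basal_ids, suitability, numeric(1))
      rank <- if (is.null(arrival_rank)) seq_along(basal_ids) else
        ifelse(basal_ids == colonizer_idx, Inf,
               arrival_rank[as.character(basal_ids)])
      ord <- order(-p_ext, -rank)  # least suitable first, newest first on ties
      victims <- basal_ids[ord][seq_len(excess)]
      removed <- victims
      causes <- rep("outcompeted", length(victims))
      res <- cascade(web2, victims)
      web2 <- res$web
      removed <- c(removed, res$coextinct)
      causes <- c(causes, res$causes)
      outcome <- if (length(res$coextinct) > 0 ||
                     !all(victims == colonizer_idx))
        "accepted_with_cascade" else "rejected"
      if (identical(as.integer(victims), colonizer_idx) &&
          length(res$coextinct) == 0)
        outcome <- "rejected"
      return(list(outcome = outcome, web = web2,
                  removed = removed, causes = causes))
    }
  }

  res <- cascade(web2, integer(0))
  if (length(res$coextinct) > 0) {
    return(list(outcome = "accepted_with_cascade", web = res$web,
                removed = res$coextinct, causes = res$causes))
  }
  list(outcome = "accepted", web = res$web,
       removed = integer(0), causes = character(0))
}
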